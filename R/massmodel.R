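#' Mass model for sequence-defined oligo(amide-urethane)s
#'
#' Everything needed to map a monomer sequence to observable masses: the
#' alpha-end group (the acid or alcohol linker residue that starts the chain),
#' the omega-end (the thiolactone-derived stop group), the constant mass
#' offsets that backbone urethane cleavage leaves on the start-containing
#' (`delta_left`) and stop-containing (`delta_right`) fragments, the adduct
#' mass (sodium cationization by default, as in positive-mode MALDI), and the
#' charge state.
#'
#' All masses are monoisotopic. The true end-group and cleavage offsets of a
#' given chemistry are instrument-calibration facts and are therefore plain
#' configuration here; [toy_mass_model()] provides the documented model used
#' throughout the tests and examples.
#'
#' @param alpha_mass Mass of the alpha-end group (Da).
#' @param omega_mass Mass of the omega-end group (Da).
#' @param delta_left Constant offset of a start-containing cleavage fragment (Da).
#' @param delta_right Constant offset of a stop-containing cleavage fragment (Da).
#' @param adduct_mass Adduct mass (Da); default is the sodium cation.
#' @param charge Positive integer charge state; MALDI read-out is singly
#'   charged, the parameter keeps ESI data usable.
#' @return An object of class `mass_model`.
#' @examples
#' m <- mass_model(100, 50, 1, 2, adduct_mass = 0)
#' @export
mass_model <- function(alpha_mass, omega_mass, delta_left = 0, delta_right = 0,
                       adduct_mass = 22.989218, charge = 1L) {
  vals <- c(alpha_mass, omega_mass, delta_left, delta_right, adduct_mass)
  if (any(!is.finite(vals))) stop("all model masses must be finite")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be an integer >= 1")
  structure(list(alpha_mass = alpha_mass, omega_mass = omega_mass,
                 delta_left = delta_left, delta_right = delta_right,
                 adduct_mass = adduct_mass, charge = charge),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model>\n")
  for (f in names(unclass(x))) cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

#' Reference toy mass model used in tests and examples
#'
#' End groups and cleavage offsets are chosen so that, with a [toy_alphabet()]
#' on a regular 5 Da mass lattice, the prefix series, suffix series and
#' precursor each sit on a distinct off-lattice residue class: peaks from
#' different series can then never fall within a realistic matching tolerance
#' of one another, which makes clean-channel reads provably exact.
#'
#' @return A [mass_model()] with `alpha_mass = 47`, `omega_mass = 75`,
#'   `delta_left = 1.3`, `delta_right = 0.9`, sodium adduct, charge 1.
#' @export
toy_mass_model <- function() {
  mass_model(alpha_mass = 47, omega_mass = 75,
             delta_left = 1.3, delta_right = 0.9)
}

#' Read / write a mass-model configuration file
#'
#' Flat `key: value` text with the fields `alpha_mass`, `omega_mass`,
#' `delta_left`, `delta_right`, `adduct_mass`, `charge`.
#'
#' @param path File path.
#' @return `read_mass_model()` returns a [mass_model()];
#'   `write_mass_model()` returns `path` invisibly.
#' @export
read_mass_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop_config("malformed mass-model line: ", lines[bad][1L])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- as.numeric(vapply(kv, `[[`, "", 3L))
  need <- c("alpha_mass", "omega_mass", "delta_left", "delta_right",
            "adduct_mass", "charge")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop_config("mass-model config lacks field(s): ",
                paste(missing, collapse = ", "))
  v <- as.list(vals[match(need, keys)])
  names(v) <- need
  mass_model(v$alpha_mass, v$omega_mass, v$delta_left, v$delta_right,
             v$adduct_mass, v$charge)
}

#' @rdname read_mass_model
#' @param model A [mass_model()] to write.
#' @export
write_mass_model <- function(model, path) {
  fields <- unclass(model)
  writeLines(sprintf("%s: %.9g", names(fields), unlist(fields)), path)
  invisible(path)
}

#' Observable m/z of an intact oligomer
#'
#' The precursor m/z: `(alpha + sum of unit masses + omega + adduct) / charge`.
#' Composition alone determines this value -- any permutation of the same
#' sequence has the same precursor mass, which is precisely why sequencing
#' needs the fragment ladders of [fragment_ladders()].
#'
#' @param seq A sequence: a single string of single-character labels
#'   (e.g. `"ABBA"`) or a character vector of labels.
#' @param model A [mass_model()].
#' @param alphabet An [alphabet()].
#' @param allow_empty If `TRUE`, an empty sequence returns the bare scaffold
#'   mass (alpha + omega + adduct)/charge instead of an error.
#' @return The precursor m/z in Da.
#' @examples
#' ab <- alphabet(c("A", "B"), c(10, 20))
#' m <- mass_model(100, 50, adduct_mass = 0)
#' oligomer_mass("AB", m, ab)  # 180
#' @export
oligomer_mass <- function(seq, model, alphabet, allow_empty = FALSE) {
  labels <- split_labels(seq)
  if (length(labels) == 0L) {
    if (!allow_empty) stop_data("empty sequence (set allow_empty = TRUE for the bare scaffold)")
    return((model$alpha_mass + model$omega_mass + model$adduct_mass) / model$charge)
  }
  u <- label_masses(labels, alphabet)
  (model$alpha_mass + sum(u) + model$omega_mass + model$adduct_mass) / model$charge
}

#' Theoretical prefix/suffix fragment ladders of an oligomer
#'
#' Backbone cleavage at each urethane bond yields two complementary fragment
#' series. The start-containing (prefix) series covers units `1..i`:
#' `p_i = alpha + sum(u_1..u_i) + delta_left + adduct`; the stop-containing
#' (suffix) series covers the last `j` units:
#' `s_j = sum(u_(L-j+1)..u_L) + omega + delta_right + adduct`.
#' Successive prefix differences reproduce the unit masses in order, successive
#' suffix differences in reverse order -- the sequence can be read left to
#' right and right to left. For every interior cleavage site,
#' `p_i + s_(L-i)` is the same constant, `precursor * charge + delta_left +
#' delta_right + adduct`.
#'
#' @inheritParams oligomer_mass
#' @return An object of class `fragment_ladder`: a list with `prefix` and
#'   `suffix` (numeric, length `L`, strictly increasing), `precursor`, and the
#'   label vector `labels`.
#' @examples
#' ab <- alphabet(c("A", "B"), c(10, 20))
#' m <- mass_model(100, 50, delta_left = 1, delta_right = 2, adduct_mass = 0)
#' fragment_ladders("AB", m, ab)
#' @export
fragment_ladders <- function(seq, model, alphabet) {
  labels <- split_labels(seq)
  if (length(labels) < 1L) stop_data("fragment ladders need a sequence of length >= 1")
  u <- label_masses(labels, alphabet)
  L <- length(u)
  prefix <- model$alpha_mass + cumsum(u) + model$delta_left + model$adduct_mass
  suffix <- cumsum(rev(u)) + model$omega_mass + model$delta_right + model$adduct_mass
  structure(list(prefix = prefix, suffix = suffix,
                 precursor = (model$alpha_mass + sum(u) + model$omega_mass +
                                model$adduct_mass) / model$charge,
                 labels = labels),
            class = "fragment_ladder")
}

#' @export
print.fragment_ladder <- function(x, ...) {
  cat("<fragment_ladder> ", paste(x$labels, collapse = ""),
      "  precursor m/z ", format(x$precursor), "\n", sep = "")
  cat("  prefix: ", paste(format(x$prefix), collapse = " "), "\n", sep = "")
  cat("  suffix: ", paste(format(x$suffix), collapse = " "), "\n", sep = "")
  invisible(x)
}
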