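#' Chemical alphabets of sequence-defined building blocks
#'
#' An alphabet is an ordered set of building blocks, each a single-character
#' label with a monoisotopic unit mass (the mass one incorporated unit adds to
#' the chain: backbone repeat plus side-chain functionality). Blocks are either
#' `coding` -- they carry information, and their 0-based position among the
#' coding blocks is their digit value in the positional numeral system -- or
#' `spacer`, a non-coding flag used only to pad fragments.
#'
#' @param labels Character vector of single printable characters, unique.
#' @param unit_masses Numeric vector of positive monoisotopic masses (Da),
#'   pairwise distinct.
#' @param roles Character vector, each `"coding"` or `"spacer"`; recycled.
#' @return An object of class `oligo_alphabet`: a data frame with columns
#'   `label`, `unit_mass`, `role`.
#' @examples
#' ab <- alphabet(c("A", "B", "*"), c(100, 105, 130), c("coding", "coding", "spacer"))
#' alphabet_base(ab)
#' @export
alphabet <- function(labels, unit_masses, roles = "coding") {
  labels <- as.character(labels)
  unit_masses <- as.numeric(unit_masses)
  roles <- rep_len(as.character(roles), length(labels))
  if (length(labels) == 0L) stop("alphabet needs at least one block")
  if (length(unit_masses) != length(labels))
    stop("`labels` and `unit_masses` must have the same length")
  if (any(nchar(labels) != 1L))
    stop("block labels must be single characters: ",
         paste(labels[nchar(labels) != 1L], collapse = ", "))
  if (anyDuplicated(labels))
    stop("duplicate block labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(!is.finite(unit_masses)) || any(unit_masses <= 0))
    stop("unit masses must be finite and > 0")
  if (anyDuplicated(unit_masses))
    stop("unit masses must be pairwise distinct")
  if (!all(roles %in% c("coding", "spacer")))
    stop("roles must be \"coding\" or \"spacer\"")
  structure(
    data.frame(label = labels, unit_mass = unit_masses, role = roles,
               stringsAsFactors = FALSE),
    class = c("oligo_alphabet", "data.frame")
  )
}

#' @export
print.oligo_alphabet <- function(x, ...) {
  cat("<oligo_alphabet> ", alphabet_base(x), " coding block(s)",
      if (any(x$role == "spacer"))
        paste0(", spacer \"", spacer_label(x), "\""),
      "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Number of coding blocks (the base of the numeral system)
#' @param ab An [alphabet()].
#' @return Integer count of coding blocks.
#' @export
alphabet_base <- function(ab) sum(ab$role == "coding")

#' Label of the non-coding spacer block
#' @param ab An [alphabet()].
#' @return The spacer label, or `NA_character_` if the alphabet has none.
#' @export
spacer_label <- function(ab) {
  sp <- ab$label[ab$role == "spacer"]
  if (length(sp) == 0L) NA_character_ else sp[[1L]]
}

#' Smallest pairwise unit-mass difference
#'
#' Readers can only discriminate blocks whose masses differ by more than twice
#' the matching tolerance; this is checked at reader construction.
#' @param ab An [alphabet()].
#' @return Minimum absolute pairwise unit-mass gap (Da); `Inf` for one block.
#' @export
alphabet_min_gap <- function(ab) {
  m <- sort(ab$unit_mass)
  if (length(m) < 2L) return(Inf)
  min(diff(m))
}

# coding labels in digit order (digit value = position - 1)
coding_labels <- function(ab) ab$label[ab$role == "coding"]

# map labels -> digit values (0-based); spacer -> NA; unknown -> error
labels_to_digits <- function(labels, ab, what = "sequence") {
  cl <- coding_labels(ab)
  idx <- match(labels, cl)
  unknown <- is.na(idx) & !(labels %in% ab$label)
  if (any(unknown))
    stop("unknown label(s) in ", what, ": ",
         paste(unique(labels[unknown]), collapse = ", "))
  idx - 1L  # NA for spacer blocks
}

# digit values (0-based) -> labels
digits_to_labels <- function(digits, ab) {
  cl <- coding_labels(ab)
  if (any(digits < 0L | digits >= length(cl)))
    stop("digit value out of range for this alphabet")
  cl[digits + 1L]
}

# unit masses of a label vector, with resolution error naming the label
label_masses <- function(labels, ab) {
  idx <- match(labels, ab$label)
  if (anyNA(idx))
    stop("unknown label(s): ", paste(unique(labels[is.na(idx)]), collapse = ", "))
  ab$unit_mass[idx]
}

# split a sequence string into single-character labels
split_labels <- function(seq) {
  if (length(seq) == 1L && is.character(seq)) {
    if (!nzchar(seq)) return(character(0))
    strsplit(seq, "", fixed = TRUE)[[1L]]
  } else {
    as.character(seq)
  }
}

#' Construct a regularly spaced test alphabet
#'
#' Generates `base` coding blocks labelled `A`, `B`, `C`, ... with unit masses
#' `base_mass + k * spacing` (k = 0, 1, ...), plus one non-coding spacer block
#' `"*"` one spacing step above the heaviest coding block. Optional mass jitter
#' perturbs each mass uniformly while preserving a minimum pairwise gap; the
#' constructor refuses settings that cannot guarantee the requested gap.
#'
#' With the default spacing the heaviest unit is lighter than two copies of the
#' lightest, so a prefix-ladder step can never be confused with two steps.
#'
#' @param base Number of coding blocks (>= 1).
#' @param spacing Mass increment between consecutive blocks (Da, > 0).
#' @param base_mass Mass of the first block (Da, > 0).
#' @param jitter Maximum absolute uniform mass perturbation per block (Da).
#' @param seed Optional integer seed for the jitter.
#' @param min_gap Minimum pairwise unit-mass gap that must survive the jitter
#'   (Da); defaults to 0.04, twice the default reader tolerance.
#' @return An [alphabet()].
#' @examples
#' toy_alphabet(15, 5, 100)
#' @export
toy_alphabet <- function(base, spacing = 5, base_mass = 100, jitter = 0,
                         seed = NULL, min_gap = 0.04) {
  stopifnot(base >= 1L, base_mass > 0)
  if (spacing <= 0) stop("spacing must be > 0")
  if (spacing - 2 * jitter <= min_gap)
    stop("spacing ", spacing, " Da is too small to guarantee a ", min_gap,
         " Da pairwise gap at jitter ", jitter)
  pool <- c(LETTERS, letters, as.character(0:9))
  if (base > length(pool)) stop("at most ", length(pool), " coding blocks supported")
  masses <- base_mass + spacing * (0:base)  # last one is the spacer
  if (jitter > 0) {
    masses <- masses + local_runif(seed, length(masses), -jitter, jitter)
  }
  alphabet(c(pool[seq_len(base)], "*"), masses,
           c(rep("coding", base), "spacer"))
}

#' Build an alphabet whose labels are text characters
#'
#' Used by the text codec: every distinct character (letters, digit position
#' prefixes, punctuation) becomes one coding block with its own mass.
#'
#' @param symbols Character vector of single characters (order fixes digit
#'   values).
#' @param spacing,base_mass As in [toy_alphabet()].
#' @return An [alphabet()] with one coding block per symbol (no spacer).
#' @export
char_alphabet <- function(symbols, spacing = 5, base_mass = 100) {
  symbols <- unique(as.character(symbols))
  alphabet(symbols, base_mass + spacing * (seq_along(symbols) - 1L), "coding")
}

#' Read / write a mass-table TSV
#'
#' The on-disk format is a UTF-8 tab-separated table with header
#' `label<TAB>unit_mass<TAB>role`, one block per line.
#'
#' @param path File path.
#' @return `read_alphabet_tsv()` returns an [alphabet()];
#'   `write_alphabet_tsv()` returns `path` invisibly.
#' @export
read_alphabet_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character"),
                          fileEncoding = "UTF-8")
  need <- c("label", "unit_mass", "role")
  if (!all(need %in% names(df)))
    stop("mass-table TSV must have columns: ", paste(need, collapse = ", "))
  alphabet(df$label, df$unit_mass, df$role)
}

#' @rdname read_alphabet_tsv
#' @param ab An [alphabet()] to write.
#' @export
write_alphabet_tsv <- function(ab, path) {
  utils::write.table(as.data.frame(ab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
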