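# De novo read-out of a monomer sequence from an MS/MS peak list.
#
# Controlled backbone cleavage produces two complementary fragment series:
# start-containing (prefix) fragments whose successive mass differences spell
# the sequence left to right, and stop-containing (suffix) fragments spelling
# it right to left. The reader filters the peak list by signal-to-noise,
# anchors each series at its smallest fragment, walks both ladders by testing
# one unit-mass extension per block per position, and merges the two
# partial readings. Each position is witnessed by up to two independent peaks,
# so a single missing peak anywhere never changes a read.

# warn (once per call) when block spacing cannot support the tolerance
.check_spacing <- function(alphabet, cfg) {
  gap <- alphabet_min_gap(alphabet)
  if (is.finite(gap) && gap <= 2 * cfg$tolerance && cfg$tolerance_unit == "da")
    warning("smallest unit-mass gap (", format(gap), " Da) is not above twice ",
            "the tolerance (", format(2 * cfg$tolerance), " Da); ",
            "ambiguous matches are possible", call. = FALSE)
  invisible(gap)
}

# series base masses: the mass every prefix (resp. suffix) fragment shares
# before any chain unit is added
.series_base <- function(model, side) {
  if (side == "left") model$alpha_mass + model$delta_left + model$adduct_mass
  else model$omega_mass + model$delta_right + model$adduct_mass
}

#' Locate the ladder anchors of a spectrum
#'
#' The anchors are the smallest fragment of each series: a start-containing
#' fragment holding only the first unit (`alpha + u(b) + delta_left + adduct`)
#' and a stop-containing fragment holding only the last
#' (`u(b) + omega + delta_right + adduct`). Every peak within tolerance of one
#' of these masses, for any block `b` (spacer included), is reported together with all
#' block labels compatible with it -- near-isobaric blocks yield multi-label
#' anchors, and the ambiguity is propagated rather than resolved.
#'
#' @param pl A [peak_list()], normally already passed through [filter_peaks()].
#' @param alphabet An [alphabet()].
#' @param model A [mass_model()].
#' @param cfg A [reader_config()]. With `require_both_anchors = TRUE` and
#'   `strict = TRUE`, an empty anchor side raises an anchor-missing error
#'   naming the side.
#' @param strict Whether to enforce the both-anchors requirement here.
#' @return A list with data frames `left` and `right`; columns `mz`,
#'   `intensity`, `labels` (list column of candidate labels).
#' @export
anchor_search <- function(pl, alphabet, model, cfg = reader_config(),
                          strict = cfg$require_both_anchors) {
  stopifnot(inherits(pl, "peak_list"))
  .check_spacing(alphabet, cfg)
  blocks <- as.data.frame(alphabet)  # spacer included: written chains contain real spacer monomers
  one_side <- function(side) {
    targets <- .series_base(model, side) + blocks$unit_mass
    hit <- vapply(targets, function(t) .match_peak(pl$mz, t, .tol_at(cfg, t)),
                  integer(1))
    ok <- !is.na(hit)
    peaks <- unique(hit[ok])
    data.frame(mz = pl$mz[peaks], intensity = pl$intensity[peaks],
               labels = I(lapply(peaks, function(p) blocks$label[ok & hit == p])))
  }
  left <- one_side("left")
  right <- one_side("right")
  if (strict) {
    for (side in c("left", "right")) {
      if (nrow(if (side == "left") left else right) == 0L)
        stop_data("anchor missing: no ", side, "-side (",
                  if (side == "left") "start" else "stop",
                  "-containing) fragment found in the spectrum",
                  class = "oligostore_anchor_error")
    }
  }
  list(left = left, right = right)
}

#' Walk one fragment ladder
#'
#' From a starting mass (by default the bare series base, before any chain
#' unit), repeatedly tests `current + u(b)` for every block `b` against
#' the peak list. A unique hit assigns the block at the current position and
#' advances the theoretical mass (observed jitter is never accumulated); no
#' hit records a gap and halts; two or more hits record an ambiguity with the
#' candidate labels and halt. Left walks assign positions `1, 2, ...`; right
#' walks assign `L, L-1, ...`. Cost is one tolerance lookup per block and
#' position: O(L * B * log P).
#'
#' @param pl A filtered [peak_list()].
#' @param start_mass Starting mass of the walk (Da); `NULL` for the series
#'   base.
#' @param direction `"left"` (prefix series) or `"right"` (suffix series).
#' @param L Known chain length.
#' @param alphabet An [alphabet()].
#' @param model A [mass_model()].
#' @param cfg A [reader_config()].
#' @param start_step First step of the walk (1-based; steps beyond the first
#'   are used when resuming a halted walk from a known mass).
#' @return A list of class `ladder_walk`: `assignment` (character length `L`,
#'   `NA` where unassigned), `matched` (peak index per position), `gap_at`,
#'   `ambiguous_at`, `candidates`, `n_lookups`.
#' @export
ladder_walk <- function(pl, start_mass = NULL, direction = c("left", "right"),
                        L, alphabet, model, cfg = reader_config(),
                        start_step = 1L) {
  direction <- match.arg(direction)
  L <- as.integer(L)
  stopifnot(inherits(pl, "peak_list"), L >= 1L)
  blocks <- as.data.frame(alphabet)  # spacer included: written chains contain real spacer monomers
  current <- start_mass %||% .series_base(model, direction)
  assignment <- rep(NA_character_, L)
  matched <- rep(NA_integer_, L)
  gap_at <- NA_integer_
  ambiguous_at <- NA_integer_
  candidates <- character(0)
  n_lookups <- 0L
  for (step in seq.int(start_step, L)) {
    pos <- if (direction == "left") step else L - step + 1L
    targets <- current + blocks$unit_mass
    hit <- vapply(targets, function(t) .match_peak(pl$mz, t, .tol_at(cfg, t)),
                  integer(1))
    n_lookups <- n_lookups + nrow(blocks)
    ok <- which(!is.na(hit))
    if (length(ok) == 0L) {
      gap_at <- pos
      break
    }
    if (length(ok) > 1L) {
      ambiguous_at <- pos
      candidates <- blocks$label[ok]
      break
    }
    assignment[pos] <- blocks$label[ok]
    matched[pos] <- hit[ok]
    current <- current + blocks$unit_mass[ok]
  }
  structure(list(direction = direction, assignment = assignment,
                 matched = matched, gap_at = gap_at,
                 ambiguous_at = ambiguous_at, candidates = candidates,
                 n_lookups = n_lookups),
            class = "ladder_walk")
}

#' Read a monomer sequence from an MS/MS spectrum
#'
#' The full read-out: signal-to-noise filtering, anchor search, a left walk
#' along the start-containing ladder, a right walk along the stop-containing
#' ladder, and a merge of the two partial readings. Positions claimed by both
#' walks must agree exactly (label equality); positions claimed by one walk
#' are accepted; an uncovered position leaves the read `ambiguous`, with
#' candidate labels inferred from the precursor mass when only one position is
#' open. A `unique` read additionally requires the reconstructed precursor
#' mass to match the observed one within tolerance and -- under
#' `require_both_anchors` -- that each fragment series contributed at least
#' one matched peak.
#'
#' @param pl A [peak_list()].
#' @param alphabet An [alphabet()].
#' @param model A [mass_model()].
#' @param L Known chain length (supplied per sample, as for any
#'   sequence-defined material of controlled length).
#' @param cfg A [reader_config()].
#' @return An object of class `read_result`: fields `sequence` (string, `NA`
#'   if not unique), `labels`, `evidence` (`"left"`, `"right"` or `"both"`
#'   per position), `status` (`"unique"`, `"ambiguous"` or `"failed"`),
#'   `candidates`, `matched_peaks`, `unexplained_peaks` and `diagnostics`.
#' @examples
#' ab <- toy_alphabet(15)
#' mm <- toy_mass_model()
#' pl <- simulate_spectrum("ACME", ab, mm)
#' read_sequence(pl, ab, mm, L = 4)
#' @export
read_sequence <- function(pl, alphabet, model, L, cfg = reader_config()) {
  stopifnot(inherits(pl, "peak_list"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop_data("chain length L must be >= 1")
  .check_spacing(alphabet, cfg)
  fl <- filter_peaks(pl, cfg)

  lw <- ladder_walk(fl, NULL, "left", L, alphabet, model, cfg)
  rw <- ladder_walk(fl, NULL, "right", L, alphabet, model, cfg)
  diag <- list(gap_left = lw$gap_at, gap_right = rw$gap_at,
               n_lookups = lw$n_lookups + rw$n_lookups)

  fail <- function(reason, ...) {
    structure(list(sequence = NA_character_, labels = rep(NA_character_, L),
                   evidence = rep(NA_character_, L), status = "failed",
                   candidates = list(), matched_peaks = NULL,
                   unexplained_peaks = NULL,
                   diagnostics = c(diag, list(reason = reason, ...))),
              class = "read_result")
  }

  labels <- rep(NA_character_, L)
  for (k in seq_len(L)) {
    l <- lw$assignment[k]
    r <- rw$assignment[k]
    if (!is.na(l) && !is.na(r)) {
      if (l != r)
        return(fail("conflict", conflict_at = k,
                    left_label = l, right_label = r))
      labels[k] <- l
    } else if (!is.na(l)) {
      if (identical(rw$ambiguous_at, k) && !(l %in% rw$candidates))
        return(fail("conflict", conflict_at = k))
      labels[k] <- l
    } else if (!is.na(r)) {
      if (identical(lw$ambiguous_at, k) && !(r %in% lw$candidates))
        return(fail("conflict", conflict_at = k))
      labels[k] <- r
    }
  }

  open <- which(is.na(labels))
  if (length(open) > 0L) {
    cand <- list()
    if (length(open) == 1L) {
      # complementary-mass inference: the one open unit mass follows from the
      # precursor and the assigned units
      blocks <- as.data.frame(alphabet)  # spacer included: written chains contain real spacer monomers
      residual <- pl$precursor_mz * model$charge - model$alpha_mass -
        model$omega_mass - model$adduct_mass -
        sum(label_masses(labels[-open], alphabet))
      hits <- blocks$label[abs(blocks$unit_mass - residual) <=
                             .tol_at(cfg, pl$precursor_mz) * 2]
      cand[[as.character(open)]] <- hits
    } else {
      for (k in open) {
        cc <- character(0)
        if (identical(lw$ambiguous_at, k)) cc <- union(cc, lw$candidates)
        if (identical(rw$ambiguous_at, k)) cc <- union(cc, rw$candidates)
        cand[[as.character(k)]] <- cc
      }
    }
    out <- fail("uncovered", uncovered = open)
    out$labels <- labels
    out$status <- "ambiguous"
    out$candidates <- cand
    return(out)
  }

  # verification pass: match the full theoretical ladders of the read
  # sequence, annotate per-position evidence, enforce the anchor policy and
  # precursor consistency
  lad <- fragment_ladders(labels, model, alphabet)
  p_hit <- vapply(lad$prefix, function(t) .match_peak(fl$mz, t, .tol_at(cfg, t)),
                  integer(1))
  s_hit <- vapply(lad$suffix, function(t) .match_peak(fl$mz, t, .tol_at(cfg, t)),
                  integer(1))
  prec_hit <- .match_peak(fl$mz, lad$precursor, .tol_at(cfg, lad$precursor))

  if (cfg$require_both_anchors) {
    if (!any(!is.na(p_hit)))
      return(fail("anchor_missing", side = "left"))
    if (!any(!is.na(s_hit)))
      return(fail("anchor_missing", side = "right"))
  }
  prec_err <- abs(lad$precursor - pl$precursor_mz)
  if (prec_err > .tol_at(cfg, lad$precursor))
    return(fail("precursor_mismatch", precursor_error = prec_err))

  # evidence: position k is witnessed on the left by prefix fragment k and on
  # the right by the suffix fragment whose newest unit is k
  ev_left <- !is.na(p_hit)
  ev_right <- rev(!is.na(s_hit))
  evidence <- ifelse(ev_left & ev_right, "both",
                     ifelse(ev_left, "left", "right"))
  matched <- data.frame(
    position = rep(seq_len(L), 2L),
    series = rep(c("prefix", "suffix"), each = L),
    theoretical = c(lad$prefix, lad$suffix),
    peak_mz = c(fl$mz[p_hit], fl$mz[s_hit]))
  explained <- unique(c(p_hit[!is.na(p_hit)], s_hit[!is.na(s_hit)],
                        if (!is.na(prec_hit)) prec_hit))
  unexpl <- setdiff(seq_along(fl$mz), explained)

  structure(list(sequence = paste(labels, collapse = ""), labels = labels,
                 evidence = evidence, status = "unique", candidates = list(),
                 matched_peaks = matched,
                 unexplained_peaks = data.frame(mz = fl$mz[unexpl],
                                                intensity = fl$intensity[unexpl]),
                 diagnostics = c(diag, list(precursor_error = prec_err))),
            class = "read_result")
}

#' @export
print.read_result <- function(x, ...) {
  cat("<read_result> status: ", x$status, "\n", sep = "")
  if (x$status == "unique") {
    cat("  sequence: ", x$sequence, "\n  evidence: ",
        paste(x$evidence, collapse = " "), "\n", sep = "")
  } else if (x$status == "ambiguous") {
    cat("  partial:  ", paste(ifelse(is.na(x$labels), ".", x$labels),
                              collapse = ""), "\n", sep = "")
    for (k in names(x$candidates))
      cat("  position ", k, " candidates: ",
          paste(x$candidates[[k]], collapse = ", "), "\n", sep = "")
  } else {
    cat("  reason: ", x$diagnostics$reason, "\n", sep = "")
  }
  invisible(x)
}
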