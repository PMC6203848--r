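#' MS/MS peak lists
#'
#' An observed tandem-MS spectrum: m/z-intensity pairs plus the precursor m/z
#' selected for fragmentation, and optionally an instrument noise level used
#' for signal-to-noise filtering. Peaks are stored sorted by m/z.
#'
#' @param mz Numeric vector of m/z values (> 0, Da).
#' @param intensity Numeric vector of intensities (>= 0, arbitrary units).
#' @param precursor_mz Precursor m/z (Da).
#' @param noise_level Optional noise floor in intensity units; when absent,
#'   readers estimate it as the median peak intensity.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(mz, intensity, precursor_mz, noise_level = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop_data("`mz` and `intensity` must have the same length")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop_data("m/z values must be > 0")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_data("intensities must be >= 0")
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop_data("`precursor_mz` must be a single positive number")
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o],
                 precursor_mz = precursor_mz,
                 noise_level = noise_level),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", length(x$mz), " peak(s), precursor m/z ",
      format(x$precursor_mz),
      if (!is.null(x$noise_level)) paste0(", noise level ", format(x$noise_level)),
      "\n", sep = "")
  invisible(x)
}

#' Reader configuration
#'
#' Matching and acceptance rules for de novo sequence read-out: signals are
#' interpreted only if they match a theoretical mass within an absolute `m/z`
#' tolerance (default 0.02 Da) and exceed a signal-to-noise threshold
#' (default 5). A ppm tolerance mode is available for high-resolution
#' instruments.
#'
#' @param tolerance Mass-match tolerance, in Da (default) or ppm.
#' @param tolerance_unit `"da"` or `"ppm"`.
#' @param snr_min Minimum signal-to-noise ratio; peaks at or below it are
#'   discarded before matching.
#' @param require_both_anchors If `TRUE` (default), a read fails unless both
#'   the start-containing and the stop-containing fragment series contribute
#'   at least one matched peak.
#' @param max_missing_per_position Each sequence position is witnessed by up
#'   to two peaks (one per series); this many of them may be absent before
#'   the position is uncovered. Only the demonstrated value 1 is supported.
#' @return An object of class `reader_config`.
#' @export
reader_config <- function(tolerance = 0.02, tolerance_unit = c("da", "ppm"),
                          snr_min = 5, require_both_anchors = TRUE,
                          max_missing_per_position = 1L) {
  tolerance_unit <- match.arg(tolerance_unit)
  if (!is.numeric(tolerance) || tolerance <= 0) stop_config("tolerance must be > 0")
  if (!is.numeric(snr_min) || snr_min < 0) stop_config("snr_min must be >= 0")
  if (!identical(as.integer(max_missing_per_position), 1L))
    stop_config("only max_missing_per_position = 1 is supported")
  structure(list(tolerance = tolerance, tolerance_unit = tolerance_unit,
                 snr_min = snr_min,
                 require_both_anchors = isTRUE(require_both_anchors),
                 max_missing_per_position = 1L),
            class = "reader_config")
}

# effective absolute tolerance at a given m/z
.tol_at <- function(cfg, mz) {
  if (cfg$tolerance_unit == "ppm") mz * cfg$tolerance * 1e-6 else cfg$tolerance
}

#' Discard peaks below the signal-to-noise threshold
#'
#' Retains peaks with `intensity / noise_level > snr_min`. If the peak list
#' carries no noise level, the median peak intensity is used as the noise
#' floor and recorded on the result, which makes the operation idempotent.
#'
#' @param pl A [peak_list()].
#' @param cfg A [reader_config()].
#' @return A filtered [peak_list()] (possibly empty).
#' @export
filter_peaks <- function(pl, cfg = reader_config()) {
  stopifnot(inherits(pl, "peak_list"))
  noise <- pl$noise_level %||% stats::median(pl$intensity)
  keep <- if (cfg$snr_min == 0) rep(TRUE, length(pl$mz))
          else pl$intensity / noise > cfg$snr_min
  out <- pl
  out$mz <- pl$mz[keep]
  out$intensity <- pl$intensity[keep]
  out$noise_level <- noise
  out
}

# index of the nearest peak within tolerance of `target`, or NA
.match_peak <- function(mz_sorted, target, tol) {
  n <- length(mz_sorted)
  if (n == 0L) return(NA_integer_)
  i <- findInterval(target, mz_sorted)
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), n))
  d <- abs(mz_sorted[cand] - target)
  ok <- d <= tol
  if (!any(ok)) return(NA_integer_)
  cand[ok][which.min(d[ok])]
}

#' Write / read a peak list in Mascot generic format (MGF)
#'
#' A minimal MGF dialect: one `BEGIN IONS` block with `TITLE`, `PEPMASS`, an
#' optional `NOISELEVEL` extension carrying the simulator's noise floor, and
#' whitespace-separated m/z-intensity lines. `read_mgf()` reads the first
#' block of a file.
#'
#' @param pl A [peak_list()].
#' @param path File path.
#' @param title Optional spectrum title.
#' @return `write_mgf()` returns `path` invisibly; `read_mgf()` a
#'   [peak_list()].
#' @export
write_mgf <- function(pl, path, title = NULL) {
  stopifnot(inherits(pl, "peak_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("BEGIN IONS",
               if (!is.null(title)) paste0("TITLE=", title),
               sprintf("PEPMASS=%.6f", pl$precursor_mz),
               "CHARGE=1+",
               if (!is.null(pl$noise_level))
                 sprintf("NOISELEVEL=%.6f", pl$noise_level),
               sprintf("%.6f %.6f", pl$mz, pl$intensity),
               "END IONS"), con)
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  a <- match("BEGIN IONS", lines)
  b <- match("END IONS", lines)
  if (is.na(a) || is.na(b) || b <= a) stop_data("no BEGIN IONS block in ", path)
  body <- lines[(a + 1L):(b - 1L)]
  pep <- grep("^PEPMASS=", body, value = TRUE)
  if (!length(pep)) stop_data("MGF block lacks PEPMASS")
  precursor <- as.numeric(strsplit(sub("^PEPMASS=", "", pep[1L]), "[[:space:]]+")[[1L]][1L])
  noise <- grep("^NOISELEVEL=", body, value = TRUE)
  noise <- if (length(noise)) as.numeric(sub("^NOISELEVEL=", "", noise[1L])) else NULL
  pk <- body[!grepl("^[A-Z]+=", body) & nzchar(body)]
  mat <- if (length(pk))
    do.call(rbind, lapply(strsplit(pk, "[[:space:]]+"),
                          function(x) as.numeric(x[1:2])))
  else matrix(numeric(0), ncol = 2L)
  peak_list(mat[, 1L], mat[, 2L], precursor, noise)
}

#' Write / read a peak list as two-column CSV
#'
#' Columns `mz,intensity`. CSV carries no precursor, so `read_peaks_csv()`
#' requires it as an argument.
#'
#' @param pl A [peak_list()].
#' @param path File path.
#' @param precursor_mz Precursor m/z for the read spectrum.
#' @param noise_level Optional noise floor for the read spectrum.
#' @return `write_peaks_csv()` returns `path` invisibly; `read_peaks_csv()` a
#'   [peak_list()].
#' @export
write_peaks_csv <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  utils::write.csv(data.frame(mz = pl$mz, intensity = pl$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path, precursor_mz, noise_level = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop_data("peak CSV needs two columns (mz, intensity)")
  peak_list(df[[1L]], df[[2L]], precursor_mz, noise_level)
}
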