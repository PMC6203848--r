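#' Encoding configuration for indexed fragment collections
#'
#' Fixes how a digit stream is cut into short index-tagged oligomer fragments:
#' the chemical alphabet (whose coding blocks are the digits), the maximum
#' fragment length (`capacity`, the longest chain the synthesis platform can
#' make), the index field policy, the length-record policy and the padding
#' policy.
#'
#' The chunk size is constant: `capacity - w_max` payload digits per fragment,
#' where `w_max` is the digit width of the largest index. Under the
#' `"minimal"` index policy small indices are written with fewer digits, so
#' early fragments are shorter than `capacity`; under a fixed integer policy
#' every index is zero-padded to the same width. Because the payload size is
#' constant, a fragment's total length always reveals its index width, which
#' keeps decoding stateless and unambiguous.
#'
#' @param alphabet An [alphabet()] with at least 2 coding blocks; a spacer
#'   block is required when `pad = TRUE` or `length_record = "dedicated"`.
#' @param capacity Maximum flags per fragment (>= 2).
#' @param index_width `"minimal"` for minimal-width indices, or a positive
#'   integer for fixed-width indices.
#' @param index_radix Radix in which indices are written (2 .. base of the
#'   alphabet). Defaults to the alphabet base.
#' @param length_record `"dedicated"`: the bit-string length is written as its
#'   own fragment, marked by a leading spacer flag. `"residual"`: a
#'   single-flag fragment records only the offset of the bit length inside the
#'   short window of lengths compatible with the payload digit count (see
#'   [bit_length_window()]), which is always expressible in one digit.
#' @param pad If `TRUE`, the final chunk is right-padded to the full chunk
#'   size with the non-coding spacer flag.
#' @return An object of class `encoding_config`.
#' @seealso [reference_config()], [encode_bits()], [decode_manifest()]
#' @export
encoding_config <- function(alphabet, capacity = 6L, index_width = "minimal",
                            index_radix = NULL, length_record = c("dedicated", "residual"),
                            pad = TRUE) {
  if (!inherits(alphabet, "oligo_alphabet")) stop_config("`alphabet` must be an alphabet()")
  base <- alphabet_base(alphabet)
  if (base < 2L) stop_config("alphabet must have at least 2 coding blocks")
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 2L)
    stop_config("capacity must be an integer >= 2 (index + at least one payload flag)")
  length_record <- match.arg(length_record)
  index_radix <- as.integer(index_radix %||% base)
  if (is.na(index_radix) || index_radix < 2L || index_radix > base)
    stop_config("index_radix must lie in [2, alphabet base]")
  if (is.character(index_width)) {
    index_width <- match.arg(index_width, "minimal")
  } else {
    index_width <- as.integer(index_width)
    if (is.na(index_width) || index_width < 1L || index_width >= capacity)
      stop_config("fixed index_width must be an integer in [1, capacity - 1]")
  }
  spacer <- spacer_label(alphabet)
  if ((isTRUE(pad) || length_record == "dedicated") && is.na(spacer))
    stop_config("this configuration needs an alphabet with a spacer block")
  if (!isTRUE(pad) && !is.numeric(index_width))
    stop_config("an unpadded final fragment requires fixed-width indices; ",
                "with minimal-width indices a short fragment can alias a ",
                "smaller index and decoding would be ambiguous")
  structure(list(alphabet = alphabet, base = base, capacity = capacity,
                 index_width = index_width, index_radix = index_radix,
                 length_record = length_record, pad = isTRUE(pad),
                 spacer = spacer),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("<encoding_config> base ", x$base, ", capacity ", x$capacity,
      ", index ", if (is.character(x$index_width)) "minimal-width"
      else paste0("fixed width ", x$index_width),
      " radix ", x$index_radix,
      ", length record ", x$length_record,
      ", pad ", x$pad, "\n", sep = "")
  invisible(x)
}

#' The shipped reference configuration
#'
#' The calibrated configuration used for the QR-code scale demonstrations and
#' by the command-line `roundtrip` driver: a 15-letter alphabet `A`..`O` plus
#' spacer `*` ([toy_alphabet()]), fragment capacity 6, minimal-width radix-11
#' indices, spacer padding, and a single-flag residual length record. Under
#' this layout any 1089-bit input (a 33 x 33 bit matrix) becomes exactly 71
#' fragments: 1 monomer, 11 pentamers and 59 hexamers.
#'
#' @return An [encoding_config()].
#' @export
reference_config <- function() {
  encoding_config(toy_alphabet(15L), capacity = 6L, index_width = "minimal",
                  index_radix = 11L, length_record = "residual", pad = TRUE)
}

# ---- index arithmetic --------------------------------------------------------

.radix_width <- function(i, r) {
  w <- rep(1L, length(i))
  lim <- r
  while (any(i >= lim)) {
    w[i >= lim] <- w[i >= lim] + 1L
    lim <- lim * r
  }
  w
}

.int_to_digits <- function(i, r, width = NULL) {
  d <- integer(0)
  repeat {
    d <- c(i %% r, d)
    i <- i %/% r
    if (i == 0) break
  }
  if (!is.null(width)) {
    if (length(d) > width) stop_data("index does not fit in ", width, " digit(s)")
    d <- c(integer(width - length(d)), d)
  }
  as.integer(d)
}

.digits_to_int <- function(d, r) {
  out <- 0
  for (x in d) out <- out * r + x
  out
}

# chunk/index geometry for D payload digits under a config
.layout <- function(D, cfg) {
  r <- cfg$index_radix
  if (is.numeric(cfg$index_width)) {
    w <- cfg$index_width
    q <- cfg$capacity - w
    if (q < 1L) stop_config("capacity leaves no payload room")
    K <- ceiling(D / q)
    if (K > r^w)
      stop_data("capacity error: ", K, " fragments cannot be indexed with ",
                w, " radix-", r, " digit(s)")
  } else {
    w <- 1L
    repeat {
      q <- cfg$capacity - w
      if (q < 1L)
        stop_data("capacity error: index width exhausts the fragment capacity")
      K <- ceiling(D / q)
      wn <- .radix_width(K - 1L, r)
      if (wn == w) break
      w <- wn
    }
  }
  widths <- if (is.numeric(cfg$index_width)) rep(w, K) else .radix_width(0:(K - 1L), r)
  list(q = as.integer(q), K = as.integer(K), w_max = as.integer(w), widths = widths)
}

# ---- encode ------------------------------------------------------------------

#' Encode a bit string as a collection of indexed oligomer fragments
#'
#' The write path: the bit string is converted as one big integer into base-B
#' digits (B = number of coding blocks), the digit stream is cut into
#' constant-size chunks, each chunk is prefixed with its position index, the
#' final chunk is optionally padded with the non-coding spacer, and a length
#' record is appended so the exact bit count (including leading zeros) can be
#' restored. The result is an unordered collection: decoding does not depend
#' on fragment order or on duplicate observations.
#'
#' @param bits A string of `"0"`/`"1"` characters (or 0/1 vector), length >= 1.
#' @param cfg An [encoding_config()].
#' @return A `fragment_manifest`: a character vector of fragment sequences
#'   with the configuration echoed in its attributes.
#' @examples
#' cfg <- reference_config()
#' m <- encode_bits("10110001", cfg)
#' decode_manifest(m, cfg)
#' @export
encode_bits <- function(bits, cfg) {
  stopifnot(inherits(cfg, "encoding_config"))
  v <- .parse_bits(bits)
  n <- length(v)
  digits <- bits_to_digits(paste(v, collapse = ""), cfg$base)
  D <- length(digits)
  lay <- .layout(D, cfg)
  ab <- cfg$alphabet
  frags <- character(lay$K)
  for (i in seq_len(lay$K)) {
    idx <- digits_to_labels(
      .int_to_digits(i - 1L, cfg$index_radix,
                     width = if (is.numeric(cfg$index_width)) cfg$index_width),
      ab)
    chunk <- digits[(lay$q * (i - 1L) + 1L):min(lay$q * i, D)]
    payload <- digits_to_labels(chunk, ab)
    if (cfg$pad && length(payload) < lay$q)
      payload <- c(payload, rep(cfg$spacer, lay$q - length(payload)))
    frags[i] <- paste(c(idx, payload), collapse = "")
  }
  lenrec <- if (cfg$length_record == "dedicated") {
    paste(c(cfg$spacer, digits_to_labels(.int_to_digits(n, cfg$base), ab)),
          collapse = "")
  } else {
    res <- n - bit_length_window(D, cfg$base)[1L]
    paste(digits_to_labels(res, ab), collapse = "")
  }
  new_manifest(c(frags, lenrec), cfg)
}

# ---- decode ------------------------------------------------------------------

#' Decode a fragment collection back to the original bit string
#'
#' The read path, inverse of [encode_bits()]: exact duplicate sequences are
#' dereplicated, the length record is identified, each data fragment's index
#' is parsed, contiguity of the index range is verified, payloads are glued in
#' index order, trailing spacer flags are trimmed, and the digit stream is
#' converted back to exactly `n` bits. The input may be in any order and
#' contain any number of duplicate observations.
#'
#' @param manifest A `fragment_manifest` or plain character vector of
#'   fragment sequences.
#' @param cfg The [encoding_config()] the data were written with.
#' @return The decoded bit string.
#' @export
decode_manifest <- function(manifest, cfg) {
  stopifnot(inherits(cfg, "encoding_config"))
  seqs <- unique(as.character(manifest))
  if (length(seqs) == 0L) stop_data("empty manifest: no length record found")
  ab <- cfg$alphabet
  lab <- strsplit(seqs, "", fixed = TRUE)
  vals <- lapply(lab, labels_to_digits, ab = ab, what = "manifest fragment")

  is_len <- if (cfg$length_record == "dedicated") {
    vapply(lab, function(x) x[[1L]] == cfg$spacer, logical(1))
  } else {
    lengths(lab) == 1L
  }
  if (!any(is_len)) stop_data("no length record found in manifest")
  if (sum(is_len) > 1L)
    stop_data("conflicting length records: ",
              paste(seqs[is_len], collapse = ", "))
  len_digits <- vals[is_len][[1L]]
  data_vals <- vals[!is_len]
  data_seqs <- seqs[!is_len]
  K <- length(data_vals)
  if (K == 0L) stop_data("manifest has a length record but no data fragments")

  r <- cfg$index_radix
  w_max <- if (is.numeric(cfg$index_width)) cfg$index_width
           else .radix_width(K - 1L, r)
  q <- cfg$capacity - w_max
  if (q < 1L) stop_config("capacity leaves no payload room")

  idx <- numeric(K)
  pay_list <- vector("list", K)
  for (j in seq_len(K)) {
    d <- data_vals[[j]]
    w <- if (is.numeric(cfg$index_width)) cfg$index_width else length(d) - q
    if (w < 1L || length(d) - w < 1L)
      stop_data("fragment too short to carry an index and payload: ",
                data_seqs[j])
    if (length(d) - w > q || w > w_max)
      stop_data("fragment longer than the configured capacity allows: ",
                data_seqs[j])
    pay_list[[j]] <- d[(w + 1L):length(d)]
    id <- d[seq_len(w)]
    if (anyNA(id) || any(id >= r))
      stop_data("invalid index digits in fragment: ", data_seqs[j])
    value <- .digits_to_int(id, r)
    if (!is.numeric(cfg$index_width) && .radix_width(value, r) != w)
      stop_data("non-minimal index encoding in fragment: ", data_seqs[j])
    idx[j] <- value
  }

  dup <- unique(idx[duplicated(idx)])
  if (length(dup))
    stop_data("conflicting fragments share index(es): ",
              paste(sort(dup), collapse = ", "))
  expected <- 0:(K - 1L)
  gaps <- setdiff(expected, idx)
  if (length(gaps))
    stop_data("missing fragment index(es): ", paste(sort(gaps), collapse = ", "),
              if (any(idx >= K))
                paste0(" (and index(es) beyond the contiguous range: ",
                       paste(sort(idx[idx >= K]), collapse = ", "), ")"))

  ord <- order(idx)
  pay_list <- pay_list[ord]
  short <- which(lengths(pay_list) < q)
  if (length(short) && !identical(short, K))
    stop_data("only the final fragment may carry fewer than ", q,
              " payload flags")
  payload <- unlist(pay_list, use.names = FALSE)
  spacers <- is.na(payload)
  if (any(spacers)) {
    first_sp <- match(TRUE, spacers)
    if (!all(spacers[first_sp:length(payload)]))
      stop_data("spacer flags must form a single trailing run")
    payload <- payload[seq_len(first_sp - 1L)]
  }
  D <- length(payload)
  if (D == 0L) stop_data("manifest carries no payload digits")

  n <- if (cfg$length_record == "dedicated") {
    len_digits <- len_digits[-1L]  # drop the spacer marker
    if (length(len_digits) == 0L || anyNA(len_digits))
      stop_data("malformed dedicated length record")
    nn <- .digits_to_int(len_digits, cfg$base)
    if (digit_width(nn, cfg$base) != D)
      stop_data("corrupt manifest: length record says ", nn,
                " bits but the payload has ", D, " digits")
    nn
  } else {
    if (anyNA(len_digits)) stop_data("length record must be a coding flag")
    win <- bit_length_window(D, cfg$base)
    nn <- win[1L] + len_digits
    if (nn > win[2L])
      stop_data("corrupt manifest: length residual ", len_digits,
                " outside the window for ", D, " payload digits")
    nn
  }
  digits_to_bits(payload, cfg$base, n)
}

#' Fragment-length census of a manifest
#'
#' Counts fragments by chain length, e.g. `{1: 1, 5: 11, 6: 59}` for a
#' 1089-bit input under the [reference_config()].
#'
#' @param manifest A `fragment_manifest` or character vector of sequences.
#' @return A named integer vector: names are chain lengths, values counts.
#' @export
census <- function(manifest) {
  seqs <- as.character(manifest)
  if (length(seqs) == 0L) {
    out <- integer(0)
    names(out) <- character(0)
    return(out)
  }
  tab <- table(nchar(seqs))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
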