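# Bit-string ingestion: raw binary files, plain 0/1 text, and PBM (P1)
# bitmaps. A bit matrix (e.g. a QR-code pixel grid) carries no structure the
# codec cares about; matrices are flattened row-major, top-left first.

#' Read bits from a raw binary file
#'
#' Bytes are expanded to bits MSB-first, so the file round-trips exactly when
#' the bit count is recorded.
#'
#' @param path File path.
#' @return A string of `"0"`/`"1"` characters, 8 bits per input byte.
#' @export
file_to_bits <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) == 0L) stop_data("empty input file: ", path)
  m <- matrix(as.integer(rawToBits(raw)), nrow = 8L)  # rawToBits is LSB first
  paste(m[8:1, ], collapse = "")
}

#' Write bits to a raw binary file
#'
#' @param bits A string of `"0"`/`"1"` characters; the length must be a
#'   multiple of 8.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
bits_to_file <- function(bits, path) {
  v <- .parse_bits(bits)
  if (length(v) %% 8L != 0L)
    stop_data("bit count ", length(v), " is not a whole number of bytes")
  m <- matrix(v, nrow = 8L)
  writeBin(packBits(as.raw(m[8:1, ]), "raw"), path)
  invisible(path)
}

#' Flatten a bit matrix to a bit string (row-major)
#'
#' @param mat Integer/logical matrix of 0s and 1s.
#' @return A string of `nrow * ncol` bits, rows concatenated top to bottom.
#' @examples
#' bit_matrix_to_bits(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
#' @export
bit_matrix_to_bits <- function(mat) {
  if (!is.matrix(mat)) stop_data("expected a matrix")
  v <- as.integer(mat)
  if (any(is.na(v)) || any(!v %in% c(0L, 1L)))
    stop_data("bit matrix entries must be 0 or 1")
  paste(as.integer(t(mat)), collapse = "")
}

#' Restore a bit matrix from a flattened bit string
#'
#' @param bits A bit string of exactly `height * width` characters.
#' @param height,width Matrix dimensions.
#' @return An integer matrix.
#' @export
bits_to_bit_matrix <- function(bits, height, width) {
  v <- .parse_bits(bits)
  if (length(v) != height * width)
    stop_data("bit string has ", length(v), " bits, expected ",
              height * width, " for a ", height, "x", width, " matrix")
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' Read / write a plain PBM (P1) bitmap
#'
#' The portable bitmap text format: magic `P1`, optional `#` comments, width,
#' height, then whitespace-separated 0/1 pixels (1 = black).
#'
#' @param path File path.
#' @return `read_pbm()` returns an integer bit matrix; `write_pbm()` returns
#'   `path` invisibly.
#' @export
read_pbm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tok <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  tok <- tok[nzchar(tok)]
  if (length(tok) < 3L || tok[1L] != "P1")
    stop_data("not a P1 PBM file: ", path)
  w <- as.integer(tok[2L])
  h <- as.integer(tok[3L])
  px <- tok[-(1:3)]
  # pixels may be packed without separators ("0110..."); split them out
  px <- unlist(strsplit(px, "", fixed = TRUE))
  if (length(px) != w * h || any(!px %in% c("0", "1")))
    stop_data("PBM pixel data malformed: expected ", w * h, " bits")
  matrix(as.integer(px), nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pbm
#' @param mat Integer bit matrix to write.
#' @export
write_pbm <- function(mat, path) {
  if (!is.matrix(mat)) stop_data("expected a matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(mat), nrow(mat))), con)
  writeLines(apply(mat, 1L, paste, collapse = " "), con)
  invisible(path)
}
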