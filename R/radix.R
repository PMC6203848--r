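# Arbitrary-precision radix conversion between bit strings and base-B digit
# vectors. Values routinely exceed 2^53 (a QR code is >1000 bits), so the
# arithmetic is done on digit/limb vectors: bits are absorbed 16 at a time into
# a base-B digit vector, digits two at a time into a base-2^16 limb vector,
# with vectorised carry propagation. Both directions are exact for any length.

# propagate carries in a little-endian digit vector of the given base
.carry <- function(x, base) {
  repeat {
    q <- x %/% base
    if (!any(q != 0)) break
    x <- x - q * base
    n <- length(x)
    if (q[n] != 0) {
      x <- c(x, 0)
      q <- c(q, 0)
      n <- n + 1L
    }
    x[2:n] <- x[2:n] + q[1:(n - 1L)]
  }
  x
}

# integer bit vector (MSB first) -> little-endian base-`base` digit vector
.bits_to_bigdigits <- function(bits, base) {
  pad <- (-length(bits)) %% 16L
  m <- matrix(c(integer(pad), bits), nrow = 16L)
  limbs <- as.numeric(2^(15:0) %*% m)  # most significant limb first
  d <- 0
  for (lv in limbs) {
    d <- d * 65536
    d[1L] <- d[1L] + lv
    d <- .carry(d, base)
  }
  d
}

# base-`base` digit vector (MSB first) -> integer bit vector (MSB first,
# natural length; numeric(0) encodes the value zero)
.bigdigits_to_bits <- function(digits, base) {
  b2 <- base * base
  limbs <- 0
  i <- 1L
  nd <- length(digits)
  if (nd %% 2L == 1L) {
    limbs <- digits[1L]
    i <- 2L
  }
  while (i < nd) {
    limbs <- limbs * b2
    limbs[1L] <- limbs[1L] + digits[i] * base + digits[i + 1L]
    limbs <- .carry(limbs, 65536)
    i <- i + 2L
  }
  bits <- as.integer(vapply(rev(limbs),
                            function(v) bitwAnd(bitwShiftR(as.integer(v), 15:0), 1L),
                            integer(16L)))
  first <- match(1L, bits)
  if (is.na(first)) integer(0) else bits[first:length(bits)]
}

.bitlen <- function(limbs) {
  top <- limbs[length(limbs)]
  nb <- 0L
  while (top > 0) {
    top <- top %/% 2
    nb <- nb + 1L
  }
  16L * (length(limbs) - 1L) + nb
}

# exact log2 for powers of two, NA otherwise
.exact_log2 <- function(base) {
  k <- round(log2(base))
  if (2^k == base) k else NA_real_
}

#' Digit width of an n-bit payload in base B
#'
#' The smallest `D` with `B^D >= 2^n`: the number of base-`B` digits needed to
#' represent every `n`-bit value, and hence the fixed width to which converted
#' digit strings are zero-padded so that leading zero bits survive encoding.
#' Computed with exact big-integer arithmetic (no floating-point boundary
#' errors).
#'
#' @param n_bits Bit-string length (>= 1).
#' @param base Radix (>= 2).
#' @return Integer digit count `D`.
#' @examples
#' digit_width(4, 15)  # 2, since 15 < 2^4 <= 15^2
#' @export
digit_width <- function(n_bits, base) {
  n_bits <- as.numeric(n_bits)
  if (n_bits < 1) stop_data("bit-string length must be >= 1")
  if (base < 2) stop_config("base must be >= 2")
  k <- .exact_log2(base)
  if (!is.na(k)) return(as.integer(ceiling(n_bits / k)))
  limbs <- 1
  D <- 0L
  repeat {
    D <- D + 1L
    limbs <- .carry(limbs * base, 65536)
    if (.bitlen(limbs) >= n_bits + 1) return(D)
  }
}

#' Range of bit lengths sharing one digit width
#'
#' All bit lengths `n` with `digit_width(n, base) == D` form a short contiguous
#' window of at most `ceiling(log2(base))` values. This is what makes a
#' single-digit "residual" length record possible: the payload width `D` is
#' visible in a decoded manifest, and one extra digit pins `n` inside the
#' window exactly.
#'
#' @param D Digit width (>= 1).
#' @param base Radix (>= 2).
#' @return Integer vector `c(n_min, n_max)`.
#' @export
bit_length_window <- function(D, base) {
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop_data("digit width must be >= 1")
  k <- .exact_log2(base)
  if (!is.na(k)) return(as.integer(c((D - 1) * k + 1, D * k)))
  limbs <- 1
  for (i in seq_len(D - 1L)) limbs <- .carry(limbs * base, 65536)
  n_min <- .bitlen(limbs)           # bitlength of base^(D-1)
  limbs <- .carry(limbs * base, 65536)
  c(n_min, .bitlen(limbs) - 1L)     # bitlength of base^D, minus one
}

# validate a bit string and return an integer 0/1 vector (MSB first)
.parse_bits <- function(bits) {
  if (is.numeric(bits)) bits <- paste(as.integer(bits), collapse = "")
  if (!is.character(bits) || length(bits) != 1L)
    stop_data("bits must be a single string of 0/1 characters")
  v <- strsplit(bits, "", fixed = TRUE)[[1L]]
  if (length(v) == 0L) stop_data("bit string must have length >= 1")
  bad <- !(v %in% c("0", "1"))
  if (any(bad))
    stop_data("non-bit character(s) in bit string: ",
              paste(unique(v[bad]), collapse = ", "))
  as.integer(v)
}

#' Convert a bit string to fixed-width base-B digits
#'
#' Interprets the bits MSB-first as one big integer `v` and returns its base-B
#' representation, left-padded with zero digits to width [digit_width()] so
#' that leading zero bits are preserved (given the recorded length `n`). This
#' is one global conversion of the whole bit string, not a per-block recoding.
#'
#' @param bits A string of `"0"`/`"1"` characters (or a 0/1 vector).
#' @param base Radix `B >= 2`.
#' @return Integer vector of digits in `[0, B)`, MSB first, length
#'   `digit_width(nchar(bits), base)`.
#' @examples
#' bits_to_digits("1011", 15)  # c(0, 11)
#' @export
bits_to_digits <- function(bits, base) {
  v <- .parse_bits(bits)
  if (base < 2) stop_config("base must be >= 2")
  D <- digit_width(length(v), base)
  d <- rev(.bits_to_bigdigits(v, base))
  first_nz <- match(TRUE, d != 0)
  d <- if (is.na(first_nz)) numeric(0) else d[first_nz:length(d)]
  as.integer(c(integer(D - length(d)), d))
}

#' Convert base-B digits back to a bit string of known length
#'
#' Exact inverse of [bits_to_digits()] for the recorded bit length `n`. If the
#' digit value needs more than `n` bits the payload is inconsistent with the
#' length record and a corruption error is raised.
#'
#' @param digits Integer vector of base-`base` digits, MSB first.
#' @param base Radix `B >= 2`.
#' @param n_bits The original bit-string length `n`.
#' @return A string of `n_bits` `"0"`/`"1"` characters.
#' @examples
#' digits_to_bits(c(0, 11), 15, 4)  # "1011"
#' @export
digits_to_bits <- function(digits, base, n_bits) {
  digits <- as.numeric(digits)
  if (base < 2) stop_config("base must be >= 2")
  n_bits <- as.numeric(n_bits)
  if (length(digits) == 0L) stop_data("empty digit vector")
  if (any(!is.finite(digits)) || any(digits < 0) || any(digits >= base) ||
      any(digits != floor(digits)))
    stop_data("digits must be integers in [0, base)")
  bits <- .bigdigits_to_bits(digits, base)
  if (length(bits) > n_bits)
    stop_data("corrupt payload: digit value needs ", length(bits),
              " bits but the length record says ", n_bits)
  paste(c(integer(n_bits - length(bits)), bits), collapse = "")
}

#' Size of the sequence space
#'
#' The number of distinct sequence-defined oligomers of length `L` over `B`
#' building blocks: `B^L`, the capacity argument for storing data in short
#' chains (e.g. 20 blocks give 8000 trimers but 2.56e10 octamers).
#'
#' @param base Number of distinct building blocks `B >= 1`.
#' @param length Chain length `L >= 0`.
#' @return `B^L` as an exactly represented number. Values beyond 2^53 cannot
#'   be held exactly in a double and raise an error.
#' @examples
#' sequence_space_size(20, 3)  # 8000
#' sequence_space_size(2, 5)   # 32
#' @export
sequence_space_size <- function(base, length) {
  stopifnot(base >= 1, length >= 0)
  out <- 1
  for (i in seq_len(length)) {
    out <- out * base
    if (out > 2^53)
      stop_data("B^L exceeds 2^53 and is no longer exactly representable")
  }
  out
}
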