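# The binary codec: cutting a digit stream into indexed fragments and gluing
# it back together.

test_that("data fragment count follows the capacity arithmetic", {
  ab <- toy_alphabet(15)
  # fixed 1-digit indices, capacity 6: chunks of 5 digits; a 43-bit payload
  # has 12 base-15 digits, so 3 data fragments plus the dedicated length record
  cfg <- encoding_config(ab, 6, index_width = 1L, length_record = "dedicated")
  bits <- random_bits(43, seed = 7)
  expect_identical(digit_width(43, 15), 12L)
  m <- encode_bits(bits, cfg)
  expect_length(m, 4L)
  expect_identical(decode_manifest(m, cfg), bits)
  # the last data fragment is spacer-padded to full capacity
  expect_true(all(nchar(as.character(m)[1:3]) == 6L))

  set.seed(301)
  for (i in 1:30) {
    B <- sample(4:30, 1)
    C <- sample(4:8, 1)
    w <- sample(1:2, 1)
    n <- sample(1:150, 1)
    cfg <- encoding_config(toy_alphabet(B), C, index_width = w,
                           length_record = "residual")
    m <- tryCatch(encode_bits(rand_bit_string(n), cfg), error = function(e) e)
    D <- digit_width(n, B)
    K <- ceiling(D / (C - w))
    if (inherits(m, "error")) {
      expect_match(conditionMessage(m), "capacity")
      expect_gt(K, B^w)
    } else {
      expect_length(m, K + 1L)  # + the length record
    }
  }
})

test_that("decoding inverts encoding for random payloads and configurations", {
  set.seed(302)
  for (i in 1:60) {
    B <- sample(2:30, 1)
    C <- sample(3:8, 1)
    iw <- if (runif(1) < 0.5) "minimal" else sample(seq_len(max(1, C - 2)), 1)
    pad <- if (is.numeric(iw)) runif(1) < 0.7 else TRUE
    cfg <- encoding_config(toy_alphabet(B), C, iw,
                           length_record = sample(c("dedicated", "residual"), 1),
                           pad = pad)
    bits <- rand_bit_string(sample(1:400, 1))
    m <- tryCatch(encode_bits(bits, cfg), error = function(e) e)
    if (inherits(m, "error")) {
      expect_match(conditionMessage(m), "capacity")
      next
    }
    # decode must not care about order or duplicate observations
    shuffled <- sample(rep(as.character(m), sample(1:3, 1)))
    expect_identical(decode_manifest(shuffled, cfg), bits)
  }
})

test_that("encoding is deterministic", {
  cfg <- reference_config()
  bits <- random_bits(777, seed = 5)
  expect_identical(as.character(encode_bits(bits, cfg)),
                   as.character(encode_bits(bits, cfg)))
})

test_that("decode failures are specific and name the culprit", {
  cfg <- reference_config()
  bits <- random_bits(300, seed = 9)
  m <- as.character(encode_bits(bits, cfg))
  data_frags <- m[nchar(m) > 1L]

  # deleting one data fragment names exactly the missing index
  victim <- data_frags[6]  # index 5: one-digit index, no width change
  expect_error(decode_manifest(setdiff(m, victim), cfg),
               "missing fragment index\\(es\\): 5")

  # a second, different fragment with the same index is a conflict
  tampered <- sub(".$", if (endsWith(victim, "A")) "B" else "A", victim)
  expect_error(decode_manifest(c(m, tampered), cfg), "conflict")

  # no length record
  monomer <- m[nchar(m) == 1L]
  expect_error(decode_manifest(setdiff(m, monomer), cfg), "length record")
  expect_error(decode_manifest(character(0), cfg), "empty manifest")

  # unknown labels are named
  expect_error(decode_manifest(c(m, "A?????"), cfg), "\\?")
})

test_that("a payload inconsistent with its length record is caught", {
  ab <- toy_alphabet(15)
  cfg <- encoding_config(ab, 6, index_width = 1L, length_record = "dedicated")
  # digits [1, 1] = 16 in base 15, but the length record claims 4 bits
  expect_error(decode_manifest(c("ABB***", "*E"), cfg), "corrupt")
  # residual outside the bit-length window for the payload width
  cfg2 <- encoding_config(ab, 6, index_width = 1L, length_record = "residual")
  m2 <- as.character(encode_bits(random_bits(16, seed = 1), cfg2))
  m2[nchar(m2) == 1L] <- "O"  # residual 14 is far outside any window
  expect_error(decode_manifest(m2, cfg2), "residual")
})

test_that("longer chains or larger alphabets never need more fragments", {
  set.seed(303)
  bits <- rand_bit_string(200)
  bases <- c(2, 4, 8, 15, 30)
  caps <- 3:8
  counts <- matrix(NA_integer_, length(bases), length(caps))
  for (i in seq_along(bases)) {
    for (j in seq_along(caps)) {
      cfg <- encoding_config(toy_alphabet(bases[i]), caps[j], "minimal",
                             length_record = "residual")
      counts[i, j] <- tryCatch(length(encode_bits(bits, cfg)),
                               error = function(e) NA_integer_)
    }
  }
  mono_dec <- function(x) all(diff(x[!is.na(x)]) <= 0)
  expect_true(all(apply(counts, 1L, mono_dec)))  # capacity up, count down
  expect_true(all(apply(counts, 2L, mono_dec)))  # alphabet up, count down
})

test_that("the census is a function of payload length only", {
  cfg <- reference_config()
  zeros <- strrep("0", 500)
  c1 <- census(encode_bits(zeros, cfg))
  c2 <- census(encode_bits(random_bits(500, seed = 4), cfg))
  expect_identical(c1, c2)
  expect_identical(census("ABC"), c(`3` = 1L))
  expect_identical(census(character(0)), structure(integer(0), names = character(0)))
})
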