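# Synthetic spectrum generator and random payload generators.

test_that("a clean channel emits exactly the ladder peaks plus the precursor", {
  s <- "ABBA"
  lad <- fragment_ladders(s, toy_mm, ab15)
  pl <- simulate_spectrum(s, ab15, toy_mm)
  expect_setequal(pl$mz, c(lad$prefix, lad$suffix, lad$precursor))
  expect_equal(pl$precursor_mz, lad$precursor)
  expect_true(all(pl$intensity == 1000))

  # explicit deletion removes exactly the requested m/z
  pl2 <- simulate_spectrum(s, ab15, toy_mm, sim_config(drop = "p1"))
  expect_setequal(setdiff(pl$mz, pl2$mz), lad$prefix[1L])
})

test_that("simulation is deterministic under a seed, down to the MGF bytes", {
  cfgs <- sim_config(dropout = 0.2, n_noise_peaks = 25, jitter = 0.01, seed = 42)
  a <- simulate_spectrum("ACME", ab15, toy_mm, cfgs)
  b <- simulate_spectrum("ACME", ab15, toy_mm, cfgs)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".mgf")
  fb <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(a, fa, title = "ACME")
  write_mgf(b, fb, title = "ACME")
  expect_identical(readLines(fa), readLines(fb))
  # and the simulator does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); simulate_spectrum("ACME", ab15, toy_mm, cfgs); y <- runif(1)
  expect_identical(x, y)
})

test_that("generated alphabets follow the labelling and spacing conventions", {
  ab <- toy_alphabet(15, 5, 100)
  expect_identical(ab$label, c(LETTERS[1:15], "*"))
  expect_equal(ab$unit_mass[1:15], seq(100, 170, by = 5))
  expect_gt(alphabet_min_gap(ab), 0.04)
  abj <- toy_alphabet(10, 5, 100, jitter = 0.5, seed = 3)
  expect_gt(alphabet_min_gap(abj), 0.04)
  expect_identical(toy_alphabet(10, jitter = 0.5, seed = 3), abj)
})

test_that("random payload generators are reproducible and sized correctly", {
  expect_identical(random_bits(40, seed = 9), random_bits(40, seed = 9))
  expect_true(random_bits(1, seed = 1) %in% c("0", "1"))
  m <- random_matrix(33, 33, seed = 2)
  expect_identical(dim(m), c(33L, 33L))
  expect_identical(nchar(bit_matrix_to_bits(m)), 1089L)
  expect_identical(m, random_matrix(33, 33, seed = 2))
})

test_that("a two-block alphabet supports the whole channel end to end", {
  ab2 <- toy_alphabet(2)
  cfg <- encoding_config(ab2, capacity = 8, index_width = 4L,
                         length_record = "residual")
  bits <- random_bits(48, seed = 13)
  m <- as.character(encode_bits(bits, cfg))
  reads <- vapply(seq_along(m), function(i) {
    pl <- simulate_spectrum(m[i], ab2, toy_mm, sim_config(seed = 700 + i))
    read_sequence(pl, ab2, toy_mm, L = nchar(m[i]))$sequence
  }, character(1))
  expect_identical(decode_manifest(reads, cfg), bits)
})
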