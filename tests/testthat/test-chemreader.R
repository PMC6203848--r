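# De novo sequence read-out from MS/MS peak lists.

rc <- reader_config()

test_that("signal-to-noise filtering keeps interpretable peaks and is idempotent", {
  pl <- peak_list(c(500, 510), c(600, 40), precursor_mz = 900, noise_level = 100)
  f1 <- filter_peaks(pl, rc)
  expect_equal(f1$mz, 500)
  expect_equal(filter_peaks(pl, reader_config(snr_min = 0))$mz, pl$mz)
  expect_identical(filter_peaks(f1, rc)[c("mz", "intensity")],
                   f1[c("mz", "intensity")])
  # without a noise level the median intensity is the floor, and it is
  # recorded so that refiltering cannot shift it
  pl2 <- peak_list(1:5 * 100, c(1, 1, 1, 100, 100), precursor_mz = 900)
  f2 <- filter_peaks(pl2, rc)
  expect_equal(f2$noise_level, 1)
  expect_equal(f2$mz, c(400, 500))
  expect_identical(filter_peaks(f2, rc)$mz, f2$mz)
})

test_that("anchor search finds the terminal fragments with their labels", {
  s <- "ACMED"
  pl <- filter_peaks(simulate_spectrum(s, ab15, toy_mm), rc)
  an <- anchor_search(pl, ab15, toy_mm, rc)
  expect_identical(nrow(an$left), 1L)
  expect_identical(nrow(an$right), 1L)
  expect_identical(an$left$labels[[1L]], "A")   # first position
  expect_identical(an$right$labels[[1L]], "D")  # last position

  # smallest left fragment deleted: left side empty, right side intact
  pl2 <- filter_peaks(simulate_spectrum(s, ab15, toy_mm, sim_config(drop = "p1")), rc)
  an2 <- anchor_search(pl2, ab15, toy_mm, rc, strict = FALSE)
  expect_identical(nrow(an2$left), 0L)
  expect_identical(nrow(an2$right), 1L)
  expect_error(anchor_search(pl2, ab15, toy_mm, rc),
               class = "oligostore_anchor_error")
})

test_that("near-isobaric blocks yield multi-label anchors, not silent choices", {
  close_ab <- alphabet(c("A", "B", "C"), c(100, 100.015, 130))
  pl <- simulate_spectrum("AC", close_ab, toy_mm)
  expect_warning(an <- anchor_search(filter_peaks(pl, rc), close_ab, toy_mm, rc),
                 "ambiguous")
  expect_setequal(an$left$labels[[1L]], c("A", "B"))
})

test_that("ladder walks assign what their series supports and halt at gaps", {
  s <- "ABCDEF"
  pl <- filter_peaks(simulate_spectrum(s, ab15, toy_mm), rc)
  lw <- ladder_walk(pl, NULL, "left", 6, ab15, toy_mm, rc)
  expect_identical(paste(lw$assignment, collapse = ""), s)
  expect_true(is.na(lw$gap_at))
  expect_identical(lw$n_lookups, 6L * 16L)  # L positions x 16 blocks

  # interior prefix peak missing: left walk stops, right walk covers it all
  pl2 <- filter_peaks(simulate_spectrum(s, ab15, toy_mm, sim_config(drop = "p3")), rc)
  lw2 <- ladder_walk(pl2, NULL, "left", 6, ab15, toy_mm, rc)
  rw2 <- ladder_walk(pl2, NULL, "right", 6, ab15, toy_mm, rc)
  expect_identical(lw2$gap_at, 3L)
  expect_identical(lw2$assignment[1:2], c("A", "B"))
  expect_identical(paste(rw2$assignment, collapse = ""), s)
})

test_that("clean spectra give unique, correct reads with two-sided evidence", {
  set.seed(601)
  for (i in 1:50) {
    L <- sample(1:8, 1)
    s <- rand_seq(L, ab15$label)  # spacer-containing chains read like any other
    rr <- read_sequence(simulate_spectrum(s, ab15, toy_mm), ab15, toy_mm, L)
    expect_identical(rr$status, "unique")
    expect_identical(rr$sequence, s)
    expect_true(all(rr$evidence == "both"))
  }
})

test_that("deleting any single ladder peak never changes an octamer read", {
  s <- "AHOBLCMN"
  for (d in c(paste0("p", 1:8), paste0("s", 1:8))) {
    rr <- read_sequence(simulate_spectrum(s, ab15, toy_mm, sim_config(drop = d)),
                        ab15, toy_mm, 8)
    expect_identical(rr$status, "unique")
    expect_identical(rr$sequence, s)
  }
  # the smallest-fragment case specifically: one anchor absent, both series
  # still represented deeper in the ladder
  rr <- read_sequence(simulate_spectrum(s, ab15, toy_mm, sim_config(drop = "p1")),
                      ab15, toy_mm, 8)
  expect_identical(rr$sequence, s)
  expect_identical(rr$evidence[1L], "right")
})

test_that("equal-composition hexamers with different order read distinctly", {
  for (s in c("ABBABA", "BABAAB")) {
    rr <- read_sequence(simulate_spectrum(s, ab15, toy_mm), ab15, toy_mm, 6)
    expect_identical(rr$status, "unique")
    expect_identical(rr$sequence, s)
  }
})

test_that("sub-threshold noise never changes a read result", {
  set.seed(602)
  for (i in 1:20) {
    L <- sample(3:8, 1)
    s <- rand_seq(L)
    clean <- read_sequence(simulate_spectrum(s, ab15, toy_mm), ab15, toy_mm, L)
    noisy <- read_sequence(
      simulate_spectrum(s, ab15, toy_mm, sim_config(n_noise_peaks = 60, seed = i)),
      ab15, toy_mm, L)
    expect_identical(noisy$sequence, clean$sequence)
    expect_identical(noisy$evidence, clean$evidence)
    expect_identical(noisy$status, "unique")
  }
})

test_that("reads stay exact under jitter up to half the tolerance", {
  set.seed(603)
  for (i in 1:20) {
    L <- sample(3:8, 1)
    s <- rand_seq(L)
    pl <- simulate_spectrum(s, ab15, toy_mm, sim_config(jitter = 0.01, seed = i))
    rr <- read_sequence(pl, ab15, toy_mm, L)
    expect_identical(rr$status, "unique")
    expect_identical(rr$sequence, s)
  }
})

test_that("failure and ambiguity modes are reported, not papered over", {
  s <- "ABCDEF"
  # entire prefix series missing: the right walk reads everything, but the
  # both-anchors policy rejects the spectrum and names the side
  pl <- simulate_spectrum(s, ab15, toy_mm, sim_config(drop = paste0("p", 1:6)))
  rr <- read_sequence(pl, ab15, toy_mm, 6)
  expect_identical(rr$status, "failed")
  expect_identical(rr$diagnostics$reason, "anchor_missing")
  expect_identical(rr$diagnostics$side, "left")
  relaxed <- read_sequence(pl, ab15, toy_mm, 6,
                           reader_config(require_both_anchors = FALSE))
  expect_identical(relaxed$sequence, s)
  expect_true(all(relaxed$evidence == "right"))

  # precursor inconsistent with the reconstruction
  pl2 <- simulate_spectrum(s, ab15, toy_mm)
  pl2$precursor_mz <- pl2$precursor_mz + 5
  rr2 <- read_sequence(pl2, ab15, toy_mm, 6)
  expect_identical(rr2$status, "failed")
  expect_identical(rr2$diagnostics$reason, "precursor_mismatch")

  # the same rung missing from both series: ambiguous with candidates from
  # complementary-mass inference
  pl3 <- simulate_spectrum(s, ab15, toy_mm, sim_config(drop = c("p3", "s4")))
  rr3 <- read_sequence(pl3, ab15, toy_mm, 6)
  expect_identical(rr3$status, "ambiguous")
  expect_identical(rr3$candidates[["3"]], "C")
  expect_identical(rr3$labels[3L], NA_character_)

  # near-isobaric blocks: ambiguity surfaces in the status
  close_ab <- alphabet(c("A", "B", "C"), c(100, 100.015, 130))
  pl4 <- simulate_spectrum("CAC", close_ab, toy_mm)
  rr4 <- suppressWarnings(read_sequence(pl4, close_ab, toy_mm, 3))
  expect_false(identical(rr4$status, "unique"))
})

test_that("read-out cost grows linearly in the chain length", {
  set.seed(604)
  lookups <- vapply(c(8L, 64L), function(L) {
    s <- rand_seq(L)
    rr <- read_sequence(simulate_spectrum(s, ab15, toy_mm), ab15, toy_mm, L)
    expect_identical(rr$status, "unique")
    rr$diagnostics$n_lookups
  }, integer(1))
  expect_identical(lookups[2L], 8L * lookups[1L])
  t0 <- proc.time()[["elapsed"]]
  for (i in 1:5) {
    s <- rand_seq(64L)
    read_sequence(simulate_spectrum(s, ab15, toy_mm), ab15, toy_mm, 64L)
  }
  expect_lt(proc.time()[["elapsed"]] - t0, 5)
})
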