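# Mass arithmetic: precursor masses and the prefix/suffix fragment ladders.

test_that("oligomer mass sums end groups, unit masses and adduct", {
  ab <- tiny_alphabet()
  m <- tiny_model()
  expect_equal(oligomer_mass("AB", m, ab), 180)
  expect_equal(oligomer_mass("BA", m, ab), 180)  # composition, not order
  expect_error(oligomer_mass("", m, ab), "empty sequence")
  expect_equal(oligomer_mass("", m, ab, allow_empty = TRUE), 150)
  expect_error(oligomer_mass("AXB", m, ab), "X")

  m2 <- mass_model(100, 50, adduct_mass = 0, charge = 2L)
  expect_equal(oligomer_mass("AB", m2, ab), 90)

  # permutation invariance on random sequences
  set.seed(101)
  for (i in 1:25) {
    s <- strsplit(rand_seq(sample(2:8, 1)), "")[[1L]]
    expect_equal(oligomer_mass(s, toy_mm, ab15),
                 oligomer_mass(sample(s), toy_mm, ab15))
  }
})

test_that("fragment ladders read the sequence forwards and backwards", {
  ab <- tiny_alphabet()
  m <- tiny_model()
  lad <- fragment_ladders("AB", m, ab)
  expect_equal(lad$prefix, c(111, 131))
  expect_equal(lad$suffix, c(72, 82))
  expect_equal(lad$precursor, 180)

  one <- fragment_ladders("A", m, ab)
  expect_equal(one$prefix, 100 + 10 + 1)
  expect_equal(one$suffix, 10 + 50 + 2)

  set.seed(102)
  for (i in 1:25) {
    L <- sample(2:9, 1)
    s <- rand_seq(L)
    u <- ab15$unit_mass[match(strsplit(s, "")[[1L]], ab15$label)]
    lad <- fragment_ladders(s, toy_mm, ab15)
    # successive differences spell the unit masses, in order and reversed
    expect_equal(diff(lad$prefix), u[-1L])
    expect_equal(diff(lad$suffix), rev(u)[-1L])
    expect_true(all(diff(lad$prefix) > 0), info = "prefix strictly increasing")
    expect_true(all(diff(lad$suffix) > 0))
  }
})

test_that("complementary fragments sum to a cleavage-independent constant", {
  set.seed(103)
  for (i in 1:25) {
    model <- mass_model(runif(1, 20, 200), runif(1, 20, 200),
                        runif(1, -5, 5), runif(1, -5, 5),
                        adduct_mass = runif(1, 0, 30))
    L <- sample(2:9, 1)
    s <- rand_seq(L)
    lad <- fragment_ladders(s, model, ab15)
    expected <- model$delta_left + model$delta_right + model$adduct_mass +
      lad$precursor * model$charge
    sums <- lad$prefix[1:(L - 1)] + lad$suffix[(L - 1):1]
    expect_true(all(abs(sums - expected) < 1e-9))
  }
})

test_that("ladders are order-sensitive even when the precursor mass is not", {
  a <- fragment_ladders("ABBABA", toy_mm, ab15)
  b <- fragment_ladders("BABAAB", toy_mm, ab15)
  expect_equal(a$precursor, b$precursor)
  expect_false(isTRUE(all.equal(a$prefix, b$prefix)))
})

test_that("alphabet construction enforces its invariants", {
  expect_error(alphabet(c("A", "A"), c(1, 2)), "duplicate")
  expect_error(alphabet(c("A", "B"), c(1, -2)), "> 0")
  expect_error(alphabet(c("A", "B"), c(5, 5)), "distinct")
  expect_error(alphabet("AB", 10), "single characters")
  expect_error(toy_alphabet(15, spacing = 0.03), "too small")
  expect_equal(alphabet_base(ab15), 15L)
  expect_equal(spacer_label(ab15), "*")
  expect_gt(alphabet_min_gap(ab15), 0.04)
})

test_that("alphabet TSV and mass-model config files round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alphabet_tsv(ab15, f)
  back <- read_alphabet_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(ab15))

  g <- withr::local_tempfile(fileext = ".cfg")
  write_mass_model(toy_mm, g)
  expect_equal(read_mass_model(g), toy_mm)
  writeLines("alpha_mass: 1", g)
  expect_error(read_mass_model(g), "lacks field")
})
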