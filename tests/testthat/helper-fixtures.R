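# Shared fixtures. Everything is built in code; no stored data.

# two-block alphabet and a hand-computable mass model: all expected masses in
# the unit tests can be summed on paper
tiny_alphabet <- function() alphabet(c("A", "B"), c(10, 20))
tiny_model <- function() mass_model(100, 50, delta_left = 1, delta_right = 2,
                                    adduct_mass = 0)

# the 15-block alphabet and off-lattice toy model used for simulated read-out
ab15 <- toy_alphabet(15)
toy_mm <- toy_mass_model()

coding15 <- ab15$label[ab15$role == "coding"]

rand_seq <- function(L, labels = coding15) {
  paste(sample(labels, L, replace = TRUE), collapse = "")
}

rand_bit_string <- function(n) paste(sample(0:1, n, replace = TRUE), collapse = "")

# independent double-precision base-conversion oracle; exact for n <= 50 bits
oracle_digits <- function(bits, base) {
  bv <- as.integer(strsplit(bits, "", fixed = TRUE)[[1L]])
  stopifnot(length(bv) <= 50L)
  v <- sum(bv * 2^((length(bv) - 1L):0))
  D <- 0L
  cap <- 1
  while (cap < 2^length(bv)) {
    cap <- cap * base
    D <- D + 1L
  }
  d <- integer(D)
  for (i in D:1) {
    d[i] <- v %% base
    v <- v %/% base
  }
  as.integer(d)
}

# every-word sentence of the text-codec demonstrations
sentence_words <- c("TO", "WRITE", "OR", "NOT", "TO", "WRITE", "ON", "OLIGOS?")
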