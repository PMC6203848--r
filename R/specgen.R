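# Synthetic MS/MS spectrum generator: the test harness standing in for
# instrument data. Emulates the qualitative structure of MALDI-MS/MS spectra
# of sequence-defined oligomers -- complete or partially missing prefix/suffix
# fragment ladders from backbone cleavage, a precursor peak, random noise
# peaks and bounded m/z jitter -- with schematic constant intensities, since
# the reader uses intensity only through signal-to-noise.

#' Simulation configuration
#'
#' @param dropout Probability that each true ladder peak is independently
#'   omitted (the precursor peak is never dropped).
#' @param drop Explicit deletions instead of / in addition to random dropout:
#'   a character vector like `c("p1", "s3")` (prefix fragment 1, suffix
#'   fragment 3).
#' @param n_noise_peaks Number of random noise peaks to add.
#' @param noise_intensity_range Intensity range for noise peaks; the default
#'   `c(0.5, 4.5) * noise_level` keeps them below the default
#'   signal-to-noise threshold of 5. Set a higher range for adversarial
#'   (above-threshold) noise.
#' @param jitter Maximum absolute m/z perturbation per peak (Da, uniform).
#' @param signal_intensity Constant intensity of true peaks.
#' @param noise_level The noise floor reported with the spectrum.
#' @param seed Optional integer seed; identical seeds give identical spectra.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dropout = 0, drop = NULL, n_noise_peaks = 0L,
                       noise_intensity_range = NULL, jitter = 0,
                       signal_intensity = 1000, noise_level = 10,
                       seed = NULL) {
  if (dropout < 0 || dropout > 1) stop_config("dropout must be in [0, 1]")
  if (jitter < 0) stop_config("jitter must be >= 0")
  if (!is.null(drop) && !all(grepl("^[ps][0-9]+$", drop)))
    stop_config("explicit drops must look like \"p1\", \"s3\", ...")
  structure(list(dropout = dropout, drop = drop,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_range = noise_intensity_range %||%
                   (c(0.5, 4.5) * noise_level),
                 jitter = jitter, signal_intensity = signal_intensity,
                 noise_level = noise_level, seed = seed),
            class = "sim_config")
}

#' Simulate the MS/MS spectrum of one oligomer
#'
#' Emits the surviving prefix/suffix ladder peaks of [fragment_ladders()] plus
#' the precursor peak, each perturbed uniformly within `±jitter`, and adds
#' `n_noise_peaks` noise peaks at uniform random m/z within the spectrum
#' span. Deterministic under a fixed seed.
#'
#' @param seq Oligomer sequence (string or label vector).
#' @param alphabet An [alphabet()].
#' @param model A [mass_model()].
#' @param sim A [sim_config()].
#' @return A [peak_list()] with the simulated precursor m/z and noise level.
#' @examples
#' pl <- simulate_spectrum("ABBA", toy_alphabet(15), toy_mass_model(),
#'                         sim_config(seed = 1))
#' @export
simulate_spectrum <- function(seq, alphabet, model, sim = sim_config()) {
  stopifnot(inherits(sim, "sim_config"))
  lad <- fragment_ladders(seq, model, alphabet)
  L <- length(lad$labels)
  id <- c(paste0("p", seq_len(L)), paste0("s", seq_len(L)))
  mz <- c(lad$prefix, lad$suffix)
  with_local_seed(sim$seed, {
    keep <- !(id %in% sim$drop)
    if (sim$dropout > 0)
      keep <- keep & (stats::runif(2L * L) >= sim$dropout)
    mz <- c(mz[keep], lad$precursor)
    if (sim$jitter > 0)
      mz <- mz + stats::runif(length(mz), -sim$jitter, sim$jitter)
    intensity <- rep(sim$signal_intensity, length(mz))
    if (sim$n_noise_peaks > 0L) {
      span <- range(mz)
      mz <- c(mz, stats::runif(sim$n_noise_peaks, span[1L], span[2L]))
      intensity <- c(intensity,
                     stats::runif(sim$n_noise_peaks,
                                  sim$noise_intensity_range[1L],
                                  sim$noise_intensity_range[2L]))
    }
    peak_list(mz, intensity, precursor_mz = mz[sum(keep) + 1L],
              noise_level = sim$noise_level)
  })
}

#' Reproducible random bit strings and bit matrices
#'
#' Stand-ins for arbitrary machine-readable payloads such as QR-code pixel
#' grids, which the codec treats as opaque bit matrices.
#'
#' @param n Number of bits (>= 1).
#' @param seed Optional integer seed.
#' @return `random_bits()` a string of `n` bits; `random_matrix()` an integer
#'   `height x width` matrix of 0/1.
#' @examples
#' nchar(bit_matrix_to_bits(random_matrix(33, 33, seed = 1)))  # 1089
#' @export
random_bits <- function(n, seed = NULL) {
  if (n < 1) stop_data("n must be >= 1")
  paste(local_sample_bits(seed, n), collapse = "")
}

#' @rdname random_bits
#' @param height,width Matrix dimensions.
#' @export
random_matrix <- function(height, width, seed = NULL) {
  stopifnot(height >= 1, width >= 1)
  matrix(local_sample_bits(seed, height * width),
         nrow = height, ncol = width, byrow = TRUE)
}
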