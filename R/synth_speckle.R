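#' Dynamic speckle simulation parameters
#'
#' Parameters for the synthetic laser-speckle generator. The temporal model
#' is a per-substep AR(1) on the complex optical field (Lorentzian-type
#' decorrelation with correlation time `tau_c_ms`); the camera exposure
#' integrates `n_substeps` intensity sub-frames over `exposure_ms`. The
#' spatial speckle grain is set by a circular frequency-domain aperture
#' with cutoff `1/grain_px` cycles/pixel, so `grain_px = 2` is
#' Nyquist-sampled speckle.
#'
#' @param shape `(frames, rows, cols)` of the output stack.
#' @param grain_px speckle grain size in pixels (>= 2).
#' @param tau_c_ms field correlation time in ms; `Inf` gives static speckle.
#' @param exposure_ms camera exposure per frame in ms.
#' @param n_substeps field evolution substeps integrated per exposure (>= 8).
#' @param beta coherence factor in (0, 1]; 1 is fully developed polarized
#'   speckle.
#' @param seed integer RNG seed.
#' @return a list of class `speckle_sim_params`.
#' @export
speckle_sim_params <- function(shape = c(15, 128, 128), grain_px = 2,
                               tau_c_ms = 0.5, exposure_ms = 5,
                               n_substeps = 16, beta = 1, seed = 1) {
  if (length(shape) != 3 || any(shape < 1)) stop_param("shape must be (frames, rows, cols)")
  if (!(tau_c_ms > 0)) stop_param("tau_c_ms must be > 0 (Inf allowed)")
  if (n_substeps < 8) stop_param("n_substeps must be >= 8")
  if (grain_px < 2) stop_param("grain_px must be >= 2")
  if (!(beta > 0 && beta <= 1)) stop_param("beta must be in (0, 1]")
  if (!(exposure_ms > 0)) stop_param("exposure_ms must be > 0")
  structure(list(shape = as.integer(shape), grain_px = grain_px,
                 tau_c_ms = tau_c_ms, exposure_ms = exposure_ms,
                 n_substeps = as.integer(n_substeps), beta = beta,
                 seed = as.integer(seed)),
            class = "speckle_sim_params")
}

# Low-pass aperture mask in FFT layout for an n x m grid.
speckle_aperture <- function(n, m, grain_px) {
  fr <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fc <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)[1:m] / m
  outer(fr^2, fc^2, "+") <= (1 / grain_px)^2
}

# Filter white complex noise through the aperture; unit intensity mean.
filtered_field <- function(n, m, mask, nmask) {
  w <- rcnorm_mat(n, m)
  stats::fft(stats::fft(w) * mask, inverse = TRUE) / (sqrt(n * m) * sqrt(nmask))
}

#' Generate a dynamic speckle stack with known ground truth
#'
#' Produces an 8-bit raw speckle image stack whose per-frame exposure
#' integrates a decorrelating complex Gaussian field, together with the
#' generating parameters and the expected speckle contrast from the
#' brute-force temporal oracle ([expected_speckle_contrast()]).
#'
#' Partial coherence (`beta < 1`) is applied as an intensity mixture
#' shrinking fluctuations about the mean so that `K^2` scales by `beta`.
#' Intensities are digitized with the mean at 1/8 of full scale.
#'
#' @param p a [speckle_sim_params].
#' @return list with `stack` (an [image_stack]) and `truth`
#'   (`tau_c_ms`, `exposure_ms`, `expected_K`, `beta`, `grain_px`).
#' @export
gen_speckle_stack <- function(p) {
  stopifnot(inherits(p, "speckle_sim_params"))
  set.seed(p$seed)
  nf <- p$shape[1]; n <- p$shape[2]; m <- p$shape[3]
  mask <- speckle_aperture(n, m, p$grain_px)
  nmask <- sum(mask)
  dt <- p$exposure_ms / p$n_substeps
  a <- if (is.infinite(p$tau_c_ms)) 1 else exp(-dt / p$tau_c_ms)
  b <- sqrt(1 - a^2)

  E <- filtered_field(n, m, mask, nmask)
  frames <- array(0, c(nf, n, m))
  for (f in seq_len(nf)) {
    acc <- matrix(0, n, m)
    for (s in seq_len(p$n_substeps)) {
      if (!(f == 1 && s == 1)) {
        E <- a * E + b * filtered_field(n, m, mask, nmask)
      }
      acc <- acc + Mod(E)^2
    }
    I <- acc / p$n_substeps
    I <- sqrt(p$beta) * (I - 1) + 1          # coherence mixing, mean 1
    frames[f, , ] <- pmin(pmax(round(I / 8 * 255), 0), 255)
  }
  expected_K <- expected_speckle_contrast(p$tau_c_ms, p$exposure_ms,
                                          p$n_substeps, p$beta,
                                          seed = p$seed + 1L)
  list(stack = image_stack(frames, bit_depth = 8, exposure_ms = p$exposure_ms),
       truth = list(tau_c_ms = p$tau_c_ms, exposure_ms = p$exposure_ms,
                    expected_K = expected_K, beta = p$beta,
                    grain_px = p$grain_px))
}

#' Brute-force expected speckle contrast
#'
#' Independent-realization oracle for the temporal speckle model: simulates
#' many scalar complex AR(1) chains with per-substep coefficient
#' `exp(-dt/tau_c)`, integrates intensity over the exposure, and returns
#' the ensemble `sd/mean`. This is the reference value the generator and
#' the contrast stage are validated against; no closed-form visibility
#' expression is used.
#'
#' @param tau_c_ms field correlation time (ms); `Inf` for static speckle.
#' @param exposure_ms exposure time (ms).
#' @param n_substeps substeps per exposure (same discretization as the
#'   generator).
#' @param beta coherence factor in (0, 1].
#' @param n_realizations ensemble size.
#' @param seed RNG seed.
#' @return expected contrast K (scalar).
#' @export
expected_speckle_contrast <- function(tau_c_ms, exposure_ms, n_substeps = 16,
                                      beta = 1, n_realizations = 50000,
                                      seed = 1) {
  set.seed(seed)
  dt <- exposure_ms / n_substeps
  a <- if (is.infinite(tau_c_ms)) 1 else exp(-dt / tau_c_ms)
  b <- sqrt(1 - a^2)
  E <- complex(real = stats::rnorm(n_realizations),
               imaginary = stats::rnorm(n_realizations)) / sqrt(2)
  acc <- Mod(E)^2
  for (s in seq_len(n_substeps - 1L)) {
    E <- a * E + b * complex(real = stats::rnorm(n_realizations),
                             imaginary = stats::rnorm(n_realizations)) / sqrt(2)
    acc <- acc + Mod(E)^2
  }
  I <- acc / n_substeps
  I <- sqrt(beta) * (I - 1) + 1
  stats::sd(I) / mean(I)
}
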