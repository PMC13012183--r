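#' Bilateral hemodynamic movie simulation parameters
#'
#' Parameters for synthetic widefield reflectance movies with a known
#' homotopic correlation structure. For each mirror pixel pair the two
#' time series are built as `sqrt(rho) * s + sqrt(1 - rho) * e` from
#' band-limited unit-variance Gaussian processes (`s` shared within the
#' pair, `e` independent per pixel), on top of a baseline intensity, an
#' optional linear drift, a common global component, and white noise.
#'
#' @param shape image dimension `(rows, cols)`.
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate (frames/s).
#' @param rho target homotopic correlation in `[0, 1]`.
#' @param band `(low, high)` Hz of the shared/unshared signal processes.
#' @param drift_slope linear drift in counts/frame (nuisance).
#' @param global_amp amplitude (counts) of a common global component
#'   (nuisance).
#' @param noise_sd white noise standard deviation (counts).
#' @param signal_amp amplitude (counts) of the unit-variance hemodynamic
#'   component.
#' @param midline a [midline_axis]; default is a vertical midline between
#'   the two center columns (all pixels paired).
#' @param mask logical brain mask (default: all pixels).
#' @param seed integer RNG seed.
#' @return a list of class `bilateral_sim_params`.
#' @export
bilateral_sim_params <- function(shape = c(128, 128), n_frames = 1800,
                                 frame_rate_hz = 3, rho = 0.7,
                                 band = c(0.035, 0.08), drift_slope = 0.01,
                                 global_amp = 5, noise_sd = 3,
                                 signal_amp = 10, midline = NULL,
                                 mask = NULL, seed = 1) {
  if (!(rho >= 0 && rho <= 1)) stop_param("rho must be in [0, 1]")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < frame_rate_hz / 2)) {
    stop_param("band must lie inside (0, frame_rate/2)")
  }
  if (is.null(midline)) {
    midline <- midline_axis(c(1, (shape[2] + 1) / 2),
                            c(shape[1], (shape[2] + 1) / 2))
  }
  structure(list(shape = as.integer(shape), n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz, rho = rho, band = band,
                 drift_slope = drift_slope, global_amp = global_amp,
                 noise_sd = noise_sd, signal_amp = signal_amp,
                 midline = midline, mask = mask, seed = as.integer(seed)),
            class = "bilateral_sim_params")
}

# n x m matrix of independent band-limited Gaussian processes,
# standardized to unit variance, synthesized in the frequency domain.
band_limited_noise <- function(n, m, fs, band) {
  if (m == 0) return(matrix(0, n, 0))
  f <- (seq_len(n) - 1) / n * fs
  pos <- which(f >= band[1] & f <= band[2] & seq_len(n) <= floor(n / 2) + 1 &
                 seq_len(n) >= 2)
  if (length(pos) == 0) stop_param("band contains no Fourier bins at this length")
  S <- matrix(0 + 0i, n, m)
  S[pos, ] <- rcnorm_mat(length(pos), m)
  conj_idx <- n - pos + 2
  keep <- conj_idx <= n & conj_idx != pos
  S[conj_idx[keep], ] <- Conj(S[pos[keep], ])
  x <- Re(stats::mvfft(S, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sds[sds < 1e-30] <- 1
  sweep(x, 2, sds, "/")
}

# Shared assembly used by gen_bilateral_movie and gen_csd_movie.
# `atten` is a length-n factor multiplying the shared component on the
# `ipsi_side` (+1/-1) only; `wave_gain_fun(dist, t)` (optional) returns a
# multiplicative intensity gain applied to ipsi-side pixels.
bilateral_assemble <- function(p, atten = NULL, ipsi_side = 0,
                               wave = NULL, n_frames = p$n_frames) {
  set.seed(p$seed)
  n <- n_frames
  nr <- p$shape[1]; nc <- p$shape[2]
  npix <- nr * nc
  mask <- if (is.null(p$mask)) matrix(TRUE, nr, nc) else p$mask
  pairs <- homotopic_pairs(c(nr, nc), p$midline, mask)
  npair <- nrow(pairs)
  paired_idx <- c(pairs$i, pairs$j)
  unpaired <- setdiff(which(mask), paired_idx)

  s <- band_limited_noise(n, npair, p$frame_rate_hz, p$band)
  eL <- band_limited_noise(n, npair, p$frame_rate_hz, p$band)
  eR <- band_limited_noise(n, npair, p$frame_rate_hz, p$band)
  eU <- band_limited_noise(n, length(unpaired), p$frame_rate_hz, p$band)
  g <- if (p$global_amp > 0) {
    band_limited_noise(n, 1, p$frame_rate_hz, p$band)[, 1]
  } else {
    numeric(n)
  }

  if (is.null(atten)) atten <- rep(1, n)
  a_i <- if (ipsi_side > 0) atten else rep(1, n)   # pairs$i is the + side
  a_j <- if (ipsi_side < 0) atten else rep(1, n)

  Z <- matrix(0, n, npix)
  if (npair > 0) {
    Z[, pairs$i] <- sqrt(p$rho) * (a_i * s) + sqrt(1 - p$rho) * eL
    Z[, pairs$j] <- sqrt(p$rho) * (a_j * s) + sqrt(1 - p$rho) * eR
  }
  if (length(unpaired) > 0) Z[, unpaired] <- eU

  I <- 128 + p$signal_amp * Z +
    p$drift_slope * (seq_len(n) - 1) +
    p$global_amp * g
  if (p$noise_sd > 0) I <- I + p$noise_sd * matrix(stats::rnorm(n * npix), n, npix)

  if (!is.null(wave)) {
    pts <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
    side <- midline_side(pts, p$midline)
    ipsi <- which(side == ipsi_side)
    dist <- sqrt((pts[ipsi, 1] - wave$origin[1])^2 +
                   (pts[ipsi, 2] - wave$origin[2])^2)
    G <- wave_gain(dist, n, wave)                 # n x length(ipsi)
    I[, ipsi] <- I[, ipsi] * G
  }

  frames <- array(pmin(pmax(round(I), 0), 255), c(n, nr, nc))
  list(movie = image_stack(frames, bit_depth = 8,
                           frame_rate_hz = p$frame_rate_hz),
       pairs = pairs, mask = mask)
}

#' Generate a bilateral hemodynamic movie with known ground truth
#'
#' @param p a [bilateral_sim_params].
#' @return list with `movie` (an 8-bit [image_stack]) and `truth`
#'   (`rho`, `midline`, `mask`, pair table).
#' @export
gen_bilateral_movie <- function(p) {
  stopifnot(inherits(p, "bilateral_sim_params"))
  res <- bilateral_assemble(p)
  list(movie = res$movie,
       truth = list(rho = p$rho, midline = p$midline, mask = res$mask,
                    pairs = res$pairs))
}

# Multiplicative flow-transient gain for a radially propagating wave:
# instantaneous rise to hyper_gain on arrival, hold, linear transition to
# oligemia_gain, then linear recovery to 1 over recovery_frames.
wave_gain <- function(dist, n, wave) {
  t_arr <- wave$onset_frame + dist / wave$speed_px_per_frame
  tt <- seq_len(n)
  G <- matrix(1, n, length(dist))
  for (k in seq_along(dist)) {
    ph <- tt - t_arr[k]
    gk <- rep(1, n)
    hy <- ph >= 0 & ph < wave$hyper_frames
    gk[hy] <- wave$hyper_gain
    tr <- ph >= wave$hyper_frames & ph < wave$hyper_frames + wave$trans_frames
    gk[tr] <- wave$hyper_gain + (wave$oligemia_gain - wave$hyper_gain) *
      (ph[tr] - wave$hyper_frames) / wave$trans_frames
    rec0 <- wave$hyper_frames + wave$trans_frames
    rc <- ph >= rec0 & ph < rec0 + wave$recovery_frames
    gk[rc] <- wave$oligemia_gain + (1 - wave$oligemia_gain) *
      (ph[rc] - rec0) / wave$recovery_frames
    G[, k] <- gk
  }
  G
}

#' CSD event description for [gen_csd_movie()]
#'
#' @param onset_frame frame at which the wave starts at `origin`.
#' @param origin `(row, col)` wave origin; must lie strictly inside one
#'   hemisphere.
#' @param speed_px_per_frame radial propagation speed.
#' @param hyper_gain transient hyperemia flow gain (> 1).
#' @param oligemia_gain post-wave oligemia gain (< 1).
#' @param hyper_frames duration of the hyperemic plateau (frames).
#' @param trans_frames hyperemia-to-oligemia transition (frames).
#' @param recovery_frames linear recovery of flow back to baseline (frames).
#' @param conn_floor attenuation floor of the ipsilateral shared component
#'   right after onset (0 = fully suppressed).
#' @param conn_recovery_frames frames over which the shared component
#'   recovers linearly to full strength.
#' @param baseline_frames length of the baseline recording generated
#'   alongside the event movie.
#' @return a list of class `csd_params`.
#' @export
csd_params <- function(onset_frame = 1, origin = c(32, 24),
                       speed_px_per_frame = 0.7, hyper_gain = 1.8,
                       oligemia_gain = 0.7, hyper_frames = 270,
                       trans_frames = 90, recovery_frames = 2700,
                       conn_floor = 0.15, conn_recovery_frames = 3000,
                       baseline_frames = 1800) {
  structure(as.list(environment()), class = "csd_params")
}

#' Generate a CSD event movie plus matched baseline
#'
#' Builds a bilateral movie and superimposes, on the hemisphere containing
#' `origin` only, (i) a radially propagating multiplicative flow transient
#' (hyperemia then oligemia recovering over `recovery_frames`) and (ii) an
#' attenuation of the shared homotopic component from `conn_floor` back to
#' 1 over `conn_recovery_frames` — the transient interhemispheric
#' connectivity loss. The contralateral hemisphere is bit-identical to a
#' no-CSD run with the same seed. A separate baseline recording (same
#' parameters, no event, independent seed) is returned alongside.
#'
#' @param p a [bilateral_sim_params].
#' @param csd a [csd_params].
#' @return list with `movie` (post-induction), `baseline`, and `truth`
#'   (generator schedule and geometry).
#' @export
gen_csd_movie <- function(p, csd = csd_params()) {
  stopifnot(inherits(p, "bilateral_sim_params"), inherits(csd, "csd_params"))
  side <- midline_side(matrix(csd$origin, ncol = 2), p$midline)
  if (side == 0) stop_geometry("CSD origin lies on the midline")
  tt <- seq_len(p$n_frames)
  atten <- ifelse(tt < csd$onset_frame, 1,
                  csd$conn_floor + (1 - csd$conn_floor) *
                    pmin(1, (tt - csd$onset_frame) / csd$conn_recovery_frames))
  res <- bilateral_assemble(p, atten = atten, ipsi_side = side, wave = csd)
  pb <- p
  pb$seed <- p$seed + 99991L
  base <- bilateral_assemble(pb, n_frames = csd$baseline_frames)
  list(movie = res$movie, baseline = base$movie,
       truth = list(rho = p$rho, midline = p$midline, ipsi_side = side,
                    csd = unclass(csd), attenuation = atten,
                    pairs = res$pairs))
}
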