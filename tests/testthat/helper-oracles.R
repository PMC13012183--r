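# Independent brute-force oracles and small fixture builders. These
# deliberately use naive double loops / exhaustive search so they share no
# code path with the implementations they check.

# Windowed speckle contrast by direct double loop: sample sd / mean over
# each fully interior window.
oracle_windowed_contrast <- function(img, w = 7) {
  h <- (w - 1) / 2
  n <- nrow(img)
  m <- ncol(img)
  K <- matrix(NA_real_, n, m)
  for (r in (h + 1):(n - h)) {
    for (cc in (h + 1):(m - h)) {
      patch <- img[(r - h):(r + h), (cc - h):(cc + h)]
      K[r, cc] <- stats::sd(patch) / mean(patch)
    }
  }
  K
}

# Exhaustive Otsu: try every interior edge of the 256-bin grid, compute
# between-class variance directly from the raw values.
oracle_otsu <- function(vals, n_bins = 256) {
  lo <- min(vals)
  hi <- max(vals)
  edges <- seq(lo, hi, length.out = n_bins + 1)[-c(1, n_bins + 1)]
  best <- -Inf
  best_t <- NA_real_
  for (t in edges) {
    g0 <- vals[vals <= t]
    g1 <- vals[vals > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(vals)
    sb <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (sb > best + 1e-15) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# Ring-band Sholl oracle: foreground pixels within half a pixel of the
# circle, clustered by angular gaps (adjacent pixels on the ring subtend
# about 1/r radians; a gap beyond 1.8/r separates clusters), with the
# 0/2pi seam wrapped.
oracle_sholl_count <- function(binary, center, r_px) {
  idx <- which(binary, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)
  ring <- idx[abs(d - r_px) <= 0.5, , drop = FALSE]
  if (nrow(ring) == 0) return(0L)
  ang <- sort(atan2(ring[, 1] - center[1], ring[, 2] - center[2]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  n_breaks <- sum(gaps > 1.8 / r_px)
  if (n_breaks == 0) 1L else as.integer(n_breaks)
}

# Binary k-armed star: disc soma plus straight arms of length L px and the
# given width, equally spaced with a rotation offset.
make_star <- function(k, L_px, soma_px = 4, width_px = 2, dim_px = 2 * L_px + 21,
                      rot = 0.3) {
  ctr <- c((dim_px + 1) / 2, (dim_px + 1) / 2)
  mask <- matrix(FALSE, dim_px, dim_px)
  pts <- expand.grid(r = 1:dim_px, c = 1:dim_px)
  d2 <- (pts$r - ctr[1])^2 + (pts$c - ctr[2])^2
  mask[d2 <= soma_px^2] <- TRUE
  for (a in rot + 2 * pi * (0:(k - 1)) / k) {
    for (t in seq(0, L_px, by = 0.25)) {
      rr <- ctr[1] + t * sin(a)
      cc <- ctr[2] + t * cos(a)
      for (dr in -width_px:width_px) {
        for (dc in -width_px:width_px) {
          if (dr^2 + dc^2 <= (width_px / 2)^2 + 0.5) {
            r2 <- round(rr) + dr
            c2 <- round(cc) + dc
            if (r2 >= 1 && r2 <= dim_px && c2 >= 1 && c2 <= dim_px) {
              mask[r2, c2] <- TRUE
            }
          }
        }
      }
    }
  }
  list(mask = mask, center = ctr)
}

# Random radial-arm binary image: a soma plus arms of random length at
# random angles with a minimum angular separation. Arms cross rings
# transversally — the geometry Sholl analysis targets, and the image
# family on which circle-sampling and ring-band counting coincide
# (tangentially grazing blobs are a genuinely ambiguous discretization).
random_star_image <- function(dim_px = 75, kmax = 7, lmin = 26, lmax = 34) {
  k <- sample(3:kmax, 1)
  # jittered equal spacing keeps a guaranteed minimum angular separation
  spacing <- 2 * pi / k
  jit <- stats::runif(k, -1, 1) * (spacing - 0.7) / 2.2
  angs <- stats::runif(1, 0, 2 * pi) + spacing * (0:(k - 1)) + jit
  ctr <- c((dim_px + 1) / 2, (dim_px + 1) / 2)
  mask <- matrix(FALSE, dim_px, dim_px)
  pts <- expand.grid(r = 1:dim_px, c = 1:dim_px)
  mask[(pts$r - ctr[1])^2 + (pts$c - ctr[2])^2 <= 9] <- TRUE
  for (a in angs) {
    L <- stats::runif(1, lmin, lmax)
    for (t in seq(0, L, by = 0.25)) {
      rr <- round(ctr[1] + t * sin(a))
      cc <- round(ctr[2] + t * cos(a))
      for (dr in -1:1) for (dc in -1:1) {
        if (dr^2 + dc^2 <= 1.5) {
          r2 <- rr + dr
          c2 <- cc + dc
          if (r2 >= 1 && r2 <= dim_px && c2 >= 1 && c2 <= dim_px) {
            mask[r2, c2] <- TRUE
          }
        }
      }
    }
  }
  list(mask = mask, center = ctr, k = k)
}

# Quiet params for a clean bilateral movie (no nuisance terms).
clean_bilateral <- function(rho, n_frames = 1800, shape = c(32, 32), seed = 1) {
  bilateral_sim_params(shape = shape, n_frames = n_frames, rho = rho,
                       drift_slope = 0, global_amp = 0, noise_sd = 0,
                       seed = seed)
}
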