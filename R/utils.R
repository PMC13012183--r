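# Internal helpers shared across modules.

stop_mesowin <- function(msg, class) {
  stop(structure(
    class = c(class, "mesowin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format <- function(msg) stop_mesowin(msg, "mesowin_format_error")
stop_geometry <- function(msg) stop_mesowin(msg, "mesowin_geometry_error")
stop_param <- function(msg) stop_mesowin(msg, "mesowin_param_error")
stop_degenerate <- function(msg) stop_mesowin(msg, "mesowin_degenerate_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

# Sliding-window box sum over the valid region (no padding); NA on the
# border of half-width (w-1)/2. Integral-image implementation.
box_sum <- function(x, w) {
  stopifnot(w %% 2 == 1, w >= 1)
  n <- nrow(x)
  m <- ncol(x)
  if (w > min(n, m)) stop_param("window larger than image")
  h <- (w - 1L) / 2L
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs))
  out <- matrix(NA_real_, n, m)
  r <- (h + 1L):(n - h)
  cc <- (h + 1L):(m - h)
  out[r, cc] <- cs[r + h + 1L, cc + h + 1L, drop = FALSE] -
    cs[r - h, cc + h + 1L, drop = FALSE] -
    cs[r + h + 1L, cc - h, drop = FALSE] +
    cs[r - h, cc - h, drop = FALSE]
  out
}

# Offsets (drow, dcol) of a rasterized disc of the given pixel radius.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Paint discs of `radius` centered at integer (row, col) points into a
# logical mask of dimension `dm`.
paint_discs <- function(mask, centers, radius) {
  off <- disc_offsets(radius)
  n <- nrow(mask)
  m <- ncol(mask)
  for (i in seq_len(nrow(centers))) {
    rr <- centers[i, 1] + off[, 1]
    cc <- centers[i, 2] + off[, 2]
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonally touching labels are merged with a union-find pass.
label_components <- function(binary) {
  lab <- EBImage::bwlabel(binary != 0)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    a <- a[keep]
    b <- b[keep]
    for (j in seq_along(a)) {
      ra <- find(a[j])
      rb <- find(b[j])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  n <- nrow(lab)
  m <- ncol(lab)
  # diagonal neighbours: (r, c) vs (r+1, c+1) and (r+1, c) vs (r, c+1)
  union_pairs(lab[-n, -m], lab[-1, -1])
  union_pairs(lab[-1, -m], lab[-n, -1])
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Drop connected components smaller than min_px (8-connectivity).
filter_small_components <- function(binary, min_px) {
  lab <- label_components(binary)
  if (max(lab) == 0L) return(binary & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

# Scanline even-odd polygon rasterization. `vertices` is an n x 2 matrix of
# (row, col); pixel centers at integer coordinates are tested.
polygon_mask <- function(vertices, dm) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop_geometry("polygon needs >= 3 (row, col) vertices")
  }
  if (any(vertices[, 1] < 0.5 - 1e-9) || any(vertices[, 1] > dm[1] + 0.5 + 1e-9) ||
      any(vertices[, 2] < 0.5 - 1e-9) || any(vertices[, 2] > dm[2] + 0.5 + 1e-9)) {
    stop_geometry("polygon vertices outside image bounds")
  }
  mask <- matrix(FALSE, dm[1], dm[2])
  ry <- vertices[, 1]
  cx <- vertices[, 2]
  nv <- length(ry)
  jj <- c(nv, seq_len(nv - 1L))
  for (row in seq_len(dm[1])) {
    y <- row
    xs <- numeric(0)
    for (i in seq_len(nv)) {
      j <- jj[i]
      y1 <- ry[i]; y2 <- ry[j]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        xs <- c(xs, cx[i] + (y - y1) / (y2 - y1) * (cx[j] - cx[i]))
      }
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      for (p in seq(1, length(xs) - 1, by = 2)) {
        c1 <- ceiling(xs[p] - 1e-9)
        c2 <- floor(xs[p + 1] + 1e-9)
        if (c2 >= c1) mask[row, max(1, c1):min(dm[2], c2)] <- TRUE
      }
    }
  }
  mask
}

# Complex circular Gaussian white noise matrix, unit variance per element.
rcnorm_mat <- function(n, m) {
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)) /
           sqrt(2), n, m)
}
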