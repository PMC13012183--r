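#' Microglia morphology simulation parameters
#'
#' Parameters for synthetic branched-cell images with analytically known
#' Sholl profiles: each cell is a disk soma with `n_branches` straight
#' processes of length `branch_length_um` at evenly spaced (randomly
#' rotated) angles, optionally bifurcating once at `bifurcate_at_um` so
#' the distal branch count doubles.
#'
#' @param n_cells number of cells per field.
#' @param soma_radius_um soma radius (um).
#' @param n_branches primary branches per cell (k >= 1).
#' @param branch_length_um radial branch length L (um); must exceed the
#'   soma radius.
#' @param bifurcate_at_um radius of a single symmetric bifurcation, or
#'   `NULL` for unbranched arms.
#' @param branch_width_um process width (um).
#' @param pixel_size_um um per pixel.
#' @param noise_level additive white noise sd (counts, 8-bit scale).
#' @param shape image dimension `(rows, cols)`.
#' @param seed RNG seed.
#' @return a list of class `morphology_sim_params`.
#' @export
morphology_sim_params <- function(n_cells = 5, soma_radius_um = 4,
                                  n_branches = 6, branch_length_um = 25,
                                  bifurcate_at_um = NULL,
                                  branch_width_um = 1.2,
                                  pixel_size_um = 0.865,
                                  noise_level = 3, shape = c(512, 512),
                                  seed = 1) {
  if (n_branches < 1) stop_param("n_branches must be >= 1")
  if (!(branch_length_um > soma_radius_um)) {
    stop_param("branch_length_um must exceed soma_radius_um")
  }
  if (!is.null(bifurcate_at_um) &&
      !(bifurcate_at_um > soma_radius_um && bifurcate_at_um < branch_length_um)) {
    stop_param("bifurcate_at_um must lie between soma radius and branch length")
  }
  structure(as.list(environment()), class = "morphology_sim_params")
}

# Paint a thick segment from a to b (px coords) into a logical mask.
paint_segment <- function(mask, a, b, half_width_px) {
  len <- sqrt(sum((b - a)^2))
  nstep <- max(2L, ceiling(len / 0.4))
  t <- seq(0, 1, length.out = nstep)
  pts <- cbind(round(a[1] + t * (b[1] - a[1])), round(a[2] + t * (b[2] - a[2])))
  paint_discs(mask, unique(pts), half_width_px)
}

#' Generate a synthetic microglia field with known Sholl ground truth
#'
#' Cells are placed at random non-touching positions (error after too many
#' rejected placements), rasterized bright on a dark background with a
#' smooth illumination gradient and additive noise to exercise the
#' preprocessing chain.
#'
#' For an unbifurcated cell the true Sholl count is `n_branches` at every
#' radius strictly between the soma edge and the branch tips; with a
#' bifurcation it steps to `2 * n_branches` beyond `bifurcate_at_um`
#' (distal extent `arbor_radius_um`, recorded in the truth).
#'
#' @param p a [morphology_sim_params].
#' @return list with `image` (8-bit matrix), and `truth` (`centers` in px,
#'   `k`, `L_um`, `soma_radius_um`, `bifurcate_at_um`, `arbor_radius_um`,
#'   `cell_mask`).
#' @export
gen_microglia_image <- function(p) {
  stopifnot(inherits(p, "morphology_sim_params"))
  set.seed(p$seed)
  nr <- p$shape[1]; nc <- p$shape[2]
  px <- function(um) um / p$pixel_size_um
  L_px <- px(p$branch_length_um)
  margin <- L_px + px(p$branch_width_um) + 3
  if (2 * margin >= min(nr, nc)) stop_param("cells do not fit in the frame")
  centers <- matrix(0, 0, 2)
  tries <- 0
  while (nrow(centers) < p$n_cells) {
    tries <- tries + 1
    if (tries > 2000) stop_mesowin("cannot place cells without touching",
                                   "mesowin_placement_error")
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 2 * margin) {
      centers <- rbind(centers, cand)
    }
  }
  centers <- round(centers)

  hw <- max(px(p$branch_width_um) / 2, 1)
  mask <- matrix(FALSE, nr, nc)
  arbor_radius_um <- p$branch_length_um
  for (i in seq_len(p$n_cells)) {
    ctr <- centers[i, ]
    mask <- paint_discs(mask, matrix(ctr, 1), px(p$soma_radius_um))
    rot <- stats::runif(1, 0, 2 * pi)
    angs <- rot + 2 * pi * (seq_len(p$n_branches) - 1) / p$n_branches
    for (a in angs) {
      dirv <- c(sin(a), cos(a))
      if (is.null(p$bifurcate_at_um)) {
        mask <- paint_segment(mask, ctr, ctr + L_px * dirv, hw)
      } else {
        bif_px <- px(p$bifurcate_at_um)
        bp <- ctr + bif_px * dirv
        mask <- paint_segment(mask, ctr, bp, hw)
        dlen <- L_px - bif_px
        for (da in c(-1, 1) * (15 * pi / 180)) {
          dv <- c(sin(a + da), cos(a + da))
          mask <- paint_segment(mask, bp, bp + dlen * dv, hw)
        }
        arbor_radius_um <- sqrt(p$bifurcate_at_um^2 +
                                  (p$branch_length_um - p$bifurcate_at_um)^2 +
                                  2 * p$bifurcate_at_um *
                                  (p$branch_length_um - p$bifurcate_at_um) *
                                  cos(15 * pi / 180))
      }
    }
  }

  grad <- outer(seq_len(nr) / nr, seq_len(nc) / nc, function(a, b) 15 * (a + b) / 2)
  img <- 20 + grad
  img[mask] <- 200
  if (p$noise_level > 0) img <- img + stats::rnorm(nr * nc, 0, p$noise_level)
  img <- pmin(pmax(round(img), 0), 255)
  list(image = img,
       truth = list(centers = centers, k = p$n_branches,
                    L_um = p$branch_length_um,
                    soma_radius_um = p$soma_radius_um,
                    bifurcate_at_um = p$bifurcate_at_um,
                    arbor_radius_um = arbor_radius_um,
                    cell_mask = mask))
}
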