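# Serial-section phantom: an ellipsoidal "heart" with thin bright tracts
# tracing a conduction-system-like course (sinoatrial blob, a His-bundle
# trunk descending from the atrioventricular node, and two Purkinje
# branches). Purely illustrative geometry with known ground truth.

# Distance from points (px, py) to segment (ax,ay)-(bx,by); all normalised.
seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# Rasterise one phantom plane at depth w (0..1). Returns list of logical
# masks (tissue, positive) of size n x n.
phantom_plane <- function(n, w) {
  s2 <- 1 - ((w - 0.5) / 0.45)^2
  tissue <- matrix(FALSE, n, n)
  positive <- matrix(FALSE, n, n)
  if (s2 <= 0) return(list(tissue = tissue, positive = positive))
  s <- sqrt(s2)
  u <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)   # x
  v <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n)  # y
  tissue <- ((u - 0.5) / (0.26 * s))^2 + ((v - 0.5) / (0.38 * s))^2 <= 1
  if (w >= 0.15 && w <= 0.45) {
    positive <- positive |
      ((u - 0.62)^2 + (v - 0.30)^2 <= 0.03^2)                  # SAN blob
  }
  if (w >= 0.30 && w <= 0.70) {
    positive <- positive |
      (seg_dist(u, v, 0.5, 0.35, 0.5, 0.60) <= 0.02)           # AVN/His
  }
  if (w >= 0.45 && w <= 0.85) {
    positive <- positive |
      (seg_dist(u, v, 0.5, 0.60, 0.38, 0.80) <= 0.018) |       # left PKJ
      (seg_dist(u, v, 0.5, 0.60, 0.62, 0.80) <= 0.018)         # right PKJ
  }
  positive <- positive & tissue
  list(tissue = tissue, positive = positive)
}

#' Generate serial fluorescence sections of a 3D phantom
#'
#' Each slice samples one plane of the phantom: tissue appears as a dense
#' speckle (nuclei-like) in the blue channel, positive cells as solid signal
#' in the red channel, and the green channel is empty. The slice is then
#' perturbed by its ground-truth rigid transform (rotation about the image
#' centre plus translation) and additive Gaussian noise. The truth volume is
#' stored untransformed with tissue voxels at 40 and positive voxels at 180.
#'
#' @param cfg A [sim_config()]; `cfg$affine_truth` (if set) supplies the
#'   per-slice perturbations, otherwise they are drawn uniformly within
#'   `cfg$affine_limits` with slice 1 held at identity.
#' @param n_slices Number of sections (>= 1).
#' @param size_px Image edge in pixels.
#' @param z_range Depth band `[lo, hi]` of the phantom sampled by the
#'   slices; the default keeps every slice non-empty.
#' @param pixel_size_um,dz_um Physical pixel size and section thickness.
#' @return List with `stack` (a [section_stack()]), `truth` (a
#'   [volume_grid()] of labels 0/40/180), and `affine_truth` (list of
#'   per-slice `list(rotation_deg, dx, dy)`).
#' @export
gen_sections <- function(cfg, n_slices, size_px = 96L,
                         z_range = c(0.2, 0.8),
                         pixel_size_um = 1, dz_um = 10) {
  if (!inherits(cfg, "sim_config")) abort_config("cfg must be a sim_config")
  if (n_slices < 1L) abort_config("n_slices must be >= 1")
  set.seed(cfg$seed + 20000L)
  n <- as.integer(size_px)

  ws <- if (n_slices == 1L) mean(z_range) else
    seq(z_range[1], z_range[2], length.out = n_slices)

  affine <- cfg$affine_truth
  if (is.null(affine)) {
    lim <- cfg$affine_limits
    affine <- lapply(seq_len(n_slices), function(i) {
      if (i == 1L) list(rotation_deg = 0, dx = 0, dy = 0) else
        list(rotation_deg = stats::runif(1, -lim[1], lim[1]),
             dx = stats::runif(1, -lim[2], lim[2]),
             dy = stats::runif(1, -lim[2], lim[2]))
    })
  }
  if (length(affine) != n_slices) {
    abort_config("affine_truth must provide one transform per slice")
  }

  truth <- array(0, c(n, n, n_slices))
  images <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    pl <- phantom_plane(n, ws[i])
    truth[, , i][pl$tissue] <- 40
    truth[, , i][pl$positive] <- 180
    blue <- matrix(0, n, n)
    speckle <- matrix(stats::runif(n * n) < cfg$speckle_density, n, n)
    blue[pl$tissue & speckle] <- 200
    red <- matrix(0, n, n)
    red[pl$positive] <- 230
    tr <- affine[[i]]
    img <- array(0, c(n, n, 3))
    img[, , 1] <- warp_rigid(red, tr$rotation_deg, tr$dx, tr$dy)
    img[, , 3] <- warp_rigid(blue, tr$rotation_deg, tr$dx, tr$dy)
    if (cfg$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd),
                         dim(img))
    }
    images[[i]] <- round(clip255(img))
  }
  list(stack = section_stack(images, pixel_size_um = pixel_size_um,
                             dz_um = dz_um),
       truth = volume_grid(truth,
                           spacing = c(pixel_size_um, pixel_size_um, dz_um)),
       affine_truth = affine)
}
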