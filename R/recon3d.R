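# Serial-section 3D reconstruction: resolution unification, hole filling,
# Sobel contours, rigid registration, contrast enhancement, channel
# recoding, layer merging, frequency analysis, volume assembly, VTK output.

# Clip to the 8-bit range without losing matrix/array shape.
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Unify stack resolution by block-mean downsampling
#'
#' Downsamples every slice by an integer factor per axis (block mean over
#' `factor x factor` pixel blocks, rounded half-up), multiplying the pixel
#' size accordingly. Used to bring adult-heart images (about 20-fold the
#' resolution of neonatal ones) onto a common grid. Images are zero-padded
#' to a multiple of the factor when needed.
#'
#' @param stack A [section_stack()] (or a single matrix/array).
#' @param factor Integer downsampling factor (>= 1).
#' @return Downsampled stack (or image) with updated `pixel_size_um`.
#' @export
unify_resolution <- function(stack, factor) {
  if (factor < 1L || factor != round(factor)) {
    abort_input("factor must be an integer >= 1")
  }
  factor <- as.integer(factor)
  down_one <- function(img) {
    if (length(dim(img)) == 3L) {
      chans <- lapply(seq_len(dim(img)[3]), function(k) down_one(img[, , k]))
      out <- array(0, c(dim(chans[[1]]), length(chans)))
      for (k in seq_along(chans)) out[, , k] <- chans[[k]]
      return(out)
    }
    if (factor == 1L) return(img)
    h <- nrow(img); w <- ncol(img)
    H <- ceiling(h / factor) * factor
    W <- ceiling(w / factor) * factor
    if (H != h || W != w) {
      pad <- matrix(0, H, W)
      pad[seq_len(h), seq_len(w)] <- img
      img <- pad
    }
    # Block mean: average rows within blocks, then columns.
    a <- array(img, c(factor, H / factor, W))
    rows <- colMeans(a)                       # (H/f) x W
    a2 <- array(t(rows), c(factor, W / factor, H / factor))
    floor(t(colMeans(a2)) + 0.5)
  }
  if (inherits(stack, "SectionStack")) {
    section_stack(lapply(stack$images, down_one),
                  pixel_size_um = stack$pixel_size_um * factor,
                  dz_um = stack$dz_um)
  } else {
    down_one(stack)
  }
}

#' Fill enclosed holes in a binary mask
#'
#' The background is flood-filled from the image border (4-connectivity);
#' the complement of the reachable background is OR'd with the input, so
#' every enclosed background region becomes foreground. Idempotent, and the
#' output is always a superset of the input foreground.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  bg <- !m
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- reach[h, ] | bg[h, ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, w] <- reach[, w] | bg[, w]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-h, ]
    grown[-h, ] <- grown[-h, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -w]
    grown[, -w] <- grown[, -w] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | !reach
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel convolution with replicate border padding.
#'
#' @param img Single-channel numeric matrix.
#' @return Matrix of gradient magnitudes.
#' @export
sobel_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  sub <- function(dy, dx) p[seq_len(h) + 1L + dy, seq_len(w) + 1L + dx]
  gx <- -sub(-1, -1) - 2 * sub(0, -1) - sub(1, -1) +
    sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)
  gy <- -sub(-1, -1) - 2 * sub(-1, 0) - sub(-1, 1) +
    sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)
  sqrt(gx^2 + gy^2)
}

# Otsu threshold on a 0..255 single-channel image; NA when the image is
# effectively empty (no signal above min_signal).
otsu255 <- function(img, min_signal = 20) {
  mx <- max(img)
  if (mx < min_signal) return(NA_real_)
  th <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1),
                      levels = 256L)
  th * 255
}

#' Emphasise contours with the Sobel operator
#'
#' Computes the Sobel gradient magnitude, thresholds it (Otsu), and adds the
#' resulting edge layer onto the input with saturation at 255.
#'
#' @param img Single-channel numeric matrix (0--255).
#' @return List: `image` (input plus edge layer, saturated), `edges`
#'   (logical edge mask), `threshold` (magnitude threshold; `NA` for a
#'   uniform image).
#' @export
extract_contour <- function(img) {
  if (length(dim(img)) == 3L) abort_input("extract_contour expects a single channel")
  mag <- sobel_magnitude(img)
  if (max(mag) == 0) {
    return(list(image = img, edges = matrix(FALSE, nrow(img), ncol(img)),
                threshold = NA_real_))
  }
  th <- EBImage::otsu(EBImage::Image(mag / max(mag)), range = c(0, 1),
                      levels = 256L) * max(mag)
  edges <- mag > th
  out <- clip255(img + 255 * edges)
  list(image = out, edges = edges, threshold = th)
}

# Binarised, hole-filled tissue mask from a section's blue channel.
tissue_mask <- function(img, min_signal = 20) {
  blue <- if (length(dim(img)) == 3L) img[, , 3] else img
  th <- otsu255(blue, min_signal)
  if (is.na(th)) return(matrix(FALSE, nrow(blue), ncol(blue)))
  fill_holes(blue > th)
}

# Centroid (x, y) and principal-axis angle (degrees in (-90, 90]) of a mask.
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]
  cxy <- c(mean(xs), mean(ys))
  cv <- stats::cov(cbind(xs, ys))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  list(centroid = cxy, angle = ang)
}

wrap_angle <- function(a) ((a + 90) %% 180) - 90

# Estimate the rigid transform mapping the reference frame onto obs_mask.
# ref_mom carries the reference centroid/angle in the aligned frame
# (propagated analytically, so measurement noise does not accumulate by
# resampling); ref_mask is the aligned predecessor mask used only to score
# the rotation refinement. The rotation starts from the principal-axis
# angle difference and is refined by an overlap-maximising search; the
# translation is tied to the mask centroids at each candidate angle.
estimate_rigid <- function(ref_mom, ref_mask, obs_mask, search_deg = 10,
                           step_deg = 0.25, min_gain = 0.01) {
  mo <- mask_moments(obs_mask)
  theta0 <- wrap_angle(mo$angle - ref_mom$angle)
  h <- nrow(ref_mask); w <- ncol(ref_mask)
  ctr <- c((w + 1) / 2, (h + 1) / 2)
  offs <- seq(-search_deg, search_deg, by = step_deg)
  cand <- theta0 + offs[order(abs(offs))]   # nearest-to-estimate first
  best <- list(score = -Inf)
  obs_num <- obs_mask * 1
  for (th in cand) {
    R <- rot_mat(th)
    t_th <- mo$centroid - (as.vector(R %*% (ref_mom$centroid - ctr)) + ctr)
    inv <- invert_rigid(th, t_th[1], t_th[2])
    back <- warp_rigid(obs_num, inv$rotation_deg, inv$dx, inv$dy,
                       interp = "nearest") > 0.5
    # Intersection over union. A candidate away from the principal-axis
    # estimate must beat it by more than resampling jitter (min_gain);
    # otherwise flat profiles (e.g. one section nested inside the other,
    # which carries no rotation information) keep the axis estimate.
    score <- sum(back & ref_mask) / sum(back | ref_mask)
    gain_needed <- if (is.finite(best$score)) min_gain else 0
    if (score > best$score + gain_needed) {
      best <- list(score = score, rotation_deg = th,
                   dx = t_th[1], dy = t_th[2])
    }
  }
  best$obs_moments <- mo
  best
}

#' Register a serial-section stack by chained rigid alignment
#'
#' Each slice is aligned to its (already aligned) predecessor: the tissue
#' mask (binarised blue channel, holes filled) provides the translation via
#' centroids and the rotation via the principal-axis angle, refined by an
#' overlap-maximising search of +/- `search_deg` degrees in `step_deg`
#' steps. The first slice is the reference and keeps the identity
#' transform.
#'
#' @param stack A [section_stack()] with >= 2 slices (RGB).
#' @param search_deg,step_deg Rotation search window and step (degrees).
#' @param min_signal Blue-channel level below which a slice counts as empty.
#' @return List: `transforms` (per-slice `list(rotation_deg, dx, dy)`
#'   estimated to map the reference frame onto the observed slice) and
#'   `aligned` (a [section_stack()] of slices warped back into the
#'   reference frame, bilinear).
#' @export
register_slices <- function(stack, search_deg = 10, step_deg = 0.25,
                            min_signal = 20) {
  if (!inherits(stack, "SectionStack")) {
    abort_input("stack must be a SectionStack")
  }
  n <- length(stack$images)
  if (n < 2L) abort_input("registration needs >= 2 slices")
  masks <- lapply(stack$images, tissue_mask, min_signal = min_signal)
  empty <- which(!vapply(masks, any, logical(1)))
  if (length(empty)) {
    abort_input(sprintf("empty tissue mask in slice(s): %s",
                        paste(empty, collapse = ", ")))
  }
  transforms <- vector("list", n)
  transforms[[1]] <- list(rotation_deg = 0, dx = 0, dy = 0)
  aligned <- stack$images
  ref_mask <- masks[[1]]
  ref_mom <- mask_moments(ref_mask)
  d <- dim(ref_mask)
  ctr <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  for (i in 2:n) {
    est <- estimate_rigid(ref_mom, ref_mask, masks[[i]], search_deg,
                          step_deg)
    transforms[[i]] <- est[c("rotation_deg", "dx", "dy")]
    inv <- invert_rigid(est$rotation_deg, est$dx, est$dy)
    aligned[[i]] <- warp_rigid(stack$images[[i]], inv$rotation_deg,
                               inv$dx, inv$dy)
    ref_mask <- warp_rigid(masks[[i]] * 1, inv$rotation_deg, inv$dx,
                           inv$dy, interp = "nearest") > 0.5
    # Propagate the reference moments analytically into the aligned frame.
    Rinv <- rot_mat(-est$rotation_deg)
    u <- as.vector(Rinv %*% (est$obs_moments$centroid - ctr -
                               c(est$dx, est$dy))) + ctr
    ref_mom <- list(centroid = u,
                    angle = wrap_angle(est$obs_moments$angle -
                                         est$rotation_deg))
  }
  list(transforms = transforms,
       aligned = section_stack(aligned,
                               pixel_size_um = stack$pixel_size_um,
                               dz_um = stack$dz_um))
}

#' Linear contrast enhancement
#'
#' `g(x, y) = gain * f(x, y) + bias`, rounded half-up and clipped to
#' 0--255. `gain` raises contrast, `bias` shifts brightness.
#'
#' @param img Numeric matrix or array (0--255).
#' @param gain,bias Gain and bias of the linear map.
#' @return Enhanced image of the same shape.
#' @export
enhance <- function(img, gain = 1, bias = 0) {
  clip255(floor(gain * img + bias + 0.5))
}

#' Recode an RGB section into the canonical single-layer image
#'
#' The hole-filled blue-channel mask becomes the tissue profile (value 40);
#' red-positive pixels are rewritten to 180 and blue-positive pixels to 10;
#' the green channel is ignored; positives override the profile and the
#' red positives (the reporter signal) take final precedence; background
#' stays 0.
#'
#' @param img RGB array (`h x w x 3`, 0--255).
#' @param min_signal Channel maximum below which a channel holds no
#'   positives.
#' @return Single-channel matrix with values in `{0, 10, 40, 180}`.
#' @export
recode_channels <- function(img, min_signal = 20) {
  if (length(dim(img)) != 3L) abort_input("recode_channels expects RGB input")
  red <- img[, , 1]; blue <- img[, , 3]
  th_b <- otsu255(blue, min_signal)
  blue_pos <- if (is.na(th_b)) matrix(FALSE, nrow(blue), ncol(blue)) else
    blue > th_b
  profile <- fill_holes(blue_pos)
  th_r <- otsu255(red, min_signal)
  red_pos <- if (is.na(th_r)) matrix(FALSE, nrow(red), ncol(red)) else
    red > th_r
  out <- matrix(0, nrow(blue), ncol(blue))
  out[profile] <- 40
  out[blue_pos] <- 10
  out[red_pos] <- 180
  out
}

#' Merge canonical layers with equal weights
#'
#' Pixel-wise mean of the layers, except that canonical positive values
#' survive merging: a pixel carrying 180 (or 10) in any layer keeps that
#' value, with 180 taking precedence, so positive fluorescence cells are
#' never washed out by the grey tissue profile.
#'
#' @param layers List of equally sized single-channel matrices.
#' @return Merged matrix.
#' @export
merge_layers <- function(layers) {
  if (!length(layers)) abort_input("no layers to merge")
  dims <- vapply(layers, dim, numeric(2))
  if (any(dims != dims[, 1])) abort_input("layers must share dimensions")
  out <- Reduce(`+`, layers) / length(layers)
  any10 <- Reduce(`|`, lapply(layers, function(l) l == 10))
  any180 <- Reduce(`|`, lapply(layers, function(l) l == 180))
  out[any10] <- 10
  out[any180] <- 180
  out
}

#' Intensity histograms before/after pre-treatment
#'
#' 256-bin intensity histograms per channel for two images plus summary
#' statistics (mean shift and standard-deviation ratio), quantifying what
#' the pre-treatment (enhancement/recoding) did to the intensity
#' distribution. Reported only; never used as a filter.
#'
#' @param before,after Images of identical shape (0--255).
#' @return List: `histograms` (`before`/`after`, one 256-vector per
#'   channel), `mean_shift`, `sd_ratio`.
#' @export
frequency_analysis <- function(before, after) {
  if (!identical(dim(before), dim(after))) {
    abort_input("before and after must share dimensions")
  }
  hist_of <- function(img) {
    if (length(dim(img)) == 3L) {
      lapply(seq_len(dim(img)[3]),
             function(k) tabulate(clip255(floor(img[, , k])) + 1L,
                                  nbins = 256L))
    } else {
      list(tabulate(clip255(floor(img)) + 1L, nbins = 256L))
    }
  }
  sdb <- stats::sd(before)
  list(histograms = list(before = hist_of(before), after = hist_of(after)),
       mean_shift = mean(after) - mean(before),
       sd_ratio = if (sdb == 0) NA_real_ else stats::sd(after) / sdb)
}

#' Assemble aligned slices into a volume
#'
#' @param layers List of equally sized single-channel matrices in slice
#'   order (or a [section_stack()] of single-channel images).
#' @param pixel_size_um In-plane pixel size.
#' @param dz_um Section thickness (slice spacing, default 10 um).
#' @return A [volume_grid()].
#' @export
build_volume <- function(layers, pixel_size_um = 1, dz_um = 10) {
  if (inherits(layers, "SectionStack")) {
    pixel_size_um <- layers$pixel_size_um
    dz_um <- layers$dz_um
    layers <- layers$images
  }
  dims <- vapply(layers, dim, numeric(2))
  if (any(dims != dims[, 1])) abort_input("slices must share dimensions")
  vol <- array(0, c(dims[1, 1], dims[2, 1], length(layers)))
  for (i in seq_along(layers)) vol[, , i] <- layers[[i]]
  volume_grid(vol, spacing = c(pixel_size_um, pixel_size_um, dz_um))
}

#' Write a volume as legacy ASCII VTK (STRUCTURED_POINTS)
#'
#' @param vol A [volume_grid()].
#' @param path Output file path.
#' @param name Scalar field name.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(vol, path, name = "intensity") {
  if (!inherits(vol, "Volume")) abort_input("vol must be a Volume")
  d <- dim(vol$data)                      # (ny, nx, nz)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort_input(sprintf("cannot open '%s' for writing", path))
  })
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "ccsmap serial-section reconstruction",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[2], d[1], d[3]),
    sprintf("SPACING %.10g %.10g %.10g", vol$spacing[1], vol$spacing[2],
            vol$spacing[3]),
    sprintf("ORIGIN %.10g %.10g %.10g", vol$origin[1], vol$origin[2],
            vol$origin[3]),
    sprintf("POINT_DATA %d", prod(d)),
    sprintf("SCALARS %s float 1", name),
    "LOOKUP_TABLE default"), con)
  # x fastest, then y, then z.
  vals <- as.vector(aperm(vol$data, c(2, 1, 3)))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 9)),
                    function(v) paste(sprintf("%.17g", v), collapse = " "),
                    character(1), USE.NAMES = FALSE), con)
  invisible(path)
}

#' Read a legacy ASCII VTK STRUCTURED_POINTS file
#'
#' @param path File written by [write_vtk()].
#' @return A [volume_grid()].
#' @export
read_vtk <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1]])
  }
  dims <- grab("DIMENSIONS")              # nx ny nz
  spacing <- grab("SPACING")
  origin <- grab("ORIGIN")
  start <- grep("^LOOKUP_TABLE", lines)[1] + 1L
  vals <- as.numeric(unlist(strsplit(lines[start:length(lines)], " +")))
  vals <- vals[!is.na(vals)]
  arr <- aperm(array(vals, c(dims[1], dims[2], dims[3])), c(2, 1, 3))
  volume_grid(arr, spacing = spacing, origin = origin)
}

#' End-to-end serial-section reconstruction
#'
#' Unifies resolution, registers the stack (chained rigid alignment),
#' optionally enhances contrast, recodes every aligned slice into the
#' canonical 0/10/40/180 layer, and assembles the volume; a frequency
#' analysis of the first slice before/after pre-treatment is attached.
#'
#' @param stack A [section_stack()] of RGB slices.
#' @param downsample_factor Resolution-unification factor (1 = none).
#' @param gain,bias Contrast enhancement parameters.
#' @param search_deg,step_deg Registration search parameters.
#' @param min_signal Channel-emptiness guard for binarisation.
#' @return List: `volume` ([volume_grid()]), `transforms`, `aligned`
#'   (aligned RGB stack), `frequency` ([frequency_analysis()] of slice 1).
#' @export
reconstruct_sections <- function(stack, downsample_factor = 1L, gain = 1,
                                 bias = 0, search_deg = 10, step_deg = 0.25,
                                 min_signal = 20) {
  stack <- unify_resolution(stack, downsample_factor)
  reg <- register_slices(stack, search_deg = search_deg,
                         step_deg = step_deg, min_signal = min_signal)
  enhanced <- lapply(reg$aligned$images, enhance, gain = gain, bias = bias)
  recoded <- lapply(enhanced, recode_channels, min_signal = min_signal)
  freq <- frequency_analysis(reg$aligned$images[[1]][, , 1], recoded[[1]])
  vol <- build_volume(recoded, pixel_size_um = reg$aligned$pixel_size_um,
                      dz_um = reg$aligned$dz_um)
  list(volume = vol, transforms = reg$transforms, aligned = reg$aligned,
       frequency = freq)
}
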