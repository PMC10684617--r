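# Rigid 2D transforms on raster images.
#
# Convention: a rigid transform (theta, dx, dy) maps an input point p
# (x = column, y = row, both 1-based) to q = R(theta) (p - c) + c + t,
# where c is the image centre ((W+1)/2, (H+1)/2) and t = (dx, dy).
# Warping resamples by inverse mapping; points falling outside the source
# are set to `fill`.

rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid (rotation + translation) transform to an image
#'
#' Rotation is about the image centre, in degrees, with positive angles
#' rotating the content counter-clockwise in standard x-right/y-down raster
#' coordinates; translation is in pixels.
#'
#' @param img Numeric matrix (`height x width`) or array
#'   (`height x width x channels`).
#' @param rotation_deg Rotation angle in degrees.
#' @param dx,dy Translation in pixels (columns, rows).
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @param fill Value for pixels mapped from outside the source.
#' @return Transformed image of the same shape.
#' @export
warp_rigid <- function(img, rotation_deg, dx = 0, dy = 0,
                       interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  if (length(dim(img)) == 3L) {
    out <- img
    for (k in seq_len(dim(img)[3])) {
      out[, , k] <- warp_rigid(img[, , k], rotation_deg, dx, dy, interp,
                               fill)
    }
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  qx <- matrix(rep(seq_len(w), each = h), h, w)
  qy <- matrix(rep(seq_len(h), times = w), h, w)
  R <- rot_mat(-rotation_deg)            # inverse rotation
  ux <- qx - cx - dx
  uy <- qy - cy - dy
  px <- R[1, 1] * ux + R[1, 2] * uy + cx
  py <- R[2, 1] * ux + R[2, 2] * uy + cy
  out <- matrix(fill, h, w)
  if (interp == "nearest") {
    ix <- round(px); iy <- round(py)
    ok <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
    out[ok] <- img[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
    i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    fxo <- fx[ok]; fyo <- fy[ok]
    out[ok] <- img[i00] * (1 - fxo) * (1 - fyo) +
      img[i01] * fxo * (1 - fyo) +
      img[i10] * (1 - fxo) * fyo +
      img[i11] * fxo * fyo
  }
  out
}

#' Invert a rigid transform
#'
#' @param rotation_deg,dx,dy Forward transform parameters.
#' @return List `(rotation_deg, dx, dy)` such that applying it after the
#'   forward transform restores the original image (up to resampling).
#' @export
invert_rigid <- function(rotation_deg, dx, dy) {
  R <- rot_mat(-rotation_deg)
  t_inv <- -as.vector(R %*% c(dx, dy))
  list(rotation_deg = -rotation_deg, dx = t_inv[1], dy = t_inv[2])
}
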