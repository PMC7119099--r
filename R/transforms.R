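# Rigid 3-D transforms and grid resampling.
#
# A rigid_transform maps physical points (mm) from a source space to a
# target space:  p' = R (p - center) + center + t, with R built from Euler
# angles (degrees) applied in Z-Y-X order.

#' Create a rigid 3-D transform
#'
#' Six-parameter (rotation + translation) transform between physical spaces,
#' used to relate the T1 grid to the Dixon grid. Angles are Euler angles in
#' degrees applied about the z, then y, then x axis; rotation is taken about
#' `center`.
#'
#' @param rotation numeric length-3, Euler angles (degrees) about (x, y, z).
#' @param translation numeric length-3, translation (mm).
#' @param center numeric length-3, rotation centre (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L,
            all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.3f, %.3f, %.3f) deg, t (%.3f, %.3f, %.3f) mm\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Apply a rigid transform to physical points
#'
#' @param tf a [rigid_transform].
#' @param pts n x 3 matrix of (x, y, z) points in mm.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  R <- rotation_matrix(tf$rotation)
  sweep(sweep(pts, 2, tf$center) %*% t(R), 2,
        tf$center + tf$translation, "+")
}

#' Invert a rigid transform
#'
#' Composing a transform with its inverse reproduces the identity to within
#' floating-point tolerance.
#'
#' @param tf a [rigid_transform].
#' @return The inverse `rigid_transform` (expressed with the same centre).
#' @export
invert_transform <- function(tf) {
  R <- rotation_matrix(tf$rotation)
  Rinv <- t(R)
  # p = Rinv (p' - center - t) + center = Rinv (p' - center) + center + t'
  # with t' = Rinv(-t) expressed about the same centre:
  tinv <- as.numeric(Rinv %*% (-tf$translation))
  ang <- euler_from_matrix(Rinv)
  rigid_transform(rotation = ang, translation = tinv, center = tf$center)
}

# recover (x, y, z) Euler angles (deg) from R = Rx Ry Rz
euler_from_matrix <- function(R) {
  sy <- R[1, 3]
  y <- asin(pmin(1, pmax(-1, sy)))
  if (abs(cos(y)) > 1e-9) {
    x <- atan2(-R[2, 3], R[3, 3])
    z <- atan2(-R[1, 2], R[1, 1])
  } else {  # gimbal lock
    x <- atan2(R[3, 2], R[2, 2])
    z <- 0
  }
  c(x, y, z) * 180 / pi
}

# Trilinear / nearest-neighbour sampling of img at physical points (mm).
# Points outside the grid get `outside`.
sample_volume <- function(img, pts, interp = c("linear", "nearest"),
                          outside = 0) {
  interp <- match.arg(interp)
  d <- dim(img$data); s <- img$spacing; o <- img$origin
  # continuous 0-based indices
  ic <- (pts[, 1] - o[1]) / s[1]   # col
  ir <- (pts[, 2] - o[2]) / s[2]   # row
  is_ <- (pts[, 3] - o[3]) / s[3]  # slice
  n <- length(ic)
  out <- rep(outside, n)
  if (interp == "nearest") {
    ci <- round(ic); ri <- round(ir); si <- round(is_)
    ok <- ci >= 0 & ci <= d[3] - 1 & ri >= 0 & ri <= d[2] - 1 &
      si >= 0 & si <= d[1] - 1
    lin <- 1 + si[ok] + d[1] * (ri[ok] + d[2] * ci[ok])
    out[ok] <- img$data[lin]
    return(out)
  }
  ok <- ic >= 0 & ic <= d[3] - 1 & ir >= 0 & ir <= d[2] - 1 &
    is_ >= 0 & is_ <= d[1] - 1
  if (!any(ok)) return(out)
  ic <- ic[ok]; ir <- ir[ok]; is_ <- is_[ok]
  c0 <- pmin(floor(ic), d[3] - 2); r0 <- pmin(floor(ir), d[2] - 2)
  s0 <- pmin(floor(is_), d[1] - 2)
  c0 <- pmax(c0, 0); r0 <- pmax(r0, 0); s0 <- pmax(s0, 0)
  fc <- ic - c0; fr <- ir - r0; fs <- is_ - s0
  at <- function(si, ri, ci) img$data[1 + si + d[1] * (ri + d[2] * ci)]
  v000 <- at(s0, r0, c0);     v001 <- at(s0, r0, c0 + 1)
  v010 <- at(s0, r0 + 1, c0); v011 <- at(s0, r0 + 1, c0 + 1)
  v100 <- at(s0 + 1, r0, c0);     v101 <- at(s0 + 1, r0, c0 + 1)
  v110 <- at(s0 + 1, r0 + 1, c0); v111 <- at(s0 + 1, r0 + 1, c0 + 1)
  w00 <- v000 * (1 - fc) + v001 * fc
  w01 <- v010 * (1 - fc) + v011 * fc
  w10 <- v100 * (1 - fc) + v101 * fc
  w11 <- v110 * (1 - fc) + v111 * fc
  w0 <- w00 * (1 - fr) + w01 * fr
  w1 <- w10 * (1 - fr) + w11 * fr
  out[ok] <- w0 * (1 - fs) + w1 * fs
  out
}

# Resample `img` (defined in source space) onto the grid of `target`,
# where `tf` maps source space -> target space.
resample_to_grid <- function(img, tf, target, interp = "linear",
                             outside = 0) {
  pts <- voxel_coords(target)
  src_pts <- apply_transform(invert_transform(tf), pts)
  vals <- sample_volume(img, src_pts, interp = interp, outside = outside)
  volume_image(array(vals, dim = dim(target$data)),
               spacing = target$spacing, origin = target$origin)
}
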