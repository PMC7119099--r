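# Pre-processing: multiplicative bias-field removal and slice-wise hand
# cross-sectional-area extraction.

#' Bias-correction configuration
#'
#' The correction estimates a smooth multiplicative field in the log domain:
#' a low-order polynomial surface is fitted by iteratively reweighted least
#' squares over the dominant foreground tissue, so tissue contrast is not
#' absorbed into the field. The field is normalised to unit mean and the
#' corrected image preserves the global mean intensity.
#'
#' @param degree total polynomial degree of the log-field surface.
#' @param max_iter maximum reweighting iterations (>= 1).
#' @param tol convergence threshold on the relative change of the field.
#' @param inlier_mads half-width of the inlier band, in median absolute
#'   deviations of the corrected log intensity, that defines the dominant
#'   tissue used to fit the field.
#' @return Object of class `bias_correction_config`.
#' @export
bias_correction_config <- function(degree = 3L, max_iter = 5L, tol = 1e-4,
                                   inlier_mads = 2.5) {
  stopifnot(degree >= 1L, max_iter >= 1L, tol > 0, inlier_mads > 0)
  structure(list(degree = as.integer(degree), max_iter = as.integer(max_iter),
                 tol = tol, inlier_mads = inlier_mads),
            class = "bias_correction_config")
}

# polynomial basis in normalised coordinates up to total degree `deg`
poly_basis <- function(pts, deg) {
  rng <- apply(pts, 2, range)
  u <- 2 * (pts[, 1] - rng[1, 1]) / max(rng[2, 1] - rng[1, 1], 1e-9) - 1
  v <- 2 * (pts[, 2] - rng[1, 2]) / max(rng[2, 2] - rng[1, 2], 1e-9) - 1
  w <- 2 * (pts[, 3] - rng[1, 3]) / max(rng[2, 3] - rng[1, 3], 1e-9) - 1
  cols <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) for (k in 0:(deg - i - j)) {
    cols[[length(cols) + 1L]] <- u^i * v^j * w^k
  }
  do.call(cbind, cols)
}

# Otsu threshold on a numeric vector (256-bin histogram), via EBImage
otsu_threshold <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  xn <- (x - lo) / (hi - lo)
  n <- length(xn)
  side <- ceiling(sqrt(n))
  pad <- rep(xn[n], side * side - n)
  m <- matrix(c(xn, pad), side, side)
  th <- EBImage::otsu(EBImage::Image(m), range = c(0, 1), levels = 256)
  lo + th * (hi - lo)
}

#' Remove the multiplicative bias field from a T1 volume
#'
#' MRI intensities are modulated by a smooth multiplicative bias field from
#' coil/field inhomogeneity; intensity-based segmentation requires its
#' removal. The field is estimated in the log domain as a smooth polynomial
#' surface fitted over the dominant tissue (selected by iterative
#' robust reweighting so that genuine tissue contrast is not flattened),
#' then normalised so the corrected image keeps the input's global mean.
#'
#' @param img a [volume_image] with non-negative intensities and some
#'   foreground signal.
#' @param cfg a [bias_correction_config].
#' @return A list with `corrected` (the bias-corrected [volume_image]) and
#'   `field` (the estimated multiplicative field, mean approximately 1).
#' @export
correct_bias_field <- function(img, cfg = bias_correction_config()) {
  stopifnot(inherits(img, "volume_image"))
  x <- as.numeric(img$data)
  if (max(x) <= 0)
    stop("degenerate input: image has no positive intensities", call. = FALSE)
  thr <- otsu_threshold(x)
  fg <- which(x > thr & x > 0)
  if (length(fg) < 100)
    stop("degenerate input: too little foreground above threshold",
         call. = FALSE)
  pts <- voxel_coords(img)
  B_all <- poly_basis(pts, cfg$degree)
  B <- B_all[fg, , drop = FALSE]
  logx <- log(x[fg])

  logfield_fg <- rep(0, length(fg))
  inl <- seq_along(fg)
  cf_total <- rep(0, ncol(B))
  for (it in seq_len(cfg$max_iter)) {
    res <- logx - logfield_fg
    fit <- stats::lm.fit(B[inl, , drop = FALSE], res[inl])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    delta <- as.numeric(B %*% cf)
    # the constant term is tissue level, not bias: centre the increment
    delta <- delta - mean(delta)
    logfield_fg <- logfield_fg + delta
    cf_total <- cf_total + cf
    corrected_log <- logx - logfield_fg
    med <- median(corrected_log[inl])
    s <- mad(corrected_log[inl])
    if (s <= 0) break
    inl <- which(abs(corrected_log - med) <= cfg$inlier_mads * s)
    if (length(inl) < ncol(B) + 5) break
    if (max(abs(delta)) < cfg$tol) break
  }
  logfield <- as.numeric(B_all %*% cf_total)
  logfield <- logfield - mean(logfield[fg])
  # the polynomial is only supported by foreground voxels; clamp the
  # extrapolated field outside to the range attained over the foreground
  logfield <- pmin(pmax(logfield, min(logfield[fg])), max(logfield[fg]))
  field <- exp(array(logfield, dim = dim(img$data)))
  corrected <- img$data / field
  # preserve the global mean intensity exactly
  sc <- mean(img$data) / mean(corrected)
  corrected <- corrected * sc
  field <- field / sc
  list(corrected = volume_image(corrected, spacing = img$spacing,
                                origin = img$origin),
       field = volume_image(field, spacing = img$spacing,
                            origin = img$origin))
}

#' Hand-mask extraction configuration
#'
#' @param threshold fixed intensity threshold, or `NULL` for automatic.
#'   The automatic threshold is Otsu on the slice histogram scaled by
#'   `otsu_fraction`: Otsu locates the bright-muscle/dark-tissue split, and
#'   the fraction lowers it so that dark tissues (subcutaneous fat, bone,
#'   tendon) above the air floor are kept in the hand area. Because Otsu's
#'   threshold scales linearly with intensity, the automatic mask is
#'   invariant to global intensity rescaling.
#' @param otsu_fraction multiplier applied to the Otsu threshold in
#'   automatic mode, in `(0, 1]`.
#' @param closing_radius radius (voxels) of the in-plane morphological
#'   closing that fills internal hypointense structures (bone, tendon) into
#'   the hand area; internal holes are filled afterwards.
#' @param min_area_mm2 minimum connected-component area per slice (mm^2);
#'   smaller islands are discarded.
#' @return Object of class `hand_mask_config`.
#' @export
hand_mask_config <- function(threshold = NULL, otsu_fraction = 0.25,
                             closing_radius = 3L, min_area_mm2 = 50) {
  stopifnot(closing_radius >= 0, min_area_mm2 >= 0,
            otsu_fraction > 0, otsu_fraction <= 1)
  structure(list(threshold = threshold, otsu_fraction = otsu_fraction,
                 closing_radius = as.integer(closing_radius),
                 min_area_mm2 = min_area_mm2),
            class = "hand_mask_config")
}

#' Extract the per-slice hand cross-sectional area mask
#'
#' For each slice: intensity threshold (automatic Otsu by default, so the
#' mask is invariant to global intensity scaling), morphological closing to
#' fill internal hypointense structures, then removal of connected
#' components below the minimum area. Slices with no above-threshold signal
#' yield an empty contour; only an entirely empty volume is an error.
#'
#' @param img bias-corrected [volume_image].
#' @param cfg a [hand_mask_config].
#' @return A [binary_mask] on the grid of `img`.
#' @export
extract_hand_mask <- function(img, cfg = hand_mask_config()) {
  stopifnot(inherits(img, "volume_image"))
  d <- dim(img$data)
  out <- array(0L, dim = d)
  min_px <- cfg$min_area_mm2 / (img$spacing[1] * img$spacing[2])
  brush <- if (cfg$closing_radius > 0)
    EBImage::makeBrush(2L * cfg$closing_radius + 1L, shape = "disc") else NULL
  glob_thr <- cfg$threshold
  # volume-level signal floor: slices with no intensity above it contain no
  # hand (beyond the fingertips) and yield empty contours
  x <- as.numeric(img$data)
  thr_full <- otsu_threshold(x)
  if (is.null(glob_thr)) {
    # a volume with no tissue/air contrast (noise only) has nothing to
    # segment: foreground and background split of a pure-noise histogram
    # have comparable means
    bg_mean <- mean(x[x <= thr_full])
    fg_mean <- mean(x[x > thr_full])
    if (!is.finite(fg_mean) ||
        (is.finite(bg_mean) && bg_mean > 0 && fg_mean / bg_mean < 3))
      stop("hand segmentation failed: no foreground/background contrast",
           call. = FALSE)
  }
  vol_thr <- if (is.null(glob_thr)) thr_full * cfg$otsu_fraction else glob_thr
  for (s in seq_len(d[1])) {
    sl <- img$data[s, , ]
    if (max(sl) <= vol_thr) next
    if (is.null(glob_thr)) {
      if (max(sl) <= min(sl) || max(sl) <= 0) next
      thr <- otsu_threshold(as.numeric(sl)) * cfg$otsu_fraction
    } else {
      thr <- glob_thr
    }
    bw <- (sl > thr) * 1
    if (!any(bw == 1)) next
    if (!is.null(brush))
      bw <- EBImage::closing(bw, brush)
    bw <- EBImage::fillHull(bw)
    lab <- EBImage::bwlabel(bw)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      keep <- which(sizes >= min_px)
      bw <- matrix(as.integer(lab %in% keep), nrow(sl), ncol(sl))
    }
    out[s, , ] <- bw
  }
  if (sum(out) == 0)
    stop("hand segmentation failed: empty mask on every slice", call. = FALSE)
  binary_mask(out, reference = img)
}
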