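# Two-point Dixon fat-fraction computation and rigid multimodal transfer of
# the T1-derived muscle VOI onto the fat-fraction grid.

#' Compute the quantitative fat-fraction image from a Dixon pair
#'
#' For water image W and fat image F the fat fraction is
#' `F / (W + F) * 1000`, rounded to integer grey values: the map ranges
#' from 0 (0% fat) to 1000 (100% fat), i.e. 1 grey value = 0.1% fat.
#' Voxels with `W + F = 0` (air) are set to 0 and flagged invalid.
#'
#' @param water,fat [volume_image]s on the same grid with non-negative
#'   values.
#' @return A `fat_fraction_image`: a [volume_image] with integer data in
#'   `[0, 1000]` plus a `valid` 0/1 array marking voxels with signal.
#' @examples
#' w <- volume_image(array(900, c(2, 2, 2)))
#' f <- volume_image(array(100, c(2, 2, 2)))
#' compute_fat_fraction(w, f)$data[1]  # 100, i.e. 10.0% fat
#' @export
compute_fat_fraction <- function(water, fat) {
  stopifnot(inherits(water, "volume_image"), inherits(fat, "volume_image"))
  check_same_grid(water, fat, "water and fat images")
  if (min(water$data) < 0 || min(fat$data) < 0)
    stop("Dixon images must be non-negative", call. = FALSE)
  tot <- water$data + fat$data
  valid <- tot > 0
  ffv <- array(0, dim = dim(tot))
  ffv[valid] <- round(fat$data[valid] / tot[valid] * 1000)
  img <- volume_image(ffv, spacing = water$spacing, origin = water$origin)
  img$valid <- array(as.integer(valid), dim = dim(tot))
  class(img) <- c("fat_fraction_image", class(img))
  img
}

#' Rigid registration configuration
#'
#' @param bins joint-histogram bins per channel for the mutual-information
#'   metric.
#' @param levels multi-resolution levels (coarse-to-fine sampling strides).
#' @param max_iter optimizer iteration cap per level.
#' @param tol relative convergence tolerance of the optimizer.
#' @param sample_fraction fraction of in-mask voxels used for the metric
#'   (1 = all).
#' @param seed seed for metric voxel sampling.
#' @return Object of class `registration_config`.
#' @export
registration_config <- function(bins = 32L, levels = 3L, max_iter = 400L,
                                tol = 1e-9, sample_fraction = 1,
                                seed = 1L) {
  stopifnot(bins >= 8L, levels >= 1L, max_iter >= 1L, tol > 0,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(bins = as.integer(bins), levels = as.integer(levels),
                 max_iter = as.integer(max_iter), tol = tol,
                 sample_fraction = sample_fraction, seed = as.integer(seed)),
            class = "registration_config")
}

# mutual information of two paired samples via a joint histogram
mutual_information <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) <= 0 || diff(rb) <= 0) return(0)
  ia <- pmin(floor((a - ra[1]) / diff(ra) * bins) + 1L, bins)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * bins) + 1L, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- p > 0
  outer_xy <- as.numeric(outer(px, py))
  sum(p[nz] * log(p[nz] / outer_xy[nz]))
}

#' Rigid multimodal registration of the T1 hand onto a Dixon-space image
#'
#' Estimates the 6-parameter rigid transform (T1 space to Dixon space) that
#' maximises the mutual information between the moving T1 image and the
#' fixed target (typically the fat-fraction image), evaluated over the
#' fixed-image voxels whose mapped position falls inside the moving hand.
#' The optimisation is multi-resolution (coarse sampling first) with a
#' Nelder-Mead simplex, initialised by aligning the intensity centroids of
#' the two hands.
#'
#' @param t1 bias-corrected moving [volume_image].
#' @param t1_hand hand [binary_mask] on the T1 grid.
#' @param dixon_ref fixed [volume_image] in Dixon space (e.g. the
#'   fat-fraction image).
#' @param cfg a [registration_config].
#' @return A list: `transform` (the fitted [rigid_transform], T1 to Dixon),
#'   `metric` (final mutual information), `converged`, and the optimizer
#'   diagnostics.
#' @export
register_rigid <- function(t1, t1_hand, dixon_ref,
                           cfg = registration_config()) {
  stopifnot(inherits(t1, "volume_image"), inherits(t1_hand, "binary_mask"),
            inherits(dixon_ref, "volume_image"))
  check_same_grid(t1, t1_hand, "T1 image and hand mask")
  set.seed(cfg$seed)
  hand_idx <- which(t1_hand$data == 1)
  t1_pts <- voxel_coords(t1)[hand_idx, , drop = FALSE]
  w <- t1$data[hand_idx]
  mov_centroid <- colSums(t1_pts * w) / sum(w)

  fix_pts_all <- voxel_coords(dixon_ref)
  fix_vals_all <- as.numeric(dixon_ref$data)
  fthr <- otsu_threshold(fix_vals_all) * 0.25
  fg <- which(fix_vals_all > fthr)
  if (length(fg) < 200)
    stop("registration failure: fixed image has too little signal",
         call. = FALSE)
  fix_centroid <- colSums(fix_pts_all[fg, , drop = FALSE] * fix_vals_all[fg]) /
    sum(fix_vals_all[fg])
  center <- mov_centroid
  t_init <- fix_centroid - mov_centroid

  hand_mask_img <- volume_image((t1_hand$data == 1) * 1,
                                spacing = t1$spacing, origin = t1$origin)

  # the sample set (fixed foreground voxels) never changes with the
  # parameters; out-of-volume moving samples read as 0, so the metric is a
  # smooth function of the transform with no overlap-driven discontinuities
  metric_at <- function(par, pts, vals) {
    tf <- rigid_transform(rotation = par[1:3], translation = par[4:6],
                          center = center)
    src <- apply_transform(invert_transform(tf), pts)
    inside <- sample_volume(hand_mask_img, src, interp = "nearest") > 0.5
    if (mean(inside) < 0.05) return(1e6)
    # the sample positions are the fixed image's hand voxels, so the metric
    # is hand-driven; the moving image is sampled unmasked because the hard
    # zero edge of a masked volume biases the slice-direction optimum
    mv <- sample_volume(t1, src, interp = "linear", outside = 0)
    -mutual_information(mv, vals, cfg$bins)
  }

  sub_at <- function(st) {
    sub <- fg[seq(1, length(fg), by = st)]
    if (cfg$sample_fraction < 1) {
      keep <- sort(sample(length(sub),
                          max(200, round(cfg$sample_fraction * length(sub)))))
      sub <- sub[keep]
    }
    sub
  }

  # joint coarse search over in-plane rotation (the dominant rotational
  # degree of freedom for an axial hand stack) and translation around the
  # centroid initialisation, on a decimated sample
  sub <- sub_at(2L^cfg$levels)
  pts <- fix_pts_all[sub, , drop = FALSE]; vals <- fix_vals_all[sub]
  best <- c(0, 0, 0, t_init); bestm <- metric_at(best, pts, vals)
  for (rz in c(-6, -3, 0, 3, 6)) for (dz in c(-4, 0, 4))
    for (dy in c(-3, 0, 3)) for (dx in c(-3, 0, 3)) {
      cand <- c(0, 0, rz, t_init + c(dx, dy, dz))
      m <- metric_at(cand, pts, vals)
      if (m < bestm) { bestm <- m; best <- cand }
    }

  par <- best
  strides <- rev(2L^(seq_len(cfg$levels) - 1L))  # e.g. 4, 2, 1
  conv <- 1L
  for (st in strides) {
    sub <- sub_at(st)
    pts <- fix_pts_all[sub, , drop = FALSE]
    vals <- fix_vals_all[sub]
    # simplex restarts: rerun from the previous optimum until no improvement
    prev <- Inf
    for (rs in 1:3) {
      opt <- optim(par, metric_at, pts = pts, vals = vals,
                   method = "Nelder-Mead",
                   control = list(maxit = cfg$max_iter, reltol = cfg$tol,
                                  parscale = c(2, 2, 2, 1, 1, 1)))
      par <- opt$par
      conv <- opt$convergence
      if (prev - opt$value < 1e-6) break
      prev <- opt$value
    }
  }
  final_metric <- -metric_at(par, fix_pts_all[fg, , drop = FALSE],
                             fix_vals_all[fg])
  if (!is.finite(final_metric) || final_metric <= 0)
    stop("registration failure: no usable overlap between the images",
         call. = FALSE)
  list(transform = rigid_transform(rotation = par[1:3],
                                   translation = par[4:6], center = center),
       metric = final_metric, converged = conv == 0L)
}

#' Transfer the muscle VOI onto the fat-fraction grid
#'
#' Applies a rigid transform (T1 space to Dixon space) to the muscle mask
#' and resamples it onto the target grid with nearest-neighbour
#' interpolation, preserving binary values.
#'
#' @param muscle muscle [binary_mask] on the T1 grid.
#' @param transform [rigid_transform] from T1 space to the target space.
#' @param target [volume_image] (or fat-fraction image) defining the
#'   output grid.
#' @return [binary_mask] on the target grid. A transform that maps the VOI
#'   entirely outside the target yields an empty mask with a warning.
#' @export
transfer_voi <- function(muscle, transform, target) {
  stopifnot(inherits(muscle, "binary_mask"),
            inherits(transform, "rigid_transform"),
            inherits(target, "volume_image"))
  msk_img <- volume_image(muscle$data * 1, spacing = muscle$spacing,
                          origin = muscle$origin)
  res <- resample_to_grid(msk_img, transform, target, interp = "nearest",
                          outside = 0)
  out <- binary_mask(array(as.integer(res$data > 0.5), dim = dim(res$data)),
                     spacing = target$spacing, origin = target$origin)
  if (sum(muscle$data) > 0 && sum(out$data) == 0)
    warning("transferred VOI falls entirely outside the target grid")
  out
}
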