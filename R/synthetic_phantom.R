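# Synthetic hand phantoms: T1 + Dixon pairs with exact ground truth.
#
# The phantom is schematic -- a palm slab with metacarpal "bones", tendon and
# vessel distractors, a subcutaneous fat rim and finger cylinders -- not an
# anatomical model. It provides what the pipeline consumes: intensity
# contrast between compartments, slice-wise connectivity, hypo/hyperintense
# distractors, a smooth multiplicative bias field, and a known rigid offset
# between the T1 and Dixon grids.

# compartment label codes
LBL <- c(background = 0L, muscle = 1L, bone = 2L, tendon = 3L,
         vessel = 4L, fat = 5L)

#' Specification of a synthetic hand phantom
#'
#' Defaults use a grid downscaled from the clinical acquisition geometry
#' (320 x 320 in-plane at 0.5 x 0.5 mm, 64 slices of 3.0 mm) to
#' 96 x 96 x 24 at 1.0 x 1.0 x 3.0 mm so that a full pipeline run takes
#' seconds. The Dixon pair is generated on its own coarser slice stack
#' (half the T1 slice count, mirroring the clinical protocol's shorter
#' Dixon coverage) displaced by a known rigid transform.
#'
#' Tissue intensities are free parameters of the phantom (arbitrary units
#' chosen for contrast): muscle is the dominant mid-intensity tissue,
#' tendons are hypointense, vessels hyperintense, and subcutaneous fat is
#' dark on the fat-suppressed T1 but almost pure fat on the Dixon pair.
#'
#' @param shape integer length-3, grid shape `(slices, rows, cols)`.
#' @param spacing numeric length-3, `(dx, dy, dz)` mm.
#' @param t1_means named intensities for
#'   `background, muscle, bone, tendon, vessel, fat` in the T1 channel.
#' @param dixon_totals named total (water+fat) Dixon signal per compartment.
#' @param fat_fractions named true fat fraction per compartment, in `[0, 1]`.
#' @param noise_sd Gaussian noise SD added to every channel (0 = noiseless).
#' @param bias_amplitude peak log-amplitude of the multiplicative bias field
#'   (0 disables it); the field is `exp(P)` for a smooth random quadratic
#'   `P` scaled to this maximum absolute value.
#' @param dixon_transform a [rigid_transform] mapping T1 space to Dixon
#'   space (default 2 mm translation and 3 degree in-plane rotation).
#' @param dixon_slices slice count of the Dixon stack.
#' @param seed integer seed; the same spec and seed reproduce the phantom
#'   bit for bit.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 96, 96),
                         spacing = c(1.0, 1.0, 3.0),
                         t1_means = c(background = 2, muscle = 100, bone = 35,
                                      tendon = 30, vessel = 190, fat = 25),
                         dixon_totals = c(background = 2, muscle = 120,
                                          bone = 60, tendon = 50, vessel = 140,
                                          fat = 150),
                         fat_fractions = c(background = 0, muscle = 0.10,
                                           bone = 0.40, tendon = 0.05,
                                           vessel = 0.02, fat = 0.90),
                         noise_sd = 3,
                         bias_amplitude = 0.25,
                         dixon_transform = rigid_transform(
                           rotation = c(0, 0, 3),
                           translation = c(2, -1.5, 1)),
                         dixon_slices = NULL,
                         seed = 1L) {
  tissues <- names(LBL)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            all(tissues %in% names(t1_means)),
            all(tissues %in% names(dixon_totals)),
            all(tissues %in% names(fat_fractions)),
            all(t1_means >= 0), all(dixon_totals >= 0),
            all(fat_fractions >= 0 & fat_fractions <= 1),
            noise_sd >= 0, bias_amplitude >= 0,
            inherits(dixon_transform, "rigid_transform"))
  if (is.null(dixon_slices)) dixon_slices <- max(4L, round(shape[1] / 2))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 t1_means = t1_means[tissues],
                 dixon_totals = dixon_totals[tissues],
                 fat_fractions = fat_fractions[tissues],
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 dixon_transform = dixon_transform,
                 dixon_slices = as.integer(dixon_slices),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Label a set of physical points (n x 3, mm) with phantom compartments.
# The phantom geometry is analytic so both T1 and Dixon grids can be
# labelled consistently (the Dixon grid queries the geometry through the
# inverse of the stored rigid transform).
phantom_labels_at <- function(spec, pts) {
  nz <- spec$shape[1]
  ext <- c(spec$shape[3] * spec$spacing[1],   # x extent
           spec$shape[2] * spec$spacing[2],   # y extent
           nz * spec$spacing[3])              # z extent
  x <- pts[, 1] / ext[1]; y <- pts[, 2] / ext[2]; z <- pts[, 3] / ext[3]
  lbl <- rep(LBL[["background"]], nrow(pts))

  # palm: ellipse in (x, y) tapering along z (wrist narrow, knuckles wide),
  # z in [0.08, 0.72]
  in_palm_z <- z >= 0.08 & z <= 0.72
  taper <- 0.62 + 0.38 * pmin(pmax((z - 0.08) / 0.64, 0), 1)
  rx <- 0.30 * taper; ry <- 0.26 * taper
  d_pal <- ((x - 0.5) / rx)^2 + ((y - 0.48) / ry)^2
  in_palm <- in_palm_z & d_pal <= 1
  # subcutaneous fat rim: outer 18% of the palm radius
  in_rim <- in_palm & d_pal > 0.45
  lbl[in_palm] <- LBL[["muscle"]]
  lbl[in_rim] <- LBL[["fat"]]

  # metacarpal bones: four parallel rods along z inside the palm
  bone_cx <- c(0.38, 0.46, 0.54, 0.62)
  bone_r <- 0.050
  for (cx in bone_cx) {
    d <- sqrt((x - cx)^2 + ((y - 0.42) * ext[2] / ext[1])^2)
    lbl[in_palm_z & d <= bone_r & !in_rim] <- LBL[["bone"]]
  }
  # tendons: hypointense rods on the dorsal side
  for (cx in c(0.38, 0.50, 0.62)) {
    d <- sqrt((x - cx)^2 + ((y - 0.60) * ext[2] / ext[1])^2)
    lbl[in_palm_z & d <= 0.018 & !in_rim] <- LBL[["tendon"]]
  }
  # vessels: hyperintense rods on the palmar side
  for (cx in c(0.42, 0.58)) {
    d <- sqrt((x - cx)^2 + ((y - 0.33) * ext[2] / ext[1])^2)
    lbl[in_palm_z & d <= 0.014 & !in_rim] <- LBL[["vessel"]]
  }

  # fingers: four muscle cylinders continuing distally from the palm
  in_fing_z <- z > 0.72 & z <= 0.95
  for (cx in bone_cx) {
    d <- sqrt((x - cx)^2 + ((y - 0.46) * ext[2] / ext[1])^2)
    sel <- in_fing_z & d <= 0.055
    lbl[sel] <- LBL[["muscle"]]
    lbl[in_fing_z & d <= 0.022] <- LBL[["bone"]]
  }
  lbl
}

# smooth random quadratic log-bias field over a grid, scaled so that
# max |log field| = amplitude within the image
make_bias_field <- function(spec, img) {
  if (spec$bias_amplitude <= 0)
    return(array(1, dim = dim(img$data)))
  pts <- voxel_coords(img)
  ext <- apply(pts, 2, range)
  u <- 2 * (pts[, 1] - ext[1, 1]) / max(ext[2, 1] - ext[1, 1], 1) - 1
  v <- 2 * (pts[, 2] - ext[1, 2]) / max(ext[2, 2] - ext[1, 2], 1) - 1
  w <- 2 * (pts[, 3] - ext[1, 3]) / max(ext[2, 3] - ext[1, 3], 1) - 1
  basis <- cbind(u, v, w, u * v, u * w, v * w, u^2, v^2, w^2)
  cf <- rnorm(ncol(basis))
  p <- as.numeric(basis %*% cf)
  p <- p - mean(p)
  p <- p * (spec$bias_amplitude / max(abs(p)))
  array(exp(p), dim = dim(img$data))
}

#' Generate a synthetic hand phantom with ground truth
#'
#' Builds a T1-weighted volume (tissue mean x multiplicative bias field +
#' Gaussian noise) and a paired Dixon water/fat volume pair on a separate
#' grid related to the T1 grid by a known rigid transform. The water/fat
#' split satisfies `fat / (water + fat) = true fat fraction` exactly before
#' noise. All ground-truth quantities (label volumes, compartment volumes,
#' bias field, transform) are returned for oracle-style testing.
#'
#' @param spec a [phantom_spec].
#' @param bounds optional [analysis_bounds] for the truth volumes; default
#'   covers the palm slices.
#' @return A list with elements `t1`, `water`, `fat` ([volume_image]s),
#'   and `truth` (label arrays for both grids, true volumes `v_h`, `v_m`,
#'   `v_m_rel`, `v_f`, `v_f_rel`, the applied `bias_field`, the stored
#'   `transform` and the `bounds` used).
#' @export
generate_hand_phantom <- function(spec = phantom_spec(), bounds = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  t1_grid <- volume_image(array(0, dim = d), spacing = spec$spacing,
                          origin = c(0, 0, 0))
  pts <- voxel_coords(t1_grid)
  lbl <- phantom_labels_at(spec, pts)
  labels_t1 <- array(lbl, dim = d)

  tissue_names <- names(LBL)
  t1_mean <- spec$t1_means[match(lbl, LBL)]
  bias <- make_bias_field(spec, t1_grid)
  t1_vals <- t1_mean * as.numeric(bias)
  if (spec$noise_sd > 0)
    t1_vals <- pmax(t1_vals + rnorm(length(t1_vals), 0, spec$noise_sd), 0)
  t1 <- volume_image(array(t1_vals, dim = d), spacing = spec$spacing)

  # Dixon grid: fewer slices centred on the palm, displaced by the stored
  # transform (T1 -> Dixon)
  nzd <- spec$dixon_slices
  z0 <- ((d[1] - nzd) %/% 2) * spec$spacing[3]
  dixon_grid <- volume_image(array(0, dim = c(nzd, d[2], d[3])),
                             spacing = spec$spacing,
                             origin = c(0, 0, z0))
  tf <- spec$dixon_transform
  dpts <- voxel_coords(dixon_grid)
  src <- apply_transform(invert_transform(tf), dpts)
  # the Dixon acquisition images the same (voxelised) object on its own
  # grid: nearest-neighbour resampling of the T1-grid labels under the
  # stored transform, so truth labels on both grids are mutually consistent
  lbl_img <- volume_image(labels_t1 + 0, spacing = spec$spacing)
  dlbl <- as.integer(sample_volume(lbl_img, src, interp = "nearest",
                                   outside = LBL[["background"]]))
  labels_dixon <- array(dlbl, dim = dim(dixon_grid$data))

  total <- spec$dixon_totals[match(dlbl, LBL)]
  ff <- spec$fat_fractions[match(dlbl, LBL)]
  water_vals <- total * (1 - ff)
  fat_vals <- total * ff
  if (spec$noise_sd > 0) {
    water_vals <- pmax(water_vals + rnorm(length(water_vals), 0, spec$noise_sd), 0)
    fat_vals <- pmax(fat_vals + rnorm(length(fat_vals), 0, spec$noise_sd), 0)
  }
  water <- volume_image(array(water_vals, dim = dim(dixon_grid$data)),
                        spacing = dixon_grid$spacing, origin = dixon_grid$origin)
  fat <- volume_image(array(fat_vals, dim = dim(dixon_grid$data)),
                      spacing = dixon_grid$spacing, origin = dixon_grid$origin)

  if (is.null(bounds)) {
    # default analysis region: the palm slab (per-slice hand area at least
    # half the maximum), the analogue of the metacarpal-III interval
    csa <- apply(labels_t1 != LBL[["background"]], 1, sum)
    palm <- which(csa >= 0.5 * max(csa))
    bounds <- analysis_bounds(min(palm) - 1, max(palm) - 1)
  }
  sl <- seq(bounds$proximal_slice + 1, bounds$distal_slice + 1)
  vv <- voxel_volume(t1)
  hand_lab <- labels_t1 != LBL[["background"]]
  musc_lab <- labels_t1 == LBL[["muscle"]]
  v_h <- sum(hand_lab[sl, , ]) * vv
  v_m <- sum(musc_lab[sl, , ]) * vv
  musc_dix <- labels_dixon == LBL[["muscle"]]
  v_m_dix <- sum(musc_dix) * voxel_volume(water)
  v_f <- v_m_dix * spec$fat_fractions[["muscle"]]

  truth <- list(labels_t1 = labels_t1, labels_dixon = labels_dixon,
                label_codes = LBL,
                v_h = v_h, v_m = v_m, v_m_rel = v_m / v_h,
                v_f = v_f, v_f_rel = spec$fat_fractions[["muscle"]],
                bias_field = bias, transform = tf, bounds = bounds)
  list(t1 = t1, water = water, fat = fat, truth = truth, spec = spec)
}

#' Perturb a volume to emulate reanalysis variability
#'
#' The study quantifies segmentation reliability by repeated analysis of the
#' same scans. With a deterministic pipeline, repeats are generated by
#' adding small random intensity noise and a sub-voxel in-plane shift to the
#' input; magnitude 0 returns the input unchanged.
#'
#' @param img a [volume_image].
#' @param magnitude non-negative scale: noise SD as a fraction of the image's
#'   robust intensity range, and shift up to `magnitude` voxels.
#' @param seed integer seed for reproducible perturbation.
#' @return A perturbed [volume_image] on the same grid.
#' @export
perturb_for_reanalysis <- function(img, magnitude, seed = 1L) {
  stopifnot(inherits(img, "volume_image"), magnitude >= 0)
  if (magnitude == 0) return(img)
  set.seed(as.integer(seed))
  rng <- diff(quantile(img$data, c(0.01, 0.99), names = FALSE))
  shift <- runif(2, -magnitude, magnitude)  # in-plane, voxels
  pts <- voxel_coords(img)
  pts[, 1] <- pts[, 1] - shift[1] * img$spacing[1]
  pts[, 2] <- pts[, 2] - shift[2] * img$spacing[2]
  vals <- sample_volume(img, pts, interp = "linear")
  vals <- vals + rnorm(length(vals), 0, magnitude * rng * 0.05)
  volume_image(array(pmax(vals, 0), dim = dim(img$data)),
               spacing = img$spacing, origin = img$origin)
}
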