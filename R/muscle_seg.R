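# Random-forest voxel classification of muscle vs background within the
# hand mask, Gaussian histogram cleanup of the muscle VOI, and restriction
# to the metacarpal analysis bounds.

#' Voxel feature configuration
#'
#' Features are computed in-plane (per slice): raw intensity, Gaussian
#' smoothed intensity at two scales, local mean and SD in box neighbourhoods,
#' gradient magnitude, plus the 2-D distance to the hand boundary and the
#' normalised slice position. The classifier stores a fingerprint of this
#' configuration and refuses to predict with a different one.
#'
#' @param box_radii integer radii (voxels) of the local mean/SD boxes.
#' @param smooth_sigmas Gaussian smoothing scales in mm.
#' @param use_distance include the in-plane distance to the hand boundary.
#' @param use_slice_pos include the normalised slice index.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(box_radii = c(1L, 2L), smooth_sigmas = c(1, 2.5),
                           use_distance = TRUE, use_slice_pos = TRUE) {
  stopifnot(all(box_radii >= 0), all(smooth_sigmas > 0))
  if (length(box_radii) == 0 && length(smooth_sigmas) == 0 &&
      !use_distance && !use_slice_pos)
    stop("at least one feature must be enabled", call. = FALSE)
  structure(list(box_radii = as.integer(box_radii),
                 smooth_sigmas = as.numeric(smooth_sigmas),
                 use_distance = isTRUE(use_distance),
                 use_slice_pos = isTRUE(use_slice_pos)),
            class = "feature_config")
}

feature_fingerprint <- function(cfg) {
  paste0("fc1|radii=", paste(cfg$box_radii, collapse = ","),
         "|sigmas=", paste(format(cfg$smooth_sigmas, digits = 10), collapse = ","),
         "|dist=", cfg$use_distance, "|slice=", cfg$use_slice_pos)
}

# separable 2-D box filter via EBImage::filter2 with a flat brush
box_filter_slice <- function(m, r) {
  if (r == 0) return(m)
  k <- matrix(1 / (2 * r + 1)^2, 2 * r + 1, 2 * r + 1)
  EBImage::filter2(m, k, boundary = "replicate")
}

gauss_filter_slice <- function(m, sigma_px) {
  size <- max(3L, 2L * ceiling(3 * sigma_px) + 1L)
  size <- min(size, 2L * ((min(dim(m)) - 1L) %/% 2L) + 1L)  # filter <= image
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  EBImage::filter2(m, k, boundary = "replicate")
}

#' Extract per-voxel features inside the hand mask
#'
#' @param img bias-corrected [volume_image].
#' @param hand non-empty hand [binary_mask] on the grid of `img`.
#' @param cfg a [feature_config].
#' @return A data frame with one row per hand voxel (in array order) and one
#'   column per feature, with attributes `voxel_index` (linear indices into
#'   the volume) and `fingerprint`.
#' @export
extract_voxel_features <- function(img, hand, cfg = feature_config()) {
  stopifnot(inherits(img, "volume_image"), inherits(hand, "binary_mask"))
  check_same_grid(img, hand, "image and hand mask")
  if (sum(hand$data) == 0)
    stop("empty hand mask", call. = FALSE)
  d <- dim(img$data)
  feats <- list(intensity = as.numeric(img$data))
  for (r in cfg$box_radii) {
    mu <- array(0, d); mu2 <- array(0, d)
    for (s in seq_len(d[1])) {
      mu[s, , ] <- box_filter_slice(img$data[s, , ], r)
      mu2[s, , ] <- box_filter_slice(img$data[s, , ]^2, r)
    }
    v <- mu2 - mu^2
    v[v < 1e-10 * pmax(mu2, 1)] <- 0  # clamp round-off on flat patches
    feats[[paste0("mean_r", r)]] <- as.numeric(mu)
    feats[[paste0("sd_r", r)]] <- as.numeric(sqrt(v))
  }
  for (sg in cfg$smooth_sigmas) {
    sm <- array(0, d)
    sg_px <- sg / mean(img$spacing[1:2])
    for (s in seq_len(d[1])) sm[s, , ] <- gauss_filter_slice(img$data[s, , ], sg_px)
    feats[[paste0("gauss_s", format(sg))]] <- as.numeric(sm)
  }
  # in-plane gradient magnitude (central differences over physical mm)
  gm <- array(0, d)
  for (s in seq_len(d[1])) {
    sl <- img$data[s, , ]
    gy <- (rbind(sl[-1, , drop = FALSE], sl[nrow(sl), , drop = FALSE]) -
           rbind(sl[1, , drop = FALSE], sl[-nrow(sl), , drop = FALSE])) /
      (2 * img$spacing[2])
    gx <- (cbind(sl[, -1, drop = FALSE], sl[, ncol(sl), drop = FALSE]) -
           cbind(sl[, 1, drop = FALSE], sl[, -ncol(sl), drop = FALSE])) /
      (2 * img$spacing[1])
    gm[s, , ] <- sqrt(gx^2 + gy^2)
  }
  feats$grad_mag <- as.numeric(gm)
  if (cfg$use_distance) {
    dist <- array(0, d)
    for (s in seq_len(d[1])) {
      hs <- hand$data[s, , ]
      if (any(hs == 1)) {
        dm <- if (all(hs == 1)) {
          # no boundary on this slice: cap at the slice diagonal
          array(sqrt(sum(dim(hs)^2)), dim(hs))
        } else EBImage::distmap(hs)
        dist[s, , ] <- dm
      }
    }
    feats$hand_dist <- as.numeric(dist) * mean(img$spacing[1:2])
  }
  if (cfg$use_slice_pos) {
    pos <- (slice.index(img$data, 1) - 1) / max(d[1] - 1, 1)
    feats$slice_pos <- as.numeric(pos)
  }
  idx <- which(hand$data == 1)
  tab <- as.data.frame(lapply(feats, function(f) f[idx]))
  stopifnot(all(vapply(tab, function(col) all(is.finite(col)), logical(1))))
  attr(tab, "voxel_index") <- idx
  attr(tab, "fingerprint") <- feature_fingerprint(cfg)
  tab
}

#' Train the random-forest muscle classifier
#'
#' An ensemble of decision trees classifies each hand voxel into muscle or
#' background from its neighbourhood features. Training scans must provide
#' voxel labels (from manual or ground-truth segmentations).
#'
#' @param features feature table from [extract_voxel_features] (rows from one
#'   or several training scans concatenated).
#' @param labels factor or character vector per row, levels
#'   `muscle`/`background`.
#' @param trees number of trees.
#' @param seed integer seed making training deterministic.
#' @param sampsize per-class sample size for each tree (class-balanced
#'   sampling); default balances to the minority class, capped at 10000.
#' @return Object of class `muscle_classifier` holding the forest, the
#'   feature fingerprint and the training accuracy.
#' @export
train_classifier <- function(features, labels, trees = 100L, seed = 42L,
                             sampsize = NULL) {
  labels <- factor(as.character(labels), levels = c("background", "muscle"))
  if (any(is.na(labels)))
    stop("labels must be 'muscle' or 'background'", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L)
    stop("training requires both classes present", call. = FALSE)
  fp <- attr(features, "fingerprint")
  x <- as.data.frame(features)
  if (is.null(sampsize)) {
    m <- min(table(labels))
    sampsize <- c(min(m, 10000L), min(m, 10000L))
  }
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = labels, ntree = as.integer(trees),
    sampsize = sampsize, strata = labels)
  acc <- 1 - rf$err.rate[rf$ntree, "OOB"]
  structure(list(forest = rf, fingerprint = fp, seed = as.integer(seed),
                 trees = as.integer(trees), oob_accuracy = as.numeric(acc)),
            class = "muscle_classifier")
}

#' @export
print.muscle_classifier <- function(x, ...) {
  cat(sprintf("<muscle_classifier> %d trees, OOB accuracy %.4f\n",
              x$trees, x$oob_accuracy))
  invisible(x)
}

#' Classify hand voxels into muscle vs background
#'
#' The union of voxels classified as muscle is the muscle volume of
#' interest (VOI); it is always contained in the hand mask.
#'
#' @param img bias-corrected [volume_image].
#' @param hand hand [binary_mask].
#' @param clf a [muscle_classifier]; its feature fingerprint must match
#'   `cfg`.
#' @param cfg the [feature_config] used for feature extraction.
#' @return Muscle VOI as a [binary_mask].
#' @export
classify_muscle <- function(img, hand, clf, cfg = feature_config()) {
  stopifnot(inherits(clf, "muscle_classifier"))
  if (!identical(feature_fingerprint(cfg), clf$fingerprint))
    stop("feature configuration does not match the classifier's fingerprint",
         call. = FALSE)
  tab <- extract_voxel_features(img, hand, cfg)
  idx <- attr(tab, "voxel_index")
  pred <- predict(clf$forest, newdata = as.data.frame(tab))
  out <- array(0L, dim = dim(img$data))
  out[idx[pred == "muscle"]] <- 1L
  binary_mask(out, reference = img)
}

#' Gaussian histogram cleanup of the muscle VOI
#'
#' Fits a Gaussian to the intensity histogram of the muscle VOI and removes
#' voxels outside the fitted mean +/- 2 SD. This strips erroneously included
#' hypointense structures (ligaments, tendons) and hyperintense vessels from
#' the VOI. The fit is nonlinear least squares on Freedman-Diaconis-binned
#' counts, falling back to the sample median/MAD when the fit fails; a VOI
#' with near-zero intensity spread is returned unchanged and flagged.
#'
#' @param img bias-corrected [volume_image].
#' @param muscle muscle VOI [binary_mask] with at least 50 voxels.
#' @return A list: `mask` (cleaned [binary_mask], subset of the input) and
#'   `report` (class `cleanup_report`: fitted `mean`, `sd`, `retained_fraction`,
#'   `removed_count`, `degenerate` flag, fit `method`).
#' @export
gaussian_cleanup <- function(img, muscle) {
  stopifnot(inherits(img, "volume_image"), inherits(muscle, "binary_mask"))
  check_same_grid(img, muscle, "image and muscle mask")
  idx <- which(muscle$data == 1)
  n <- length(idx)
  if (n < 50)
    stop(sprintf("muscle VOI too small for a reliable histogram fit (%d voxels)", n),
         call. = FALSE)
  v <- img$data[idx]
  s0 <- mad(v)
  if (s0 <= .Machine$double.eps^0.5 * max(abs(v), 1)) {
    report <- structure(list(mean = median(v), sd = 0,
                             retained_fraction = 1, removed_count = 0L,
                             degenerate = TRUE, method = "degenerate"),
                        class = "cleanup_report")
    return(list(mask = muscle, report = report))
  }
  # Freedman-Diaconis binning
  bw <- 2 * stats::IQR(v) / n^(1 / 3)
  if (bw <= 0) bw <- diff(range(v)) / 30
  brk <- seq(min(v) - bw, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = brk, plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  mu <- median(v); sg <- s0; method <- "nls"
  fit <- try(minpack.lm::nlsLM(
    cnt ~ A * exp(-(mids - m)^2 / (2 * s^2)),
    start = list(A = max(cnt), m = mu, s = sg),
    lower = c(A = 0, m = min(v), s = bw / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(fit, "try-error") && coef(fit)[["s"]] > 0) {
    mu <- coef(fit)[["m"]]; sg <- coef(fit)[["s"]]
  } else {
    method <- "median_mad"
  }
  keep <- v >= mu - 2 * sg & v <= mu + 2 * sg
  out <- array(0L, dim = dim(muscle$data))
  out[idx[keep]] <- 1L
  report <- structure(list(mean = mu, sd = sg,
                           retained_fraction = mean(keep),
                           removed_count = as.integer(sum(!keep)),
                           degenerate = FALSE, method = method),
                      class = "cleanup_report")
  list(mask = binary_mask(out, spacing = muscle$spacing,
                          origin = muscle$origin),
       report = report)
}

#' @export
print.cleanup_report <- function(x, ...) {
  cat(sprintf("<cleanup_report> mean %.2f, sd %.2f, retained %.1f%%, removed %d (%s)\n",
              x$mean, x$sd, 100 * x$retained_fraction, x$removed_count,
              x$method))
  invisible(x)
}

#' Restrict a mask to the analysis bounds
#'
#' Zeroes all voxels outside the inclusive `[proximal_slice, distal_slice]`
#' interval; the output parameters are only accumulated inside it.
#'
#' @param mask a [binary_mask].
#' @param bounds an [analysis_bounds]; must lie within the slice range.
#' @return Restricted [binary_mask].
#' @export
restrict_to_bounds <- function(mask, bounds) {
  stopifnot(inherits(mask, "binary_mask"), inherits(bounds, "analysis_bounds"))
  nslice <- dim(mask$data)[1]
  if (bounds$distal_slice >= nslice)
    stop("analysis bounds exceed the slice range", call. = FALSE)
  out <- mask$data
  keep <- seq(bounds$proximal_slice + 1, bounds$distal_slice + 1)
  out[-keep, , ] <- 0L
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}
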