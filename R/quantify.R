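# Output parameters (hand volume, muscle volume, relative muscle volume,
# fat volume, relative fat content) and reanalysis precision errors.

#' Compute hand and muscle volumes between analysis bounds
#'
#' Hand volume `v_h` and muscle volume `v_m` are the accumulated volumes of
#' all voxels in the respective segmentation between the proximal and distal
#' bound slices (inclusive); the relative muscle volume is
#' `v_m_rel = v_m / v_h`.
#'
#' @param hand hand [binary_mask].
#' @param muscle muscle [binary_mask] contained in `hand`, same grid.
#' @param bounds an [analysis_bounds].
#' @param scan_id optional identifier carried into the result.
#' @return Object of class `hand_metrics`: `v_h`, `v_m` (mm^3), `v_m_rel`,
#'   `bounds`, `scan_id`; `v_f`/`v_f_rel` are `NA` until filled by
#'   [compute_fat_metrics].
#' @examples
#' h <- binary_mask(array(1L, c(4, 10, 25)), spacing = c(0.5, 0.5, 3))
#' m <- h; m$data[, , 11:25] <- 0L
#' compute_hand_metrics(h, m, analysis_bounds(0, 3))
#' @export
compute_hand_metrics <- function(hand, muscle, bounds, scan_id = NA_character_) {
  stopifnot(inherits(hand, "binary_mask"), inherits(muscle, "binary_mask"),
            inherits(bounds, "analysis_bounds"))
  check_same_grid(hand, muscle, "hand and muscle masks")
  if (any(muscle$data > hand$data))
    stop("muscle mask is not contained in the hand mask", call. = FALSE)
  nslice <- dim(hand$data)[1]
  if (bounds$distal_slice >= nslice)
    stop("analysis bounds exceed the slice range", call. = FALSE)
  sl <- seq(bounds$proximal_slice + 1, bounds$distal_slice + 1)
  vv <- voxel_volume(hand)
  v_h <- sum(hand$data[sl, , , drop = FALSE]) * vv
  v_m <- sum(muscle$data[sl, , , drop = FALSE]) * vv
  if (v_h == 0)
    stop("hand volume is zero within the analysis bounds", call. = FALSE)
  structure(list(v_h = v_h, v_m = v_m, v_m_rel = v_m / v_h,
                 v_f = NA_real_, v_f_rel = NA_real_,
                 bounds = bounds, scan_id = scan_id),
            class = "hand_metrics")
}

#' @export
print.hand_metrics <- function(x, ...) {
  cat(sprintf("<hand_metrics> V_H %.1f mm^3, V_M %.1f mm^3, V_M_rel %.4f",
              x$v_h, x$v_m, x$v_m_rel))
  if (!is.na(x$v_f))
    cat(sprintf(", V_F %.1f mm^3, V_F_rel %.4f", x$v_f, x$v_f_rel))
  cat(sprintf(" [slices %d..%d]\n", x$bounds$proximal_slice,
              x$bounds$distal_slice))
  invisible(x)
}

#' Compute fat metrics within the transferred muscle VOI
#'
#' The absolute fat volume is the accumulated voxel volume weighted by each
#' voxel's fat fraction: `v_f = sum(voxel_volume * I_ff / 1000)` over the
#' muscle VOI on the Dixon grid. The relative fat content is
#' `v_f_rel = v_f / v_m`, with `v_m` the muscle volume recomputed on the
#' same (Dixon) grid so numerator and denominator share a grid.
#'
#' @param ff a `fat_fraction_image` from [compute_fat_fraction].
#' @param muscle_on_ff muscle VOI [binary_mask] on the Dixon grid
#'   (see [transfer_voi]); must be non-empty.
#' @return A list with `v_f` (mm^3), `v_f_rel`, and `v_m_dixon` (mm^3).
#' @export
compute_fat_metrics <- function(ff, muscle_on_ff) {
  stopifnot(inherits(ff, "fat_fraction_image"),
            inherits(muscle_on_ff, "binary_mask"))
  check_same_grid(ff, muscle_on_ff, "fat-fraction image and muscle VOI")
  idx <- which(muscle_on_ff$data == 1)
  if (length(idx) == 0)
    stop("empty muscle VOI on the fat-fraction grid", call. = FALSE)
  vv <- voxel_volume(ff)
  v_m <- length(idx) * vv
  v_f <- sum(vv * ff$data[idx] / 1000)
  list(v_f = v_f, v_f_rel = v_f / v_m, v_m_dixon = v_m)
}

#' Reanalysis precision errors (RMS-SD and RMS-CV)
#'
#' Reliability of repeated analyses of the same scans: for each dataset the
#' standard deviation (n-1 denominator) and coefficient of variation
#' (SD/mean) of its repeats are computed per parameter, then aggregated as
#' the root-mean-square average across datasets. RMS-SD is reported in the
#' parameter's unit and RMS-CV in percent.
#'
#' @param measurements data frame with columns `dataset`, `repeat_id` and one
#'   column per parameter; every dataset needs at least two repeats.
#' @param mode label, `"inter-operator"` or `"intra-operator"`.
#' @return Object of class `precision_report`: data frame `errors` with
#'   columns `parameter`, `rms_sd`, `rms_cv_pct`, `cv_undefined` (flagged
#'   when some dataset mean is 0), plus `mode`, `n_datasets`, `n_repeats`.
#' @export
precision_errors <- function(measurements,
                             mode = c("inter-operator", "intra-operator")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(measurements),
            all(c("dataset", "repeat_id") %in% names(measurements)))
  params <- setdiff(names(measurements), c("dataset", "repeat_id"))
  if (length(params) == 0)
    stop("no parameter columns in `measurements`", call. = FALSE)
  counts <- table(measurements$dataset)
  if (length(counts) < 1)
    stop("at least one dataset required", call. = FALSE)
  if (any(counts < 2))
    stop(sprintf("every dataset needs >= 2 repeats (offending: %s)",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  ds <- split(measurements, measurements$dataset)
  rows <- lapply(params, function(p) {
    sds <- vapply(ds, function(g) sd(g[[p]]), numeric(1))
    means <- vapply(ds, function(g) mean(g[[p]]), numeric(1))
    zero_mean <- means == 0
    cvs <- ifelse(zero_mean, NA_real_, sds / means)
    data.frame(parameter = p,
               rms_sd = sqrt(mean(sds^2)),
               rms_cv_pct = 100 * sqrt(mean(cvs[!zero_mean]^2)),
               cv_undefined = any(zero_mean))
  })
  structure(list(errors = do.call(rbind, rows), mode = mode,
                 n_datasets = length(ds),
                 n_repeats = as.integer(max(counts))),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> %s, %d datasets x up to %d repeats\n",
              x$mode, x$n_datasets, x$n_repeats))
  print(x$errors, row.names = FALSE)
  invisible(x)
}
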