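# Per-subject pipeline orchestration and cohort-level study runs.

#' Train a muscle classifier from labelled phantom scans
#'
#' Convenience wrapper that generates phantoms for the given seeds, runs
#' bias correction and hand masking, extracts voxel features and trains the
#' random-forest classifier on the ground-truth muscle labels.
#'
#' @param seeds integer vector of phantom seeds to train on.
#' @param spec_template [phantom_spec] whose geometry/intensities are used
#'   (its seed is replaced per phantom).
#' @param feature_cfg a [feature_config].
#' @param trees,train_seed forwarded to [train_classifier].
#' @return A [train_classifier] result.
#' @export
train_phantom_classifier <- function(seeds = c(101L, 102L, 103L),
                                     spec_template = phantom_spec(),
                                     feature_cfg = feature_config(),
                                     trees = 100L, train_seed = 42L) {
  feats <- list(); labs <- list()
  for (s in seeds) {
    spec <- spec_template; spec$seed <- as.integer(s)
    ph <- generate_hand_phantom(spec)
    bc <- correct_bias_field(ph$t1)
    hm <- extract_hand_mask(bc$corrected)
    ft <- extract_voxel_features(bc$corrected, hm, feature_cfg)
    idx <- attr(ft, "voxel_index")
    labs[[length(labs) + 1]] <-
      ifelse(ph$truth$labels_t1[idx] == ph$truth$label_codes[["muscle"]],
             "muscle", "background")
    feats[[length(feats) + 1]] <- ft
  }
  allf <- do.call(rbind, feats)
  attr(allf, "fingerprint") <- attr(feats[[1]], "fingerprint")
  train_classifier(allf, unlist(labs), trees = trees, seed = train_seed)
}

#' Run the full per-subject pipeline
#'
#' Pre-processing (bias correction, hand mask), muscle segmentation
#' (random-forest classification, Gaussian cleanup, restriction to the
#' metacarpal bounds) and, when a Dixon pair is supplied, fat quantification
#' (fat-fraction map, rigid multimodal registration, VOI transfer, fat
#' metrics). Without a Dixon pair the fat metrics stay `NA` and the run
#' still succeeds, mirroring cohorts where Dixon imaging covers only a
#' subset of subjects.
#'
#' @param t1 T1-weighted [volume_image] or path to a NIfTI file.
#' @param classifier a trained [train_classifier] result.
#' @param water,fat optional Dixon pair ([volume_image]s or paths).
#' @param bounds [analysis_bounds]; `NULL` derives them from the hand mask
#'   (slices whose cross-sectional area is at least half the maximum).
#' @param bias_cfg,mask_cfg,feature_cfg,reg_cfg stage configurations.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param scan_id identifier recorded in the metrics.
#' @param out_dir if non-`NULL`, a directory where `metrics_<scan_id>.json`
#'   and intermediate masks are written.
#' @return A list with `metrics` ([compute_hand_metrics] result including
#'   fat metrics when available), the stage artifacts (`corrected`, `field`,
#'   `hand_mask`, `muscle_voi`, `cleanup_report`, and for Dixon runs
#'   `fat_fraction`, `registration`, `muscle_on_ff`), and `seed`.
#' @export
run_subject <- function(t1, classifier, water = NULL, fat = NULL,
                        bounds = NULL,
                        bias_cfg = bias_correction_config(),
                        mask_cfg = hand_mask_config(),
                        feature_cfg = feature_config(),
                        reg_cfg = registration_config(),
                        seed = 1L, scan_id = "subject",
                        out_dir = NULL) {
  if (is.character(t1)) t1 <- read_volume(t1)
  if (is.character(water)) water <- read_volume(water)
  if (is.character(fat)) fat <- read_volume(fat)
  stopifnot(inherits(t1, "volume_image"))
  if (xor(is.null(water), is.null(fat)))
    stop("supply both Dixon water and fat images, or neither", call. = FALSE)

  bc <- correct_bias_field(t1, bias_cfg)
  hm <- extract_hand_mask(bc$corrected, mask_cfg)
  muscle_raw <- classify_muscle(bc$corrected, hm, classifier, feature_cfg)
  cl <- gaussian_cleanup(bc$corrected, muscle_raw)
  if (is.null(bounds)) {
    csa <- apply(hm$data, 1, sum)
    palm <- which(csa >= 0.5 * max(csa))
    bounds <- analysis_bounds(min(palm) - 1, max(palm) - 1)
  }
  muscle <- restrict_to_bounds(cl$mask, bounds)
  hand_b <- restrict_to_bounds(hm, bounds)
  metrics <- compute_hand_metrics(hand_b, muscle, bounds, scan_id = scan_id)

  artifacts <- list(corrected = bc$corrected, field = bc$field,
                    hand_mask = hm, muscle_voi = muscle,
                    cleanup_report = cl$report)
  if (!is.null(water)) {
    ff <- compute_fat_fraction(water, fat)
    reg_cfg$seed <- as.integer(seed) + 1000L
    reg <- register_rigid(bc$corrected, hm, ff, reg_cfg)
    m_ff <- transfer_voi(muscle, reg$transform, ff)
    fm <- compute_fat_metrics(ff, m_ff)
    metrics$v_f <- fm$v_f
    metrics$v_f_rel <- fm$v_f_rel
    artifacts$fat_fraction <- ff
    artifacts$registration <- reg
    artifacts$muscle_on_ff <- m_ff
  }
  res <- list(metrics = metrics, artifacts = artifacts, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_json(res, file.path(out_dir,
                                      paste0("metrics_", scan_id, ".json")))
  }
  res
}

# deterministic serialization: fixed digit count, stable field order
write_metrics_json <- function(res, path) {
  m <- res$metrics
  obj <- list(scan_id = m$scan_id,
              seed = res$seed,
              bounds = c(m$bounds$proximal_slice, m$bounds$distal_slice),
              v_h_mm3 = round(m$v_h, 6),
              v_m_mm3 = round(m$v_m, 6),
              v_m_rel = round(m$v_m_rel, 10),
              v_f_mm3 = if (is.na(m$v_f)) NULL else round(m$v_f, 6),
              v_f_rel = if (is.na(m$v_f_rel)) NULL else round(m$v_f_rel, 10))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a study over multiple subjects
#'
#' Applies [run_subject] to each entry, assembles the per-subject metrics
#' into a cohort table (volumes in cm^3) joined with the provided
#' demographics, and optionally runs the configured statistical analyses.
#' Per-subject failures are caught, logged and excluded; the exclusion list
#' plus the cohort rows always account for every input subject.
#'
#' @param subjects a non-empty named list; each element is a list with at
#'   least `t1` and optionally `water`, `fat`, `sex`, `diagnosis`, `age`,
#'   `bmi`.
#' @param classifier trained classifier passed to [run_subject].
#' @param model_specs optional list of [model_spec]s to fit on the
#'   resulting cohort table.
#' @param ... further arguments forwarded to [run_subject].
#' @return A list with `cohort` (data frame), `exclusions` (character),
#'   `fits` (list of [fit_model] results), `results` (raw per-subject
#'   outputs).
#' @export
run_study <- function(subjects, classifier, model_specs = list(), ...) {
  stopifnot(is.list(subjects))
  if (length(subjects) == 0)
    stop("no subjects supplied", call. = FALSE)
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("S%03d", seq_along(subjects))
  rows <- list(); results <- list(); exclusions <- character()
  for (nm in names(subjects)) {
    s <- subjects[[nm]]
    res <- try(run_subject(t1 = s$t1, classifier = classifier,
                           water = s$water, fat = s$fat,
                           scan_id = nm, ...), silent = TRUE)
    if (inherits(res, "try-error")) {
      exclusions <- c(exclusions, nm)
      next
    }
    results[[nm]] <- res
    m <- res$metrics
    rows[[nm]] <- data.frame(
      id = nm,
      sex = if (is.null(s$sex)) NA_character_ else s$sex,
      diagnosis = if (is.null(s$diagnosis)) NA_character_ else s$diagnosis,
      age = if (is.null(s$age)) NA_real_ else s$age,
      bmi = if (is.null(s$bmi)) NA_real_ else s$bmi,
      vh = m$v_h / 1000, vm = m$v_m / 1000, vmrel = m$v_m_rel,
      vf = m$v_f / 1000, vfrel = m$v_f_rel)
  }
  if (length(rows) == 0)
    stop("all subjects failed; nothing to analyse", call. = FALSE)
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  fits <- lapply(model_specs, function(sp) try(fit_model(cohort, sp),
                                               silent = TRUE))
  list(cohort = cohort, exclusions = exclusions, fits = fits,
       results = results)
}
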