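test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generate_hand_phantom(small_phantom_spec(seed = 11L))
  b <- generate_hand_phantom(small_phantom_spec(seed = 11L))
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$water$data, b$water$data)
  expect_identical(a$truth$labels_t1, b$truth$labels_t1)
})

test_that("noise-free, bias-free phantom has exactly constant tissue intensities", {
  ph <- generate_hand_phantom(small_phantom_spec(seed = 3L, noise_sd = 0,
                                                 bias_amplitude = 0))
  muscle <- ph$truth$labels_t1 == ph$truth$label_codes[["muscle"]]
  expect_length(unique(ph$t1$data[muscle]), 1L)
})

test_that("Dixon pair reconstructs the true fat fraction exactly at noise 0", {
  sp <- small_phantom_spec(seed = 5L, noise_sd = 0,
                           fat_fractions = c(background = 0, muscle = 0.30,
                                             bone = 0.40, tendon = 0.05,
                                             vessel = 0.02, fat = 0.90))
  ph <- generate_hand_phantom(sp)
  muscle <- ph$truth$labels_dixon == ph$truth$label_codes[["muscle"]]
  ffv <- ph$fat$data[muscle] / (ph$water$data[muscle] + ph$fat$data[muscle])
  expect_equal(range(ffv), c(0.30, 0.30), tolerance = 1e-12)
})

test_that("truth volumes equal label counts times the voxel volume", {
  ph <- generate_hand_phantom(small_phantom_spec(seed = 7L))
  b <- ph$truth$bounds
  sl <- seq(b$proximal_slice + 1, b$distal_slice + 1)
  vv <- voxel_volume(ph$t1)
  hand <- ph$truth$labels_t1 != 0
  musc <- ph$truth$labels_t1 == ph$truth$label_codes[["muscle"]]
  expect_identical(ph$truth$v_h, sum(hand[sl, , ]) * vv)
  expect_identical(ph$truth$v_m, sum(musc[sl, , ]) * vv)
  expect_lte(ph$truth$v_m, ph$truth$v_h)
  expect_gte(ph$truth$v_m_rel, 0)
  expect_lte(ph$truth$v_m_rel, 1)
})

test_that("cohort generator reproduces the configured group sizes", {
  co <- generate_cohort(cohort_spec(seed = 1L))
  tab <- table(co$diagnosis, co$sex)
  expect_identical(as.vector(tab["Pso", ]), c(63L, 38L))
  expect_identical(as.vector(tab["PsA", ]), c(61L, 76L))
  expect_identical(as.vector(tab["RA", ]), c(41L, 51L))
  expect_equal(nrow(co), 330L)
  expect_true(all(co$age >= 20 & co$age <= 80))
  expect_equal(co$vmrel, co$vm / co$vh, tolerance = 1e-9)
})

test_that("degenerate cohorts follow the generating model exactly", {
  flat <- function(v) list(male = list(Pso = v, PsA = v, RA = v),
                           female = list(Pso = v, PsA = v, RA = v))
  # zero residual SD, zero slopes: every subject in a group identical
  sp <- cohort_spec(resid_sd_vmrel = 0, resid_sd_vh = 0,
                    vmrel_slope = flat(0), vh_slope = flat(0), seed = 2L)
  co <- generate_cohort(sp)
  for (g in split(co$vmrel, interaction(co$sex, co$diagnosis)))
    expect_length(unique(g), 1L)

  # configured RA-vs-Pso offset appears exactly in the group means
  sp2 <- cohort_spec(resid_sd_vmrel = 0, vmrel_slope = flat(0),
                     vmrel_intercept = list(
                       male = list(Pso = 0.30, PsA = 0.30, RA = 0.26),
                       female = list(Pso = 0.30, PsA = 0.30, RA = 0.26)),
                     seed = 3L)
  co2 <- generate_cohort(sp2)
  means <- tapply(co2$vmrel, co2$diagnosis, mean)
  expect_equal(unname(means["RA"] - means["Pso"]), -0.04, tolerance = 1e-12)
})

test_that("OLS on a near-noiseless cohort recovers the generating coefficients", {
  eq <- function(v) list(male = list(Pso = v, PsA = v, RA = v),
                         female = list(Pso = v, PsA = v, RA = v))
  sp <- cohort_spec(resid_sd_vmrel = 0, resid_sd_vh = 0,
                    vmrel_intercept = list(
                      male = list(Pso = 0.31, PsA = 0.29, RA = 0.27),
                      female = list(Pso = 0.31, PsA = 0.29, RA = 0.27)),
                    vmrel_slope = eq(-0.0012), seed = 4L)
  co <- generate_cohort(sp)
  fit <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                  group = TRUE, window = c(20, 80)))
  cf <- coef(fit$fit)
  expect_equal(unname(cf["age"]), -0.0012, tolerance = 1e-7)
  expect_equal(unname(cf["diagnosisPsA"]), -0.02, tolerance = 1e-7)
  expect_equal(unname(cf["diagnosisRA"]), -0.04, tolerance = 1e-7)
})

test_that("reanalysis perturbation is deterministic and vanishes at magnitude 0", {
  ph <- generate_hand_phantom(small_phantom_spec(seed = 9L))
  expect_identical(perturb_for_reanalysis(ph$t1, 0, seed = 1L)$data,
                   ph$t1$data)
  p1 <- perturb_for_reanalysis(ph$t1, 0.3, seed = 7L)
  p2 <- perturb_for_reanalysis(ph$t1, 0.3, seed = 7L)
  expect_identical(p1$data, p2$data)
  expect_false(identical(p1$data, ph$t1$data))
})

test_that("perturbation magnitude orders the voxelwise RMS difference", {
  ph <- generate_hand_phantom(small_phantom_spec(seed = 10L))
  rms_at <- function(mag, seed) {
    p <- perturb_for_reanalysis(ph$t1, mag, seed = seed)
    sqrt(mean((p$data - ph$t1$data)^2))
  }
  for (s in 1:10) {
    expect_lte(rms_at(0.1, s), rms_at(0.5, s))
  }
})
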