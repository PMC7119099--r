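eq_by_group <- function(v) list(male = list(Pso = v, PsA = v, RA = v),
                                female = list(Pso = v, PsA = v, RA = v))

noise_free_cohort <- function(seed = 4L, ra_off = -0.04, psa_off = -0.02) {
  cohort_spec(resid_sd_vmrel = 0, resid_sd_vh = 0,
              vmrel_intercept = list(
                male = list(Pso = 0.31, PsA = 0.31 + psa_off,
                            RA = 0.31 + ra_off),
                female = list(Pso = 0.28, PsA = 0.28 + psa_off,
                              RA = 0.28 + ra_off)),
              vmrel_slope = eq_by_group(-0.0012), seed = seed)
}

test_that("group differences reproduce the generating offsets exactly", {
  co <- generate_cohort(noise_free_cohort())
  fit <- fit_model(co, model_spec(response = "vmrel", sex = "male"))
  d_ra <- suppressWarnings(group_difference(fit, c("RA", "Pso")))
  expect_equal(d_ra$delta, -0.04, tolerance = 1e-9)
  d_psa <- suppressWarnings(group_difference(fit, c("PsA", "Pso")))
  expect_equal(d_psa$delta, -0.02, tolerance = 1e-9)
  # algebraic identity in a parallel-slopes model
  d_rp <- suppressWarnings(group_difference(fit, c("RA", "PsA")))
  expect_equal(d_rp$delta, d_ra$delta - d_psa$delta, tolerance = 1e-9)
  # self-contrast is zero with flagged p
  self <- group_difference(fit, c("RA", "RA"))
  expect_identical(self$delta, 0)
  expect_true(is.na(self$p))
  expect_error(group_difference(fit, c("RA", "XX")), "unknown")
})

test_that("percent change over a window follows the closed form", {
  # linear model: value 1.0 at age 40, slope -0.005/yr -> -20% over 40..80
  co <- data.frame(sex = "male", diagnosis = rep(c("Pso", "PsA", "RA"), 40),
                   age = rep(seq(20, 80, length.out = 40), each = 3))
  co$vmrel <- 1.0 - 0.005 * (co$age - 40)
  fit <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                  group = FALSE, window = c(20, 80)))
  expect_equal(percent_change_over_window(fit, c(40, 80)), -20,
               tolerance = 1e-9)
  # zero slope: zero percent
  co$vmrel <- 0.5
  fit0 <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                   group = FALSE))
  expect_equal(percent_change_over_window(fit0, c(40, 80)), 0,
               tolerance = 1e-9)
  # negative slope implies negative percent change
  co$vmrel <- 0.9 - 0.001 * co$age
  fitn <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                   group = FALSE))
  expect_lt(percent_change_over_window(fitn, c(40, 80)), 0)
})

test_that("age and age^3 models agree when the response is constant in age", {
  co <- generate_cohort(cohort_spec(
    resid_sd_vmrel = 0, resid_sd_vh = 0,
    vmrel_slope = eq_by_group(0), seed = 6L))
  f1 <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                 age_term = "age"))
  f3 <- fit_model(co, model_spec(response = "vmrel", sex = "male",
                                 age_term = "age3"))
  expect_equal(unname(coef(f1$fit)["age"]), 0, tolerance = 1e-10)
  expect_equal(unname(coef(f3$fit)["age3"]), 0, tolerance = 1e-12)
  expect_equal(suppressWarnings(group_difference(f1, c("RA", "Pso"))$delta),
               suppressWarnings(group_difference(f3, c("RA", "Pso"))$delta),
               tolerance = 1e-9)
})

test_that("BMI models use exactly the BMI-complete subset", {
  co <- generate_cohort(cohort_spec(seed = 8L, bmi_fraction = 0.6))
  spec <- model_spec(response = "vmrel", sex = "male", covariates = "bmi",
                     window = c(20, 80))
  fit <- fit_model(co, spec)
  manual <- co[co$sex == "male" & !is.na(co$bmi) &
                 co$age >= 20 & co$age <= 80, ]
  expect_equal(fit$n, nrow(manual))
  # without BMI no record is dropped
  fit2 <- fit_model(co, model_spec(response = "vmrel", sex = "male"))
  expect_equal(fit2$n, sum(co$sex == "male"))
})

test_that("decade ANOVA handles no-signal, strong-signal and symmetry", {
  # identical value sets in all groups: between-group variance 0, F = 0,
  # p = 1, pairwise differences 0
  co <- data.frame(sex = "male",
                   diagnosis = rep(c("Pso", "PsA", "RA"), each = 20),
                   age = rep(seq(40.5, 79.5, length.out = 20), 3))
  co$vmrel <- 0.25 + 0.001 * (co$age - 40)  # same set in every group
  da <- decade_anova(co, "vmrel", "male")
  for (dec in da$decades) {
    if (!dec$testable) next
    expect_gte(dec$anova_p, 0.999)
    expect_true(all(abs(dec$tukey[, "diff"]) < 1e-12))
  }

  # two groups separated by 5 pooled SDs: overwhelming significance
  set.seed(11)
  co2 <- data.frame(sex = "male",
                    diagnosis = rep(c("Pso", "RA"), each = 20),
                    age = runif(40, 40, 49.9))
  co2$vmrel <- rnorm(40, 0.30, 0.01) + ifelse(co2$diagnosis == "RA", -0.05, 0)
  da2 <- decade_anova(co2, "vmrel", "male")
  dec1 <- da2$decades[["40-50"]]
  expect_true(dec1$testable)
  expect_lt(dec1$tukey["RA-Pso", "p adj"], 0.001)
  # pairwise difference equals the difference of group means (symmetric)
  mean_diff <- mean(co2$vmrel[co2$diagnosis == "RA"]) -
    mean(co2$vmrel[co2$diagnosis == "Pso"])
  expect_equal(unname(dec1$tukey["RA-Pso", "diff"]), mean_diff,
               tolerance = 1e-12)

  # sparse decades are reported as not testable, not as errors
  co3 <- co2[co2$diagnosis == "Pso", ][1:3, ]
  da3 <- decade_anova(co3, "vmrel", "male")
  expect_false(da3$decades[["40-50"]]$testable)
})

test_that("decade partition is left-closed with the last decade closed", {
  co <- data.frame(sex = "male",
                   diagnosis = rep(c("Pso", "PsA", "RA"), each = 4),
                   age = rep(c(40, 49.999, 50, 80), 3), vmrel = 0.3)
  da <- decade_anova(co, "vmrel", "male")
  expect_equal(sum(da$decades[["40-50"]]$n), 6)   # 40 and 49.999
  expect_equal(sum(da$decades[["50-60"]]$n), 3)   # 50
  expect_equal(sum(da$decades[["70-80"]]$n), 3)   # 80 included
})

test_that("insufficient or degenerate designs raise model errors", {
  co <- generate_cohort(cohort_spec(seed = 10L))
  expect_error(fit_model(co[1:4, ], model_spec(response = "vmrel")),
               "too few|empty")
  co2 <- co[co$diagnosis == "Pso", ]
  expect_error(fit_model(co2, model_spec(response = "vmrel", sex = "male")),
               "empty|rank|too few")
})
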