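# Cohort-level statistics: linear models of hand and relative muscle volume
# in age (or age^3), BMI and diagnosis; adjusted group differences; percent
# change over an age window; decade-partitioned ANOVA with Tukey HSD.

#' Model specification for cohort regressions
#'
#' @param response one of `"vh"`, `"vmrel"`, `"vf"`, `"vfrel"`.
#' @param age_term `"age"` for a linear age term or `"age3"` for age cubed.
#' @param covariates character vector, currently `"bmi"` or empty. When BMI
#'   is included, subjects without BMI are dropped (complete-case subset);
#'   without it, no subject is dropped.
#' @param group `TRUE` to add diagnosis as a categorical factor.
#' @param sex stratum, `"male"`, `"female"` or `NULL` for both pooled.
#' @param window age window `c(lo, hi)` restricting the records used.
#' @param reference reference diagnosis level for the factor coding
#'   (default `"Pso"`, the control group).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response = "vmrel", age_term = c("age", "age3"),
                       covariates = character(), group = TRUE,
                       sex = NULL, window = c(20, 80), reference = "Pso") {
  age_term <- match.arg(age_term)
  stopifnot(response %in% c("vh", "vmrel", "vf", "vfrel"),
            all(covariates %in% "bmi"),
            is.null(sex) || sex %in% c("male", "female"),
            length(window) == 2L, window[1] < window[2],
            reference %in% c("Pso", "PsA", "RA"))
  structure(list(response = response, age_term = age_term,
                 covariates = covariates, group = isTRUE(group),
                 sex = sex, window = window, reference = reference),
            class = "model_spec")
}

#' Fit a cohort linear model
#'
#' Ordinary least squares of the response on the age term (age or age^3),
#' optional BMI, and optionally the diagnosis factor with a configurable
#' reference level. Records are filtered to the sex stratum and age window;
#' BMI-containing models use only records with observed BMI.
#'
#' @param cohort cohort data frame (see [generate_cohort]).
#' @param spec a [model_spec].
#' @return Object of class `cohort_fit`: the `lm` fit, `spec`, `n` records
#'   used, and the age values used.
#' @export
fit_model <- function(cohort, spec = model_spec()) {
  stopifnot(is.data.frame(cohort), inherits(spec, "model_spec"))
  d <- cohort
  if (!is.null(spec$sex)) d <- d[d$sex == spec$sex, , drop = FALSE]
  d <- d[d$age >= spec$window[1] & d$age <= spec$window[2], , drop = FALSE]
  if ("bmi" %in% spec$covariates) d <- d[!is.na(d$bmi), , drop = FALSE]
  d$diagnosis <- stats::relevel(factor(d$diagnosis,
                                       levels = c("Pso", "PsA", "RA")),
                                ref = spec$reference)
  d$age3 <- d$age^3
  terms <- c(if (spec$age_term == "age") "age" else "age3",
             spec$covariates,
             if (spec$group) "diagnosis")
  p <- length(terms) + 1 + if (spec$group) 1 else 0  # factor has 2 dummies
  if (nrow(d) < p + 3)
    stop(sprintf("too few records (%d) for the model", nrow(d)),
         call. = FALSE)
  if (spec$group && any(table(d$diagnosis) == 0))
    stop("empty diagnosis group in the filtered data", call. = FALSE)
  fml <- as.formula(paste(spec$response, "~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design", call. = FALSE)
  structure(list(fit = fit, spec = spec, n = nrow(d), data = d),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit> %s ~ %s%s%s, n = %d, R^2 = %.3f\n",
              x$spec$response, x$spec$age_term,
              if (length(x$spec$covariates)) " + bmi" else "",
              if (x$spec$group) " + diagnosis" else "",
              x$n, summary(x$fit)$r.squared))
  print(coef(summary(x$fit)))
  invisible(x)
}

# linear contrast c'beta with t-based p-value
linear_contrast <- function(fit, cvec) {
  b <- coef(fit)
  V <- vcov(fit)
  est <- sum(cvec * b)
  se <- sqrt(as.numeric(t(cvec) %*% V %*% cvec))
  df <- fit$df.residual
  if (se == 0) return(list(estimate = est, se = 0, p = NA_real_))
  tt <- est / se
  list(estimate = est, se = se, p = 2 * pt(-abs(tt), df))
}

#' Adjusted group difference over an age window
#'
#' The difference between two diagnosis groups' model-predicted means,
#' averaged over the ages observed in the model's window with other
#' covariates held at their means. In the default parallel-slopes model
#' this equals the difference of the diagnosis factor coefficients; the
#' p-value comes from the corresponding linear contrast.
#'
#' @param model a [cohort_fit] whose spec includes the diagnosis factor.
#' @param contrast character length-2, e.g. `c("RA", "Pso")` for RA - Pso.
#' @return Object of class `group_difference`: `contrast`, `delta`, `p`,
#'   `window`, `adjusted_for`.
#' @export
group_difference <- function(model, contrast) {
  stopifnot(inherits(model, "cohort_fit"), length(contrast) == 2L)
  spec <- model$spec
  if (!spec$group)
    stop("the model does not include the diagnosis factor", call. = FALSE)
  lev <- levels(model$data$diagnosis)
  if (!all(contrast %in% lev))
    stop(sprintf("unknown group in contrast: %s",
                 paste(setdiff(contrast, lev), collapse = ", ")),
         call. = FALSE)
  nm <- names(coef(model$fit))
  cvec <- setNames(rep(0, length(nm)), nm)
  if (contrast[1] == contrast[2]) {
    return(structure(list(contrast = contrast, delta = 0, p = NA_real_,
                          window = spec$window,
                          adjusted_for = c(spec$age_term, spec$covariates),
                          note = "contrast of a group with itself"),
                     class = "group_difference"))
  }
  for (k in 1:2) {
    g <- contrast[k]
    sign_ <- if (k == 1) 1 else -1
    coef_name <- paste0("diagnosis", g)
    if (coef_name %in% nm)       # reference level has no coefficient
      cvec[coef_name] <- cvec[coef_name] + sign_
  }
  res <- linear_contrast(model$fit, cvec)
  structure(list(contrast = contrast, delta = res$estimate, p = res$p,
                 window = spec$window,
                 adjusted_for = c(spec$age_term, spec$covariates)),
            class = "group_difference")
}

#' @export
print.group_difference <- function(x, ...) {
  cat(sprintf("<group_difference> %s - %s: delta = %+.4g (p = %.3g), ages %g-%g, adjusted for %s\n",
              x$contrast[1], x$contrast[2], x$delta,
              if (is.na(x$p)) NA else x$p, x$window[1], x$window[2],
              paste(x$adjusted_for, collapse = " + ")))
  invisible(x)
}

#' Percent change of the model prediction over an age window
#'
#' `100 * (prediction(b) - prediction(a)) / prediction(a)` with all
#' covariates other than age at their stratum means and, when the model
#' includes the diagnosis factor, at the requested group.
#'
#' @param model a [cohort_fit] containing an age term.
#' @param window age window `c(a, b)`.
#' @param group diagnosis level to evaluate at (default the model's
#'   reference level).
#' @return Percent change (negative = loss).
#' @export
percent_change_over_window <- function(model, window = NULL, group = NULL) {
  stopifnot(inherits(model, "cohort_fit"))
  spec <- model$spec
  if (is.null(window)) window <- spec$window
  if (is.null(group)) group <- spec$reference
  nd <- data.frame(age = c(window[1], window[2]))
  nd$age3 <- nd$age^3
  if ("bmi" %in% spec$covariates) nd$bmi <- mean(model$data$bmi)
  if (spec$group)
    nd$diagnosis <- factor(group, levels = levels(model$data$diagnosis))
  pr <- predict(model$fit, newdata = nd)
  if (pr[1] <= 0)
    stop("prediction at the window start is non-positive; percent change undefined",
         call. = FALSE)
  unname(100 * (pr[2] - pr[1]) / pr[1])
}

#' Decade-partitioned one-way ANOVA with Tukey HSD
#'
#' Partitions the 40-80 year range into the four decades `[40,50)`,
#' `[50,60)`, `[60,70)`, `[70,80]` and, within each, tests diagnosis group
#' differences of the response with a one-way ANOVA followed by Tukey's
#' honestly-significant-difference pairwise comparisons. A decade without
#' at least two groups of two or more records is reported as not testable
#' rather than erroring.
#'
#' @param cohort cohort data frame.
#' @param response response column name (default `"vmrel"`).
#' @param sex stratum, `"male"`, `"female"` or `NULL` for both.
#' @param decades matrix-like list of decade bounds; the default implements
#'   the convention above.
#' @return Object of class `decade_anova`: one element per decade with
#'   group means and sizes, the ANOVA p-value and the Tukey table.
#' @export
decade_anova <- function(cohort, response = "vmrel", sex = NULL,
                         decades = list(c(40, 50), c(50, 60),
                                        c(60, 70), c(70, 80))) {
  stopifnot(is.data.frame(cohort), response %in% names(cohort))
  d <- cohort
  if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
  d$diagnosis <- factor(d$diagnosis, levels = c("Pso", "PsA", "RA"))
  out <- list()
  for (i in seq_along(decades)) {
    win <- decades[[i]]
    last <- i == length(decades)
    sel <- d$age >= win[1] & (if (last) d$age <= win[2] else d$age < win[2])
    dd <- droplevels(d[sel, , drop = FALSE])
    tab <- table(dd$diagnosis)
    name <- sprintf("%d-%d", win[1], win[2])
    if (sum(tab >= 2) < 2) {
      out[[name]] <- list(window = win, testable = FALSE,
                          n = as.vector(tab), groups = names(tab))
      next
    }
    fml <- as.formula(paste(response, "~ diagnosis"))
    fit <- aov(fml, data = dd)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$diagnosis
    means <- tapply(dd[[response]], dd$diagnosis, mean)
    out[[name]] <- list(window = win, testable = TRUE,
                        n = as.vector(tab), groups = names(tab),
                        means = means, anova_p = p, tukey = tk)
  }
  structure(list(decades = out, response = response, sex = sex),
            class = "decade_anova")
}

#' @export
print.decade_anova <- function(x, ...) {
  cat(sprintf("<decade_anova> %s%s\n", x$response,
              if (is.null(x$sex)) "" else paste0(", ", x$sex)))
  for (nm in names(x$decades)) {
    dec <- x$decades[[nm]]
    if (!dec$testable) {
      cat(sprintf("  %s: not testable (n = %s)\n", nm,
                  paste(dec$n, collapse = "/")))
    } else {
      cat(sprintf("  %s: n = %s, ANOVA p = %.3g\n", nm,
                  paste(dec$n, collapse = "/"), dec$anova_p))
    }
  }
  invisible(x)
}
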