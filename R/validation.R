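#' Mean percent error (bias) of predictions
#'
#' MPE = 100/N x sum((Cpred - Cobs)/Cobs), with a Student-t 95% confidence
#' interval computed on the per-point percent errors.
#'
#' @param predictions,observations Equal-length numeric vectors;
#'   observations must be strictly positive.
#' @param conf Confidence level for the interval (default 0.95).
#' @return List with `mpe` (%), `ci` (length-2, %), `n`.
#' @export
mpe <- function(predictions, observations, conf = 0.95) {
  pe <- .percent_errors(predictions, observations)
  m <- mean(pe)
  n <- length(pe)
  ci <- if (n >= 2) {
    se <- stats::sd(pe) / sqrt(n)
    m + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, df = n - 1) * se
  } else c(NA_real_, NA_real_)
  list(mpe = m, ci = ci, n = n)
}

#' Root-mean-squared percent error (imprecision) of predictions
#'
#' RMSE = 100 x sqrt(1/N x sum(((Cpred - Cobs)/Cobs)^2)).
#'
#' @inheritParams mpe
#' @return RMSE (%).
#' @export
rmse <- function(predictions, observations) {
  pe <- .percent_errors(predictions, observations)
  sqrt(mean(pe^2))
}

.percent_errors <- function(predictions, observations) {
  stopifnot(is.numeric(predictions), is.numeric(observations))
  if (length(predictions) != length(observations) || length(predictions) < 1)
    stop("predictions and observations must be equal-length, non-empty")
  if (any(!is.finite(observations)) || any(observations <= 0))
    stop("all observations must be finite and strictly positive")
  100 * (predictions - observations) / observations
}

#' Predictive-performance summary (bias and imprecision)
#'
#' @inheritParams mpe
#' @return An object of class `performance_summary` with fields `mpe`, `ci`,
#'   `rmse`, `n`.
#' @export
performance_summary <- function(predictions, observations, conf = 0.95) {
  b <- mpe(predictions, observations, conf)
  structure(list(mpe = b$mpe, ci = b$ci, rmse = rmse(predictions, observations),
                 n = b$n),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("MPE %.1f%% [95%% CI %.1f; %.1f], RMSE %.1f%% (n = %d)\n",
              x$mpe, x$ci[1], x$ci[2], x$rmse, x$n))
  invisible(x)
}

#' Bland-Altman agreement between two paired sets of values
#'
#' Per-pair percent difference 100 x (A - B) / mean(A, B) (symmetric
#' denominator convention; set `denominator = "reference"` to divide by B
#' instead). Limits of agreement are mean difference +/- 1.96 SD; pairs
#' outside them are flagged.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 2). No
#'   pair may have A + B = 0 under the symmetric convention (B = 0 under the
#'   reference convention).
#' @param denominator `"mean"` (default) or `"reference"`.
#' @param ids Optional identifiers for the pairs, used in the outlier list.
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `limits` (length-2), `n`, `n_outside`, `fraction_outside`, `diffs`,
#'   `outliers` (ids outside the limits).
#' @examples
#' bland_altman(c(1, 2, 3), c(1, 2, 3))
#' @export
bland_altman <- function(values_a, values_b,
                         denominator = c("mean", "reference"), ids = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b) || length(values_a) < 2)
    stop("paired vectors of equal length >= 2 required")
  denom <- if (denominator == "mean") (values_a + values_b) / 2 else values_b
  if (any(denom == 0))
    stop("a pair has zero denominator; percent difference undefined")
  if (is.null(ids)) ids <- seq_along(values_a)
  d <- 100 * (values_a - values_b) / denom
  m <- mean(d)
  s <- stats::sd(d)
  limits <- m + c(-1.96, 1.96) * s
  outside <- d < limits[1] | d > limits[2]
  structure(list(mean_diff = m, sd_diff = s, limits = limits,
                 n = length(d), n_outside = sum(outside),
                 fraction_outside = mean(outside), diffs = d,
                 outliers = ids[outside], denominator = denominator),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean bias %.1f%% (SD %.1f%%), 95%% limits [%.1f; %.1f]\n",
              x$mean_diff, x$sd_diff, x$limits[1], x$limits[2]))
  cat(sprintf("  %d of %d pairs (%.1f%%) outside the limits\n",
              x$n_outside, x$n, 100 * x$fraction_outside))
  invisible(x)
}

#' Ordinary least-squares agreement regression
#'
#' Regresses A on B and reports slope, intercept and R-squared (perfect
#' agreement: slope 1, intercept 0, R-squared 1 on the identity line).
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 3); B
#'   must have non-zero variance.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regression_r2 <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b) || length(values_a) < 3)
    stop("paired vectors of equal length >= 3 required")
  if (stats::var(values_b) == 0)
    stop("predictor values have zero variance; regression undefined")
  fit <- stats::lm(values_a ~ values_b)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((values_a - mean(values_a))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(values_a))
}

## Fit one patient under a given model spec; returns a uniform record.
.fit_one <- function(spec, patient, prior = NULL, target = 80,
                     n_doses = 16L, auc_window = c(0, 6)) {
  obs <- patient$observations
  if (spec$type == "parametric") {
    fit <- map_fit(spec, patient$covariates, patient$regimen, obs)
    ok <- fit$converged
  } else {
    fit <- np_posterior(spec, patient$covariates, patient$regimen, obs,
                        prior = prior)
    ok <- !fit$degenerate_likelihood
  }
  exposure <- individual_auc_and_dose(fit, patient$regimen, times = obs$time,
                                      auc_window = auc_window)
  rec <- dose_for_target_auc(exposure$CL, target = target, n_doses = n_doses,
                             model = spec$type)
  list(fit = fit, ok = ok, predictions = exposure$predictions,
       auc_first = exposure$auc_first, auc_cum = exposure$auc_cum,
       CL = exposure$CL, dose = rec$dose)
}

#' Cross-validate two busulfan models on a patient cohort
#'
#' Fits every patient's first-occasion concentrations with both a test and a
#' reference model, then compares the two models' individual predictions:
#' bias/imprecision of each model against the observations, and agreement
#' (OLS regression + Bland-Altman) on three quantities — the predicted
#' concentrations at the sampling times (pooled over patients), the AUC over
#' the first 6 h, and the predicted dose per administration required to
#' reach the target cumulative AUC. Pairs outside the 95% limits of
#' agreement are flagged with patient identifiers.
#'
#' @param cohort A list of patients as produced by [simulate_cohort()] or
#'   [read_dataset()]: each element has `id`, `covariates`, `regimen`,
#'   `observations` (data frame `time`, `conc` in mg/L).
#' @param test_spec,ref_spec `model_spec` objects (parametric or
#'   nonparametric); the published cross-validation compares a parametric
#'   test model against a nonparametric reference.
#' @param target Target cumulative AUC (mg.h/L) for the dose comparison.
#' @param n_doses Number of doses in the planned course.
#' @param np_prior Prior used for any nonparametric spec (defaults to a
#'   400-point reconstruction).
#' @param ba_denominator Bland-Altman denominator convention, see
#'   [bland_altman()].
#' @return An object of class `crossval_report`: `performance` (list of two
#'   `performance_summary`, test and reference), `agreement` (list of three
#'   `bland_altman`: `concentration`, `auc_first`, `dose`), `regression`
#'   (matching list of OLS summaries), `per_patient` data frame, `excluded`
#'   data frame of patients failing either fit, and `n_patients`, `n_obs`.
#' @export
cross_validate <- function(cohort, test_spec, ref_spec, target = 80,
                           n_doses = 16L, np_prior = NULL,
                           ba_denominator = "mean") {
  stopifnot(length(cohort) >= 2L,
            inherits(test_spec, "model_spec"),
            inherits(ref_spec, "model_spec"))
  if (is.null(np_prior)) {
    npspec <- if (test_spec$type == "nonparametric") test_spec
              else if (ref_spec$type == "nonparametric") ref_spec else NULL
    if (!is.null(npspec)) np_prior <- build_np_prior(npspec)
  }

  rows <- list()
  excluded <- list()
  conc_obs <- conc_test <- conc_ref <- numeric(0)
  conc_ids <- character(0)
  for (p in cohort) {
    res <- tryCatch({
      ft <- .fit_one(test_spec, p, prior = np_prior, target = target,
                     n_doses = n_doses)
      fr <- .fit_one(ref_spec, p, prior = np_prior, target = target,
                     n_doses = n_doses)
      if (!ft$ok) stop("test-model fit not converged/degenerate")
      if (!fr$ok) stop("reference-model fit not converged/degenerate")
      list(ft = ft, fr = fr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(id = p$id, reason = conditionMessage(res))
      next
    }
    ft <- res$ft; fr <- res$fr
    rows[[length(rows) + 1L]] <- data.frame(
      id = p$id, n_obs = nrow(p$observations),
      cl_test = ft$CL, cl_ref = fr$CL,
      auc_first_test = ft$auc_first, auc_first_ref = fr$auc_first,
      auc_cum_test = ft$auc_cum, auc_cum_ref = fr$auc_cum,
      dose_test = ft$dose, dose_ref = fr$dose)
    conc_obs <- c(conc_obs, p$observations$conc)
    conc_test <- c(conc_test, ft$predictions)
    conc_ref <- c(conc_ref, fr$predictions)
    conc_ids <- c(conc_ids, rep(as.character(p$id), nrow(p$observations)))
  }
  if (length(rows) < 2L)
    stop("fewer than two patients fitted successfully; cannot compare models")
  per_patient <- do.call(rbind, rows)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(id = character(0), reason = character(0))

  performance <- list(
    test = performance_summary(conc_test, conc_obs),
    reference = performance_summary(conc_ref, conc_obs))
  agreement <- list(
    concentration = bland_altman(conc_test, conc_ref,
                                 denominator = ba_denominator, ids = conc_ids),
    auc_first = bland_altman(per_patient$auc_first_test,
                             per_patient$auc_first_ref,
                             denominator = ba_denominator,
                             ids = per_patient$id),
    dose = bland_altman(per_patient$dose_test, per_patient$dose_ref,
                        denominator = ba_denominator, ids = per_patient$id))
  regression <- list(
    concentration = regression_r2(conc_test, conc_ref),
    auc_first = regression_r2(per_patient$auc_first_test,
                              per_patient$auc_first_ref),
    dose = regression_r2(per_patient$dose_test, per_patient$dose_ref))

  structure(list(performance = performance, agreement = agreement,
                 regression = regression, per_patient = per_patient,
                 excluded = excluded, n_patients = nrow(per_patient),
                 n_obs = length(conc_obs), target = target,
                 n_doses = n_doses),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("Cross-validation: %d patients, %d concentrations (%d excluded)\n",
              x$n_patients, x$n_obs, nrow(x$excluded)))
  cat("Test model:      "); print(x$performance$test)
  cat("Reference model: "); print(x$performance$reference)
  for (q in names(x$agreement)) {
    ba <- x$agreement[[q]]
    rg <- x$regression[[q]]
    cat(sprintf("%-14s bias %+.1f%% (SD %.1f), %d/%d outside limits; R2 = %.3f, slope = %.3f\n",
                q, ba$mean_diff, ba$sd_diff, ba$n_outside, ba$n,
                rg$r_squared, rg$slope))
  }
  invisible(x)
}
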