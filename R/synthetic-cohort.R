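#' Configuration for the virtual pediatric cohort generator
#'
#' The generator emulates the design of a routine-care busulfan TDM cohort
#' in children undergoing conditioning before stem-cell transplantation:
#' body weight log-normal with median 16.7 kg truncated to 3.2-90.9 kg,
#' 2-h infusions every 6 h (16-dose course), two blood samples at 0.5 and
#' 2 h after the end of the first infusion, individual parameters drawn from
#' the parametric model's log-normal between-subject distributions, and
#' combined proportional + additive residual noise on the observations.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param bw_median,bw_sdlog,bw_range Body-weight distribution: log-normal
#'   median (kg), SD on the log scale, truncation bounds (kg).
#' @param height_cv Log-normal noise CV on the height-from-weight relation.
#' @param height_range Plausible height bounds (cm); draws outside are
#'   redrawn.
#' @param interval,duration,n_doses Regimen defaults (q6h, 2-h infusion,
#'   16 doses).
#' @param sampling_offsets Sampling times (h) after the end of the first
#'   infusion; default `c(0.5, 2)`.
#' @param dose_bands Weight-banded starting-dose nomogram: data frame with
#'   `upper_bw` (kg, band upper bound, last is `Inf`) and `mg_per_kg` (per
#'   administration). The default is the conventional label nomogram for q6h
#'   intravenous busulfan in children; the starting dose only scales
#'   concentrations linearly and does not affect model agreement.
#' @param bsv Logical: draw between-subject variability? `FALSE` puts every
#'   patient at the typical values.
#' @param residual Logical: add residual noise to observations?
#' @param spec [parametric_model_spec()] providing typical values,
#'   variability and residual error for simulation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 61L, seed = 20221001L,
                          bw_median = 16.7, bw_sdlog = 0.67,
                          bw_range = c(3.2, 90.9),
                          height_cv = 0.05, height_range = c(46, 190),
                          interval = 6, duration = 2, n_doses = 16L,
                          sampling_offsets = c(0.5, 2),
                          dose_bands = data.frame(
                            upper_bw = c(9, 16, 23, 34, Inf),
                            mg_per_kg = c(1.0, 1.2, 1.1, 0.95, 0.8)),
                          bsv = TRUE, residual = TRUE,
                          spec = parametric_model_spec()) {
  stopifnot(n >= 1L, bw_range[1] < bw_range[2],
            all(sampling_offsets > 0), bw_sdlog > 0,
            is.data.frame(dose_bands),
            all(c("upper_bw", "mg_per_kg") %in% names(dose_bands)))
  if (bw_median < bw_range[1] || bw_median > bw_range[2])
    stop("bw_median must lie inside bw_range")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 bw_median = bw_median, bw_sdlog = bw_sdlog,
                 bw_range = bw_range, height_cv = height_cv,
                 height_range = height_range, interval = interval,
                 duration = duration, n_doses = as.integer(n_doses),
                 sampling_offsets = sampling_offsets,
                 dose_bands = dose_bands, bsv = bsv, residual = residual,
                 spec = spec),
            class = "cohort_config")
}

## draw from a distribution, redrawing values failing a predicate
.redraw <- function(n, rfun, keep, max_tries = 100L) {
  x <- rfun(n)
  for (i in seq_len(max_tries)) {
    bad <- !keep(x)
    if (!any(bad)) return(x)
    x[bad] <- rfun(sum(bad))
  }
  stop("failed to draw values satisfying the constraint after ",
       max_tries, " attempts")
}

.starting_dose <- function(bw, bands) {
  band <- which(bw <= bands$upper_bw)[1]
  bw * bands$mg_per_kg[band]
}

#' Simulate a virtual pediatric busulfan cohort
#'
#' Draws covariates, true individual parameters and sparse noisy TDM
#' observations after the first infusion; ground truth is retained for
#' recovery experiments.
#'
#' @param config [cohort_config()] object.
#' @return A list of class `cohort`: one element per patient, each with
#'   `id`, `covariates`, `true_params` ([individual_parameters()]),
#'   `regimen`, `observations` (noisy, data frame `time`/`conc` in mg/L) and
#'   `observations_noiseless`. The truth table is available via
#'   [truth_table()].
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 5, seed = 1))
#' coh[[1]]$observations
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  spec <- config$spec
  meanlog_bw <- log(config$bw_median)

  bw <- .redraw(config$n,
                function(k) stats::rlnorm(k, meanlog_bw, config$bw_sdlog),
                function(x) x >= config$bw_range[1] & x <= config$bw_range[2])
  # height from the pediatric ideal-body-weight relation inverted,
  # ht = sqrt(BW / 0.00165) cm, with multiplicative noise
  ht <- .redraw_heights(bw, config)
  age <- pmin(21, pmax(0.1, (bw / 3.5)^0.9))  # crude weight-for-age, reporting only
  sex <- sample(c("male", "female"), config$n, replace = TRUE)

  omega_cl <- sqrt(log(1 + spec$cv_cl^2))
  omega_v <- sqrt(log(1 + spec$cv_v^2))
  eta_cl <- if (config$bsv) stats::rnorm(config$n, 0, omega_cl) else numeric(config$n)
  eta_v <- if (config$bsv) stats::rnorm(config$n, 0, omega_v) else numeric(config$n)

  obs_times <- config$duration + config$sampling_offsets

  patients <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    cov <- patient_covariates(bw[i], height = ht[i], age = age[i],
                              sex = sex[i])
    typ <- paci_typical_params(cov, spec)
    truth <- individual_parameters(typ$CL * exp(eta_cl[i]),
                                   typ$V * exp(eta_v[i]))
    dose <- .starting_dose(bw[i], config$dose_bands)
    reg <- standard_regimen(dose, n_doses = config$n_doses,
                            interval = config$interval,
                            duration = config$duration)
    clean <- predict_concentration(truth, reg, obs_times)
    noisy <- if (config$residual) {
      vapply(clean, function(cc) {
        sd <- residual_sd(spec, cc)
        # negative draws are redrawn, not truncated, to avoid a mass at 0
        .redraw(1, function(k) stats::rnorm(k, cc, sd), function(x) x >= 0)
      }, numeric(1))
    } else clean
    patients[[i]] <- list(
      id = sprintf("P%03d", i), covariates = cov, true_params = truth,
      true_eta = c(eta_cl[i], eta_v[i]), starting_dose = dose,
      regimen = reg,
      observations = data.frame(time = obs_times, conc = noisy),
      observations_noiseless = data.frame(time = obs_times, conc = clean))
  }
  structure(patients, class = "cohort", config = config)
}

.redraw_heights <- function(bw, config) {
  vapply(bw, function(b) {
    # plateau: above ~53 kg the inverse-IBW relation exceeds adolescent
    # stature, so cap the deterministic part at 180 cm
    mu <- min(sqrt(b / 0.00165), 180)
    h <- .redraw(1,
                 function(k) mu * stats::rlnorm(k, 0, config$height_cv),
                 function(x) x >= config$height_range[1] &
                   x <= config$height_range[2],
                 max_tries = 100L)
    h
  }, numeric(1))
}

#' @export
print.cohort <- function(x, ...) {
  bw <- vapply(x, function(p) p$covariates$body_weight, numeric(1))
  cat(sprintf("Virtual cohort: %d patients, BW median %.1f kg (range %.1f-%.1f)\n",
              length(x), stats::median(bw), min(bw), max(bw)))
  invisible(x)
}

#' Ground-truth table of a simulated cohort
#'
#' @param cohort A `cohort` object from [simulate_cohort()].
#' @return Data frame: `id`, covariates, true `CL`, `V`, starting dose, and
#'   true first-window and cumulative AUC under the simulated regimen.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(id = p$id, bw = p$covariates$body_weight,
               height = p$covariates$height, age = p$covariates$age,
               sex = p$covariates$sex,
               cl_true = p$true_params$CL, v_true = p$true_params$V,
               starting_dose = p$starting_dose,
               auc_first_true = auc_interval(p$true_params, p$regimen, 0, 6),
               auc_cum_true = auc_cumulative(p$true_params, p$regimen))
  }))
}

#' Parameter-recovery experiment on a simulated cohort
#'
#' Simulates a cohort, fits every patient with the given model, and reports
#' the bias (MPE) and imprecision (RMSE) of the estimated clearance and
#' cumulative AUC against the simulated truth.
#'
#' @param config [cohort_config()].
#' @param spec Model specification used for fitting (parametric MAP by
#'   default; a nonparametric spec triggers discrete-prior estimation).
#' @param np_prior Optional prior for a nonparametric spec.
#' @return List of class `recovery_report`: `cl` and `auc_cum` performance
#'   summaries (estimate vs truth), `per_patient` data frame, `n_failed`.
#' @export
recovery_experiment <- function(config = cohort_config(n = 200L),
                                spec = parametric_model_spec(),
                                np_prior = NULL) {
  cohort <- simulate_cohort(config)
  if (spec$type == "nonparametric" && is.null(np_prior))
    np_prior <- build_np_prior(spec)
  rows <- list()
  failed <- 0L
  for (p in cohort) {
    res <- tryCatch(
      .fit_one(spec, p, prior = np_prior),
      error = function(e) e)
    if (inherits(res, "error") || !res$ok) {
      failed <- failed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = p$id, cl_true = p$true_params$CL, cl_est = res$CL,
      auc_cum_true = auc_cumulative(p$true_params, p$regimen),
      auc_cum_est = res$auc_cum)
  }
  per_patient <- do.call(rbind, rows)
  structure(list(
    cl = performance_summary(per_patient$cl_est, per_patient$cl_true),
    auc_cum = performance_summary(per_patient$auc_cum_est,
                                  per_patient$auc_cum_true),
    per_patient = per_patient, n_failed = failed),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery vs simulated truth\n")
  cat("  CL:      "); print(x$cl)
  cat("  AUC_cum: "); print(x$auc_cum)
  if (x$n_failed > 0) cat(sprintf("  %d patient(s) failed to fit\n", x$n_failed))
  invisible(x)
}
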