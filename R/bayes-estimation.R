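#' Residual-error standard deviation
#'
#' Parametric model: combined error, SD = sqrt((0.11 C)^2 + 0.057^2) mg/L
#' (11% proportional, 57 ng/mL additive). Nonparametric model: linear rule,
#' SD = 0.02 + 0.1 C mg/L. For the parametric model C is the model
#' prediction; for the nonparametric rule C is the observed concentration,
#' following each published formula literally.
#'
#' @param spec A `model_spec` object.
#' @param concentration Concentration(s) (mg/L), non-negative.
#' @return Residual SD(s) (mg/L).
#' @examples
#' residual_sd(parametric_model_spec(), 0)     # 0.057 mg/L floor
#' residual_sd(nonparametric_model_spec(), 1)  # 0.12 mg/L
#' @export
residual_sd <- function(spec, concentration) {
  UseMethod("residual_sd")
}

#' @export
residual_sd.parametric_model_spec <- function(spec, concentration) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and non-negative")
  sqrt((spec$prop_error * concentration)^2 + spec$add_error_sd^2)
}

#' @export
residual_sd.nonparametric_model_spec <- function(spec, concentration) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and non-negative")
  spec$sd_intercept + spec$sd_slope * concentration
}

## MAP objective: -2 log posterior up to a constant.
## sum_i [ (Cobs_i - Cpred_i)^2 / sigma_i^2 + log sigma_i^2 ] + sum_k eta_k^2/omega_k^2
## sigma_i is evaluated at the prediction (the error magnitude depends on the
## model value, not the noisy observation). The log sigma^2 term is kept
## because sigma depends on eta through the prediction.
.map_objective <- function(eta, spec, typ, regimen, obs_times, obs_conc,
                           omega2) {
  CL <- typ$CL * exp(eta[1])
  V <- typ$V * exp(eta[2])
  pars <- individual_parameters(CL, V)
  pred <- predict_concentration(pars, regimen, obs_times)
  sd <- residual_sd(spec, pred)
  sum((obs_conc - pred)^2 / sd^2 + log(sd^2)) +
    eta[1]^2 / omega2[1] + eta[2]^2 / omega2[2]
}

#' MAP Bayesian fit of the parametric model to one patient
#'
#' Estimates individual clearance and volume by maximum a posteriori
#' estimation: the log-normal between-subject distributions around the
#' covariate-predicted typical values are the prior, and the combined
#' residual-error model gives the likelihood of the observed concentrations.
#' Minimized objective (\eqn{-2\log} posterior up to a constant):
#' \deqn{\sum_i \left[ \frac{(C_{obs,i}-C_{pred,i})^2}{\sigma_i^2} +
#'   \ln \sigma_i^2 \right] + \sum_k \frac{\eta_k^2}{\omega_k^2}}
#' with \eqn{\sigma_i} the residual SD at the prediction and
#' \eqn{\omega_k^2 = \ln(1 + CV_k^2)}.
#'
#' Optimization is derivative-free (Nelder-Mead) started from the prior mode
#' eta = 0 and, as a safeguard against local minima, restarted from the best
#' point of a coarse 5 x 5 eta grid; the better of the two solutions is
#' returned.
#'
#' @param spec [parametric_model_spec()].
#' @param cov [patient_covariates()].
#' @param regimen [regimen()] describing the doses given before/around the
#'   observations.
#' @param observations Data frame with columns `time` (h) and `conc` (mg/L).
#'   Zero rows are allowed: the fit returns the typical values (prior mode).
#' @return An object of class `map_fit`: fields `eta`, `params`
#'   ([individual_parameters()]), `objective`, `predictions` (mg/L at the
#'   observation times), `converged`, `typical`.
#' @export
map_fit <- function(spec, cov, regimen, observations) {
  stopifnot(inherits(spec, "parametric_model_spec"),
            inherits(cov, "patient_covariates"),
            inherits(regimen, "regimen"))
  observations <- .check_observations(observations)
  typ <- paci_typical_params(cov, spec)
  omega2 <- c(log(1 + spec$cv_cl^2), log(1 + spec$cv_v^2))

  if (nrow(observations) == 0L) {
    return(structure(list(eta = c(0, 0), params = typ,
                          objective = 0, predictions = numeric(0),
                          converged = TRUE, typical = typ),
                     class = "map_fit"))
  }
  if (all(observations$conc == 0))
    warning("all observed concentrations are zero; fit proceeds but is driven by the prior")

  obj <- function(eta) .map_objective(eta, spec, typ, regimen,
                                      observations$time, observations$conc,
                                      omega2)
  fit0 <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
  # coarse grid restart
  g <- seq(-1, 1, length.out = 5)
  grid <- as.matrix(expand.grid(g, g))
  vals <- apply(grid, 1, obj)
  fit1 <- stats::optim(as.numeric(grid[which.min(vals), ]), obj,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
  fit <- if (fit1$value < fit0$value) fit1 else fit0
  converged <- (fit$convergence == 0)
  if (!converged)
    warning("MAP optimizer did not report convergence; result flagged")
  eta <- unname(fit$par)
  params <- individual_parameters(typ$CL * exp(eta[1]), typ$V * exp(eta[2]))
  structure(list(eta = eta, params = params, objective = fit$value,
                 predictions = predict_concentration(params, regimen,
                                                     observations$time),
                 converged = converged, typical = typ),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit: CL = %.4g L/h (eta %.3f), V = %.4g L (eta %.3f), objective %.4g%s\n",
              x$params$CL, x$eta[1], x$params$V, x$eta[2], x$objective,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

.check_observations <- function(observations) {
  if (is.null(observations) ||
      (is.data.frame(observations) && nrow(observations) == 0L))
    return(data.frame(time = numeric(0), conc = numeric(0)))
  stopifnot(is.data.frame(observations),
            all(c("time", "conc") %in% names(observations)))
  if (any(!is.finite(observations$time)) || any(observations$time < 0))
    stop("observation times must be finite and non-negative")
  if (any(!is.finite(observations$conc)) || any(observations$conc < 0))
    stop("observed concentrations must be finite and non-negative (mg/L)")
  observations
}

#' Discrete-prior (nonparametric) Bayesian posterior for one patient
#'
#' Updates the prior weights of a fixed discrete support set: posterior
#' weight of support point j is proportional to
#' prior_j x prod_i Normal(Cobs_i; Cpred_ij, sigma_ij^2), with sigma from the
#' nonparametric residual rule evaluated at the observed concentration. The
#' support points themselves never move.
#'
#' If every support point has numerically zero likelihood (a gross outlier
#' relative to the whole support set), the posterior falls back to uniform
#' weights with an explicit diagnostic rather than failing.
#'
#' @param spec [nonparametric_model_spec()].
#' @param cov [patient_covariates()] (height required for IBW).
#' @param regimen [regimen()].
#' @param observations Data frame with columns `time` (h), `conc` (mg/L);
#'   zero rows return the prior unchanged.
#' @param prior [build_np_prior()] result; defaults to a 400-point grid.
#' @return An object of class `np_posterior`: `support` data frame with
#'   `KeS`, `VS`, `CL`, `V`, prior and posterior `weight`; posterior-mean and
#'   posterior-median summaries; posterior-mean predictions at the
#'   observation times; `degenerate_likelihood` flag.
#' @export
np_posterior <- function(spec, cov, regimen, observations,
                         prior = build_np_prior(spec)) {
  stopifnot(inherits(spec, "nonparametric_model_spec"),
            inherits(cov, "patient_covariates"),
            inherits(regimen, "regimen"),
            inherits(prior, "np_prior"))
  observations <- .check_observations(observations)
  sup <- prior$support
  n <- nrow(sup)
  size <- neely_size(cov)
  Ke <- sup$KeS * size^(-0.25)
  V <- sup$VS * size
  CL <- Ke * V

  pred <- matrix(0, nrow = n, ncol = nrow(observations))
  if (nrow(observations) > 0L) {
    for (j in seq_len(n)) {
      pred[j, ] <- predict_concentration(individual_parameters(CL[j], V[j]),
                                         regimen, observations$time)
    }
    sd <- residual_sd(spec, observations$conc)  # rule uses Cobs
    loglik <- vapply(seq_len(n), function(j) {
      sum(stats::dnorm(observations$conc, mean = pred[j, ], sd = sd,
                       log = TRUE))
    }, numeric(1))
    logw <- log(sup$weight) + loglik
    # degenerate when even the best support point's likelihood underflows to
    # zero in linear space: no candidate parameter set remotely fits the data
    degenerate <- !any(is.finite(logw)) ||
      max(loglik) < log(.Machine$double.xmin)
    if (degenerate) {
      warning("all support points have numerically zero likelihood; ",
              "falling back to uniform posterior weights (possible outlier data)")
      w <- rep(1 / n, n)
    } else {
      logw <- logw - max(logw[is.finite(logw)])
      w <- exp(logw)
      w <- w / sum(w)
    }
  } else {
    w <- sup$weight
    degenerate <- FALSE
  }

  support <- data.frame(KeS = sup$KeS, VS = sup$VS, CL = CL, V = V,
                        prior_weight = sup$weight, weight = w)
  post_mean <- c(KeS = sum(w * sup$KeS), VS = sum(w * sup$VS),
                 CL = sum(w * CL), V = sum(w * V))
  post_median <- c(KeS = weighted_quantile(sup$KeS, w),
                   VS = weighted_quantile(sup$VS, w))
  predictions <- if (nrow(observations) > 0L) drop(crossprod(pred, w)) else numeric(0)
  structure(list(support = support, posterior_mean = post_mean,
                 posterior_median = post_median,
                 predictions = as.numeric(predictions),
                 degenerate_likelihood = degenerate,
                 n_obs = nrow(observations)),
            class = "np_posterior")
}

#' @export
print.np_posterior <- function(x, ...) {
  cat(sprintf("Nonparametric posterior over %d support points (%d observation%s)\n",
              nrow(x$support), x$n_obs, if (x$n_obs == 1) "" else "s"))
  cat(sprintf("  posterior-mean CL = %.4g L/h, V = %.4g L%s\n",
              x$posterior_mean["CL"], x$posterior_mean["V"],
              if (x$degenerate_likelihood) " [degenerate likelihood: uniform fallback]" else ""))
  invisible(x)
}

#' Individual exposure summaries from a fit
#'
#' Computes the AUC over the first 6 h of therapy (integral of the fitted
#' curve over [0, 6] h after the first dose), the cumulative AUC of the whole
#' course, and predictions at requested times. For a MAP fit these are
#' evaluated at the MAP parameters; for a nonparametric posterior they are
#' posterior-weighted means over the support points.
#'
#' @param fit A `map_fit` or `np_posterior` object.
#' @param regimen [regimen()] over which to evaluate exposure.
#' @param times Optional times (h) at which to return predicted
#'   concentrations.
#' @param auc_window Window (h) for the first-dose AUC; default `c(0, 6)`.
#' @return A list with `auc_first` (mg.h/L over `auc_window`), `auc_cum`
#'   (mg.h/L to infinity), `predictions` (mg/L at `times`), and `CL` (the
#'   clearance summary used, L/h).
#' @export
individual_auc_and_dose <- function(fit, regimen, times = numeric(0),
                                    auc_window = c(0, 6)) {
  UseMethod("individual_auc_and_dose")
}

#' @export
individual_auc_and_dose.map_fit <- function(fit, regimen, times = numeric(0),
                                            auc_window = c(0, 6)) {
  p <- fit$params
  list(auc_first = auc_interval(p, regimen, auc_window[1], auc_window[2]),
       auc_cum = auc_cumulative(p, regimen),
       predictions = predict_concentration(p, regimen, times),
       CL = p$CL)
}

#' @export
individual_auc_and_dose.np_posterior <- function(fit, regimen,
                                                 times = numeric(0),
                                                 auc_window = c(0, 6)) {
  w <- fit$support$weight
  auc_first <- 0
  auc_cum <- 0
  pred <- numeric(length(times))
  for (j in seq_len(nrow(fit$support))) {
    pj <- individual_parameters(fit$support$CL[j], fit$support$V[j])
    auc_first <- auc_first +
      w[j] * auc_interval(pj, regimen, auc_window[1], auc_window[2])
    auc_cum <- auc_cum + w[j] * auc_cumulative(pj, regimen)
    if (length(times))
      pred <- pred + w[j] * predict_concentration(pj, regimen, times)
  }
  list(auc_first = auc_first, auc_cum = auc_cum, predictions = pred,
       CL = unname(fit$posterior_mean["CL"]))
}
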