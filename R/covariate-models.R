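#' Patient covariates
#'
#' @param body_weight Body weight (kg), strictly positive.
#' @param height Height (cm); may be `NA` when ideal body weight is not
#'   needed.
#' @param age Age (years), non-negative; carried for reporting, unused by
#'   either dosing model.
#' @param sex `"male"` or `"female"`; carried but unused by either model.
#' @return An object of class `patient_covariates`.
#' @export
patient_covariates <- function(body_weight, height = NA_real_,
                               age = NA_real_, sex = NA_character_) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive number (kg)")
  if (!is.na(height) && (!is.numeric(height) || height <= 0))
    stop("height must be positive (cm) or NA")
  if (!is.na(age) && (!is.numeric(age) || age < 0))
    stop("age must be non-negative (years) or NA")
  if (!is.na(sex)) sex <- match.arg(sex, c("male", "female"))
  structure(list(body_weight = body_weight, height = height,
                 age = age, sex = sex),
            class = "patient_covariates")
}

#' Parametric (allometric MAP) busulfan model specification
#'
#' Typical clearance scales allometrically with body weight around a 9-kg
#' reference: CL = 2.18 (BW/9)^theta with theta = 1.25 below 9 kg and 0.76 at
#' or above 9 kg; typical volume is V = BW^0.86. Between-subject variability
#' is log-normal with CVs of 23% (CL) and 22% (V). Residual error combines
#' 11% proportional with a 57 ng/mL (0.057 mg/L) additive SD.
#'
#' @param cl_ref Typical CL at the reference weight (L/h).
#' @param bw_ref Reference body weight (kg).
#' @param theta_low,theta_high CL allometric exponents below / at-or-above
#'   `bw_ref`.
#' @param theta_v V allometric exponent.
#' @param cv_cl,cv_v Between-subject CVs (fractions).
#' @param prop_error Proportional residual error (fraction).
#' @param add_error_sd Additive residual SD (mg/L).
#' @return An object of class `c("parametric_model_spec", "model_spec")`.
#' @export
parametric_model_spec <- function(cl_ref = 2.18, bw_ref = 9,
                                  theta_low = 1.25, theta_high = 0.76,
                                  theta_v = 0.86,
                                  cv_cl = 0.23, cv_v = 0.22,
                                  prop_error = 0.11, add_error_sd = 0.057) {
  vals <- c(cl_ref, bw_ref, theta_v, cv_cl, cv_v, prop_error, add_error_sd)
  if (any(!is.finite(vals)) || any(vals <= 0) ||
      !is.finite(theta_low) || !is.finite(theta_high))
    stop("all parametric model constants must be finite and positive")
  structure(list(cl_ref = cl_ref, bw_ref = bw_ref,
                 theta_low = theta_low, theta_high = theta_high,
                 theta_v = theta_v, cv_cl = cv_cl, cv_v = cv_v,
                 prop_error = prop_error, add_error_sd = add_error_sd,
                 type = "parametric"),
            class = c("parametric_model_spec", "model_spec"))
}

#' Nonparametric (discrete-prior) busulfan model specification
#'
#' Reference model parameterized by allometric "slope" parameters: the
#' elimination rate is Ke = KeS x size^(-0.25) and the volume V = VS x size,
#' with size the lower of body weight and Traub-Johnson ideal body weight.
#' Published summaries of the support distribution: KeS median 0.71 (range
#' 0.42-0.98, CV 18%); VS median 0.72 (range 0.53-1.40, CV 21%). Residual SD
#' (mg/L) = 0.02 + 0.1 x observed concentration. The true discrete support
#' set is unpublished; [build_np_prior()] reconstructs an approximation
#' moment-matched to these summaries.
#'
#' @param kes_median,kes_min,kes_max,kes_cv KeS summary statistics
#'   (1/h per kg^-0.25; CV as fraction).
#' @param vs_median,vs_min,vs_max,vs_cv VS summary statistics (L/kg).
#' @param sd_intercept,sd_slope Residual SD rule coefficients:
#'   SD = sd_intercept + sd_slope x Cobs (mg/L).
#' @return An object of class `c("nonparametric_model_spec", "model_spec")`.
#' @export
nonparametric_model_spec <- function(kes_median = 0.71, kes_min = 0.42,
                                     kes_max = 0.98, kes_cv = 0.18,
                                     vs_median = 0.72, vs_min = 0.53,
                                     vs_max = 1.40, vs_cv = 0.21,
                                     sd_intercept = 0.02, sd_slope = 0.1) {
  stopifnot(kes_min < kes_median, kes_median < kes_max,
            vs_min < vs_median, vs_median < vs_max,
            kes_cv > 0, vs_cv > 0, sd_intercept >= 0, sd_slope >= 0)
  structure(list(kes_median = kes_median, kes_min = kes_min,
                 kes_max = kes_max, kes_cv = kes_cv,
                 vs_median = vs_median, vs_min = vs_min,
                 vs_max = vs_max, vs_cv = vs_cv,
                 sd_intercept = sd_intercept, sd_slope = sd_slope,
                 type = "nonparametric"),
            class = c("nonparametric_model_spec", "model_spec"))
}

#' Typical parameters under the parametric allometric model
#'
#' @param cov [patient_covariates()] object.
#' @param spec [parametric_model_spec()] object.
#' @return [individual_parameters()] at the typical (population) values for
#'   this body weight.
#' @examples
#' paci_typical_params(patient_covariates(9))     # CL = 2.18 L/h
#' paci_typical_params(patient_covariates(16.7))  # CL ~ 3.49, V ~ 11.26
#' @export
paci_typical_params <- function(cov, spec = parametric_model_spec()) {
  stopifnot(inherits(cov, "patient_covariates"),
            inherits(spec, "parametric_model_spec"))
  bw <- cov$body_weight
  theta <- if (bw < spec$bw_ref) spec$theta_low else spec$theta_high
  CL <- spec$cl_ref * (bw / spec$bw_ref)^theta
  V <- bw^spec$theta_v
  individual_parameters(CL = CL, V = V)
}

#' Pediatric ideal body weight (Traub-Johnson)
#'
#' Default formula: IBW (kg) = height^2 x 1.65 / 1000, height in cm. The
#' coefficient and exponent are configurable because published variants of
#' the formula differ; the variant in use should be echoed in any report.
#'
#' @param height Height (cm).
#' @param coef,exponent Formula constants: IBW = height^exponent x coef / 1000.
#' @param bounds Plausible height range (cm); heights outside it produce a
#'   warning but the value is still computed, never silently truncated.
#' @return Ideal body weight (kg).
#' @examples
#' traub_johnson_ibw(103)  # 17.50 kg
#' traub_johnson_ibw(100)  # 16.5 kg
#' @export
traub_johnson_ibw <- function(height, coef = 1.65, exponent = 2,
                              bounds = c(40, 200)) {
  if (any(!is.finite(height)) || any(height <= 0))
    stop("height must be finite and positive (cm)")
  if (any(height < bounds[1] | height > bounds[2]))
    warning(sprintf("height outside plausible range [%g, %g] cm; value computed anyway",
                    bounds[1], bounds[2]))
  height^exponent * coef / 1000
}

#' Size descriptor for the nonparametric model
#'
#' The lower of actual body weight and Traub-Johnson ideal body weight.
#' Height is required only when it could matter, i.e. when IBW cannot be
#' shown to exceed BW.
#'
#' @param cov [patient_covariates()] object.
#' @return Size (kg) used in the Ke and V covariate equations.
#' @export
neely_size <- function(cov) {
  stopifnot(inherits(cov, "patient_covariates"))
  if (is.na(cov$height))
    stop("height is required to evaluate ideal body weight for the nonparametric model")
  min(cov$body_weight, traub_johnson_ibw(cov$height))
}

#' Individual parameters under the nonparametric reference model
#'
#' Ke = KeS x size^(-0.25), V = VS x size, size = min(BW, IBW). Returned in
#' the common (CL, V) parameterization with CL = Ke x V.
#'
#' @param KeS Elimination-rate slope (1/h per kg^-0.25), positive.
#' @param VS Volume slope (L/kg), positive.
#' @param cov [patient_covariates()] object (height required).
#' @return [individual_parameters()] object.
#' @examples
#' # size = 16 kg: 16^0.25 = 2 exactly, so Ke = 0.71/2 = 0.355 1/h
#' cov <- patient_covariates(16, height = 150)
#' neely_params(0.71, 0.72, cov)
#' @export
neely_params <- function(KeS, VS, cov) {
  if (!is.numeric(KeS) || KeS <= 0 || !is.numeric(VS) || VS <= 0)
    stop("KeS and VS must be positive")
  size <- neely_size(cov)
  Ke <- KeS * size^(-0.25)
  V <- VS * size
  individual_parameters(CL = Ke * V, V = V)
}

#' Build a discrete prior for the nonparametric model
#'
#' The published reference model's support points are not public; only the
#' median, range and CV of each slope parameter are. This constructs a
#' log-spaced rectangular grid of (KeS, VS) pairs spanning the published
#' ranges, weighted by the product of independent truncated log-normal
#' densities moment-matched to the published median and CV of each slope.
#' It is an approximation to the true support set and is flagged as such in
#' reports.
#'
#' @param spec [nonparametric_model_spec()] object.
#' @param n_points Requested number of support points (>= 1). The grid uses
#'   m x m points with m = round(sqrt(n_points)); `n_points = 1` degenerates
#'   to a single point at the medians with weight 1.
#' @param seed Optional integer seed, recorded in the result for provenance
#'   (the default grid construction is deterministic).
#' @return An object of class `np_prior`: data frame `support` with columns
#'   `KeS`, `VS`, `weight` (weights sum to 1), plus attributes.
#' @examples
#' pr <- build_np_prior(nonparametric_model_spec(), n_points = 400)
#' sum(pr$support$weight)  # 1
#' @export
build_np_prior <- function(spec = nonparametric_model_spec(),
                           n_points = 400, seed = NULL) {
  stopifnot(inherits(spec, "nonparametric_model_spec"))
  if (!is.numeric(n_points) || n_points < 1)
    stop("n_points must be at least 1")
  if (n_points == 1) {
    support <- data.frame(KeS = spec$kes_median, VS = spec$vs_median,
                          weight = 1)
  } else {
    m <- max(2L, round(sqrt(n_points)))
    kes <- exp(seq(log(spec$kes_min), log(spec$kes_max), length.out = m))
    vs <- exp(seq(log(spec$vs_min), log(spec$vs_max), length.out = m))
    grid <- expand.grid(KeS = kes, VS = vs)
    # truncated log-normal marginals, median-matched (meanlog = log(median))
    # and CV-matched (sdlog^2 = log(1 + CV^2))
    dk <- stats::dlnorm(grid$KeS, meanlog = log(spec$kes_median),
                        sdlog = sqrt(log(1 + spec$kes_cv^2)))
    dv <- stats::dlnorm(grid$VS, meanlog = log(spec$vs_median),
                        sdlog = sqrt(log(1 + spec$vs_cv^2)))
    w <- dk * dv * grid$KeS * grid$VS  # log-spaced grid: cell width prop. to value
    support <- data.frame(KeS = grid$KeS, VS = grid$VS, weight = w / sum(w))
  }
  structure(list(support = support, spec = spec, seed = seed,
                 approximate = TRUE),
            class = "np_prior")
}

#' @export
print.np_prior <- function(x, ...) {
  cat(sprintf("Discrete nonparametric prior: %d support points (approximate reconstruction)\n",
              nrow(x$support)))
  cat(sprintf("  KeS in [%.3g, %.3g], VS in [%.3g, %.3g], weights sum to %.6f\n",
              min(x$support$KeS), max(x$support$KeS),
              min(x$support$VS), max(x$support$VS), sum(x$support$weight)))
  invisible(x)
}

#' Weighted quantile of a discrete distribution
#'
#' @param x Values.
#' @param w Non-negative weights.
#' @param probs Probabilities.
#' @return Weighted quantiles (type-1 / left-continuous inverse CDF).
#' @keywords internal
weighted_quantile <- function(x, w, probs = 0.5) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}
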