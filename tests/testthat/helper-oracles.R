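# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive quantities by different routes (ODE integration,
# dense quadrature, exhaustive grid search, direct enumeration) rather than
# calling the closed-form/optimizer code paths they check.

# Numerical solution of dC/dt = R0(t)/V - k C over a multi-infusion regimen
# (lsoda, tight tolerances).
ode_concentrations <- function(CL, V, regimen, times) {
  k <- CL / V
  rate_at <- function(t) {
    r <- 0
    for (ev in regimen$events) {
      if (t >= ev$start && t < ev$start + ev$duration)
        r <- r + ev$amount / ev$duration
    }
    r
  }
  deriv <- function(t, y, parms) list(rate_at(t) / V - k * y)
  ev_edges <- unlist(lapply(regimen$events,
                            function(ev) c(ev$start, ev$start + ev$duration)))
  grid <- sort(unique(c(0, times, ev_edges[ev_edges <= max(times)])))
  out <- deSolve::lsoda(c(C = 0), times = grid, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[match(times, out[, "time"]), "C"]
}

# Dense trapezoidal AUC of the model curve over [t0, t1].
trapezoid_auc <- function(params, regimen, t0, t1, step = 1e-4) {
  tt <- seq(t0, t1, by = step)
  cc <- predict_concentration(params, regimen, tt)
  sum((cc[-1] + cc[-length(cc)]) / 2) * step
}

# Exhaustive grid minimization of the MAP objective, with the objective and
# the concentration model re-derived from the formulas (vectorized over the
# grid, independent of the package's optimizer and prediction code).
brute_force_map_eta <- function(spec, cov, regimen, obs,
                                lim = 1.5, step = 0.005) {
  g <- seq(-lim, lim, by = step)
  grid <- expand.grid(e1 = g, e2 = g)
  typ_cl <- spec$cl_ref *
    (cov$body_weight / spec$bw_ref)^(
      if (cov$body_weight < spec$bw_ref) spec$theta_low else spec$theta_high)
  typ_v <- cov$body_weight^spec$theta_v
  CL <- typ_cl * exp(grid$e1)
  V <- typ_v * exp(grid$e2)
  k <- CL / V
  omega2 <- c(log(1 + spec$cv_cl^2), log(1 + spec$cv_v^2))
  obj <- grid$e1^2 / omega2[1] + grid$e2^2 / omega2[2]
  for (i in seq_len(nrow(obs))) {
    t <- obs$time[i]
    pred <- 0
    for (ev in regimen$events) {
      te <- t - ev$start
      if (te <= 0) next
      R0 <- ev$amount / ev$duration
      pred <- pred + if (te <= ev$duration) {
        R0 / CL * (1 - exp(-k * te))
      } else {
        R0 / CL * (1 - exp(-k * ev$duration)) * exp(-k * (te - ev$duration))
      }
    }
    s2 <- (spec$prop_error * pred)^2 + spec$add_error_sd^2
    obj <- obj + (obs$conc[i] - pred)^2 / s2 + log(s2)
  }
  best <- which.min(obj)
  c(grid$e1[best], grid$e2[best])
}

# Direct enumeration of a discrete-prior posterior with hand-rolled normal
# densities (no dnorm).
enumerate_np_posterior <- function(prior_weights, pred_matrix, obs_conc,
                                   sd_intercept = 0.02, sd_slope = 0.1) {
  sds <- sd_intercept + sd_slope * obs_conc
  w <- prior_weights
  for (j in seq_along(w)) {
    lik <- 1
    for (i in seq_along(obs_conc)) {
      z <- (obs_conc[i] - pred_matrix[j, i]) / sds[i]
      lik <- lik * exp(-0.5 * z^2) / (sds[i] * sqrt(2 * pi))
    }
    w[j] <- w[j] * lik
  }
  w / sum(w)
}

# Small fast cohort for structural tests.
tiny_cohort <- function(n = 5, seed = 11, ...) {
  simulate_cohort(cohort_config(n = n, seed = seed, ...))
}
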