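test_that("residual-error rules evaluate to the published formulas", {
  pspec <- parametric_model_spec()
  npspec <- nonparametric_model_spec()
  expect_equal(residual_sd(npspec, 1), 0.12)
  expect_equal(residual_sd(npspec, 0), 0.02)
  expect_equal(residual_sd(pspec, 0), 0.057)  # the 57 ng/mL additive floor
  expect_equal(residual_sd(pspec, 1), sqrt(0.0121 + 0.003249))
  expect_error(residual_sd(pspec, -0.1), "non-negative")
  expect_error(residual_sd(npspec, -1), "non-negative")
})

test_that("MAP with no observations returns the prior mode (typical values)", {
  spec <- parametric_model_spec()
  cov <- patient_covariates(16.7)
  reg <- standard_regimen(20, n_doses = 1)
  fit <- map_fit(spec, cov, reg, data.frame(time = numeric(0),
                                            conc = numeric(0)))
  expect_equal(fit$eta, c(0, 0))
  expect_equal(fit$params$CL, paci_typical_params(cov)$CL)
  expect_true(fit$converged)
})

test_that("observations generated at the typical curve barely move the MAP estimate", {
  spec <- parametric_model_spec()
  set.seed(31)
  for (bw in c(5, 16.7, 40)) {
    cov <- patient_covariates(bw)
    typ <- paci_typical_params(cov, spec)
    reg <- standard_regimen(1.1 * bw, n_doses = 16)
    tt <- c(2.5, 4)
    obs <- data.frame(time = tt, conc = predict_concentration(typ, reg, tt))
    fit <- map_fit(spec, cov, reg, obs)
    # the ln sigma^2 term allows a small pull away from eta = 0, but no more
    expect_lt(max(abs(fit$eta)), 0.02)
    expect_lte(fit$objective,
               busmipd:::.map_objective(c(0, 0), spec, typ, reg, tt, obs$conc,
                                        c(log(1 + spec$cv_cl^2),
                                          log(1 + spec$cv_v^2))))
  }
})

test_that("the MAP optimizer agrees with exhaustive grid search", {
  spec <- parametric_model_spec()
  coh <- tiny_cohort(n = 4, seed = 23)
  for (p in coh) {
    fit <- map_fit(spec, p$covariates, p$regimen, p$observations)
    eta_grid <- brute_force_map_eta(spec, p$covariates, p$regimen,
                                    p$observations)
    expect_lt(max(abs(fit$eta - eta_grid)), 0.005 + 1e-9)
  }
})

test_that("MAP shrinks fully to the prior as residual error grows, and to the data as it vanishes", {
  cov <- patient_covariates(12)
  reg <- standard_regimen(14, n_doses = 16)
  truth <- individual_parameters(
    paci_typical_params(cov)$CL * exp(0.3),
    paci_typical_params(cov)$V * exp(-0.25))
  tt <- c(2.5, 4)
  obs <- data.frame(time = tt, conc = predict_concentration(truth, reg, tt))
  # huge residual SD: the data carry no information
  loose <- parametric_model_spec(prop_error = 1e-6, add_error_sd = 1e3)
  fit_loose <- map_fit(loose, cov, reg, obs)
  expect_lt(max(abs(fit_loose$eta)), 1e-3)
  # tiny residual SD with two informative noiseless samples: curve through
  # the points, parameters recovered within 1%
  tight <- parametric_model_spec(prop_error = 1e-4, add_error_sd = 1e-6)
  fit_tight <- map_fit(tight, cov, reg, obs)
  expect_lt(abs(fit_tight$params$CL - truth$CL) / truth$CL, 0.01)
  expect_lt(abs(fit_tight$params$V - truth$V) / truth$V, 0.01)
})

test_that("discrete-prior posterior reduces to the prior without data and to enumeration with it", {
  spec <- nonparametric_model_spec()
  cov <- patient_covariates(16, height = 150)
  reg <- standard_regimen(18, n_doses = 16)
  prior <- build_np_prior(spec, n_points = 25)
  # no observations: posterior = prior
  post0 <- np_posterior(spec, cov, reg,
                        data.frame(time = numeric(0), conc = numeric(0)),
                        prior = prior)
  expect_equal(post0$support$weight, prior$support$weight)
  # single support point: weight 1 whatever the data
  pr1 <- build_np_prior(spec, n_points = 1)
  post1 <- np_posterior(spec, cov, reg,
                        data.frame(time = c(2.5, 4), conc = c(0.9, 0.5)),
                        prior = pr1)
  expect_equal(post1$support$weight, 1)
  # 5-point prior vs independent enumeration, exact to 1e-12
  pr5 <- build_np_prior(spec, n_points = 1)
  pr5$support <- data.frame(
    KeS = c(0.45, 0.6, 0.71, 0.85, 0.95),
    VS = c(0.6, 0.9, 0.72, 1.1, 0.55),
    weight = c(0.1, 0.2, 0.4, 0.2, 0.1))
  obs <- data.frame(time = c(2.5, 4), conc = c(0.85, 0.45))
  post5 <- np_posterior(spec, cov, reg, obs, prior = pr5)
  size <- min(16, traub_johnson_ibw(150))
  pred <- t(vapply(seq_len(5), function(j) {
    V <- pr5$support$VS[j] * size
    Ke <- pr5$support$KeS[j] * size^(-0.25)
    predict_concentration(individual_parameters(Ke * V, V), reg, obs$time)
  }, numeric(2)))
  expected <- enumerate_np_posterior(pr5$support$weight, pred, obs$conc)
  expect_equal(post5$support$weight, expected, tolerance = 1e-12)
  expect_false(post5$degenerate_likelihood)
})

test_that("posterior weights always normalize and the mean stays in the support hull", {
  spec <- nonparametric_model_spec()
  prior <- build_np_prior(spec, n_points = 100)
  set.seed(99)
  for (i in 1:6) {
    cov <- patient_covariates(runif(1, 4, 60), height = runif(1, 60, 170))
    reg <- standard_regimen(1.1 * cov$body_weight, n_doses = 16)
    # observations consistent with a random support point, plus noise
    truth <- neely_params(runif(1, 0.45, 0.95), runif(1, 0.55, 1.3), cov)
    obs <- data.frame(time = c(2.5, 4),
                      conc = predict_concentration(truth, reg, c(2.5, 4)) *
                        exp(rnorm(2, 0, 0.1)))
    post <- np_posterior(spec, cov, reg, obs, prior = prior)
    expect_equal(sum(post$support$weight), 1, tolerance = 1e-12)
    expect_gte(post$posterior_mean["KeS"], min(prior$support$KeS))
    expect_lte(post$posterior_mean["KeS"], max(prior$support$KeS))
    expect_gte(post$posterior_mean["VS"], min(prior$support$VS))
    expect_lte(post$posterior_mean["VS"], max(prior$support$VS))
  }
})

test_that("gross outlier data trigger the uniform-posterior fallback diagnostic", {
  spec <- nonparametric_model_spec()
  cov <- patient_covariates(16, height = 150)
  reg <- standard_regimen(100, n_doses = 1)
  prior <- build_np_prior(spec, n_points = 25)
  # zero measured after a 100-mg infusion: impossible under every support
  # point, all likelihoods underflow
  obs <- data.frame(time = c(2.5, 4), conc = c(0, 0))
  expect_warning(post <- np_posterior(spec, cov, reg, obs, prior = prior),
                 "uniform")
  expect_true(post$degenerate_likelihood)
  expect_equal(post$support$weight, rep(1 / 25, 25))
})

test_that("exposure summaries follow the fit type: MAP point vs posterior mean", {
  # MAP fit at CL = 2.18 dosing 10.9 mg q6h x16 gives the 80 mg.h/L course
  spec <- parametric_model_spec()
  cov <- patient_covariates(9)  # typical CL exactly 2.18
  reg <- standard_regimen(10.9, n_doses = 16)
  fit <- map_fit(spec, cov, reg, NULL)
  e <- individual_auc_and_dose(fit, reg)
  expect_equal(e$auc_cum, 16 * 10.9 / 2.18, tolerance = 1e-12)
  expect_lt(e$auc_first, e$auc_cum)

  # single-support posterior reduces to the parametric evaluation at that point
  npspec <- nonparametric_model_spec()
  covh <- patient_covariates(16, height = 150)
  pr1 <- build_np_prior(npspec, n_points = 1)
  post <- np_posterior(npspec, covh, reg,
                       data.frame(time = 2.5, conc = 0.8), prior = pr1)
  en <- individual_auc_and_dose(post, reg)
  pt <- individual_parameters(post$support$CL[1], post$support$V[1])
  expect_equal(en$auc_first, auc_interval(pt, reg, 0, 6))
  expect_equal(en$auc_cum, auc_cumulative(pt, reg))

  # posterior-mean AUC is a convex combination of per-support AUCs
  pr <- build_np_prior(npspec, n_points = 49)
  post2 <- np_posterior(npspec, covh, reg,
                        data.frame(time = c(2.5, 4), conc = c(0.9, 0.5)),
                        prior = pr)
  e2 <- individual_auc_and_dose(post2, reg)
  aucs <- vapply(seq_len(nrow(post2$support)), function(j)
    auc_cumulative(individual_parameters(post2$support$CL[j],
                                         post2$support$V[j]), reg),
    numeric(1))
  expect_gte(e2$auc_cum, min(aucs))
  expect_lte(e2$auc_cum, max(aucs))
})
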