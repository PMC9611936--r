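test_that("domain objects enforce their invariants", {
  expect_error(dose_event(-1, 0, 2), "non-negative")
  expect_error(dose_event(10, 0, 0), "bolus")
  expect_error(dose_event(10, -1, 2), "start")
  expect_error(individual_parameters(0, 5), "CL")
  expect_error(individual_parameters(2, -1), "V")
  expect_error(regimen(list(dose_event(10, 0, 2), dose_event(10, 0, 2))),
               "share a start")
  p <- individual_parameters(2.18, 6.62)
  expect_equal(p$k, 2.18 / 6.62)
})

test_that("no drug has been infused at time zero and predictions are linear in dose", {
  p <- individual_parameters(2.18, 6.62)
  r <- standard_regimen(10.9, n_doses = 1)
  expect_identical(predict_concentration(p, r, 0), 0)
  r2 <- standard_regimen(21.8, n_doses = 16)
  r1 <- standard_regimen(10.9, n_doses = 16)
  tt <- c(0.5, 2, 2.5, 4, 7, 26, 95)
  expect_equal(predict_concentration(p, r2, tt),
               2 * predict_concentration(p, r1, tt))
})

test_that("closed-form concentrations match numerical ODE integration", {
  p <- individual_parameters(2.18, 6.62)
  r <- standard_regimen(10.9, n_doses = 1)
  tt <- c(2.5, 6)
  expect_equal(predict_concentration(p, r, tt),
               ode_concentrations(2.18, 6.62, r, tt),
               tolerance = 1e-4)
  # 20 random parameter/regimen draws, multi-dose
  set.seed(42)
  for (i in 1:20) {
    CL <- runif(1, 0.5, 15)
    V <- runif(1, 2, 50)
    nd <- sample(1:4, 1)
    dur <- runif(1, 0.5, 3)
    reg <- standard_regimen(runif(1, 5, 80), n_doses = nd, interval = 6,
                            duration = dur)
    tt <- sort(runif(3, 0.1, nd * 6 + 4))
    closed <- predict_concentration(individual_parameters(CL, V), reg, tt)
    numeric <- ode_concentrations(CL, V, reg, tt)
    expect_equal(closed, numeric, tolerance = 1e-4)
  }
})

test_that("concentration is continuous at the end of each infusion", {
  p <- individual_parameters(3.1, 12)
  r <- standard_regimen(20, n_doses = 3)
  eps <- 1e-10
  for (tend in c(2, 8, 14)) {
    left <- predict_concentration(p, r, tend - eps)
    right <- predict_concentration(p, r, tend + eps)
    expect_lt(abs(left - right), 1e-8)
  }
})

test_that("multi-dose prediction is the superposition of shifted single doses", {
  p <- individual_parameters(2.5, 10)
  two <- regimen(list(dose_event(15, 0, 2), dose_event(15, 6, 2)))
  one_a <- regimen(list(dose_event(15, 0, 2)))
  one_b <- regimen(list(dose_event(15, 6, 2)))
  tt <- seq(0, 20, by = 0.25)
  expect_equal(predict_concentration(p, two, tt),
               predict_concentration(p, one_a, tt) +
                 predict_concentration(p, one_b, tt),
               tolerance = 1e-12)
})

test_that("AUC identities hold: dose/CL, window additivity, cumulative limit", {
  p <- individual_parameters(2.18, 11.26)
  r <- standard_regimen(10.9, n_doses = 1)
  expect_equal(auc_interval(p, r, 0, Inf), 10.9 / 2.18, tolerance = 1e-12)
  expect_lt(auc_interval(p, r, 0, 6), 10.9 / 2.18)
  # additivity over abutting windows
  full <- standard_regimen(10.9, n_doses = 16)
  expect_equal(auc_interval(p, full, 0, 13) + auc_interval(p, full, 13, 40),
               auc_interval(p, full, 0, 40), tolerance = 1e-9)
  # cumulative AUC equals the course integral in the long-time limit
  t_half <- log(2) / p$k
  t_long <- 16 * 6 + 50 * t_half
  expect_equal(auc_interval(p, full, 0, t_long), auc_cumulative(p, full),
               tolerance = 1e-6)
  # 16 x 10.9 mg at CL 2.18 gives the conventional 80 mg.h/L course
  expect_equal(auc_cumulative(p, full), 80)
  # order of equal dose events does not matter
  ev <- list(dose_event(10, 6, 2), dose_event(10, 0, 2))
  expect_equal(auc_cumulative(p, regimen(ev)),
               auc_cumulative(p, regimen(rev(ev))))
})

test_that("windowed AUC matches dense trapezoidal quadrature", {
  set.seed(7)
  for (i in 1:5) {
    p <- individual_parameters(runif(1, 1, 8), runif(1, 4, 30))
    r <- standard_regimen(runif(1, 10, 60), n_doses = 2)
    a_closed <- auc_interval(p, r, 0, 6)
    a_trap <- trapezoid_auc(p, r, 0, 6)
    expect_equal(a_closed, a_trap, tolerance = 1e-4)
  }
  expect_error(auc_interval(p, r, 4, 4), "t0 < t1")
})

test_that("AUC unit conversion reproduces the conventional target span and round-trips", {
  lo <- convert_auc(900, "uM.min", "mg.h/L")
  hi <- convert_auc(1500, "uM.min", "mg.h/L")
  expect_lt(abs(lo - 3.7), 0.1)  # printed as 3.7 mg.h/L
  expect_lt(abs(hi - 6.1), 0.1)  # printed as 6.1 mg.h/L
  expect_equal(convert_auc(lo, "mg.h/L", "uM.min"), 900, tolerance = 1e-12)
  x <- c(0.3, 47, 1234)
  expect_equal(convert_auc(convert_auc(x, "mg.h/L", "uM.min"),
                           "uM.min", "mg.h/L"), x, tolerance = 1e-12)
  expect_error(convert_auc(1, "mol", "mg.h/L"), "unit")
})
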