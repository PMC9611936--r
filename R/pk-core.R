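#' Create a single intravenous infusion dose event
#'
#' A dose event is a zero-order (constant-rate) infusion of a given drug mass,
#' starting at a given time relative to the start of the first dose of the
#' course.
#'
#' @param amount Drug mass infused (mg). Must be non-negative.
#' @param start Infusion start time (h since start of first dose). Must be
#'   non-negative.
#' @param duration Infusion duration (h). Must be strictly positive; true
#'   bolus inputs (duration below 1e-6 h) are rejected because intravenous
#'   busulfan is always given as an infusion.
#' @return An object of class `dose_event` with fields `amount`, `start`,
#'   `duration`.
#' @examples
#' dose_event(35, start = 0, duration = 2)
#' @export
dose_event <- function(amount, start = 0, duration = 2) {
  stopifnot(is.numeric(amount), length(amount) == 1L,
            is.numeric(start), length(start) == 1L,
            is.numeric(duration), length(duration) == 1L)
  if (!is.finite(amount) || amount < 0)
    stop("dose amount must be a finite non-negative number (mg)")
  if (!is.finite(start) || start < 0)
    stop("dose start time must be a finite non-negative number (h)")
  if (!is.finite(duration) || duration <= 1e-6)
    stop("infusion duration must exceed 1e-6 h; bolus events are not supported")
  structure(list(amount = amount, start = start, duration = duration),
            class = "dose_event")
}

#' Create a dosing regimen (ordered list of infusion events)
#'
#' @param events List of [dose_event()] objects. They are sorted by start
#'   time; two events sharing a start time are rejected.
#' @param interval Nominal inter-dose interval (h), carried as metadata.
#' @return An object of class `regimen` with fields `events`, `interval`,
#'   `n_doses`.
#' @seealso [standard_regimen()] for the conventional q6h course.
#' @export
regimen <- function(events, interval = NA_real_) {
  if (length(events) < 1L) stop("a regimen needs at least one dose event")
  ok <- vapply(events, inherits, logical(1), what = "dose_event")
  if (!all(ok)) stop("all elements of `events` must be dose_event objects")
  starts <- vapply(events, `[[`, numeric(1), "start")
  events <- events[order(starts)]
  starts <- sort(starts)
  if (anyDuplicated(starts)) stop("two dose events share a start time")
  structure(list(events = events, interval = interval,
                 n_doses = length(events)),
            class = "regimen")
}

#' Conventional busulfan course: repeated identical infusions
#'
#' Builds the standard conditioning course of `n_doses` identical zero-order
#' infusions every `interval` hours (default: 16 doses of 2-h infusions every
#' 6 h over 4 days).
#'
#' @param dose Dose per administration (mg).
#' @param n_doses Number of administrations.
#' @param interval Inter-dose interval (h).
#' @param duration Infusion duration (h).
#' @return A `regimen` object.
#' @examples
#' standard_regimen(10.9)               # 16 x 10.9 mg, q6h, 2-h infusions
#' standard_regimen(35, n_doses = 1)    # single test dose
#' @export
standard_regimen <- function(dose, n_doses = 16L, interval = 6, duration = 2) {
  stopifnot(n_doses >= 1L)
  ev <- lapply(seq_len(n_doses) - 1L,
               function(i) dose_event(dose, start = i * interval,
                                      duration = duration))
  regimen(ev, interval = interval)
}

#' Individual one-compartment parameters
#'
#' @param CL Total body clearance (L/h), strictly positive.
#' @param V Volume of distribution (L), strictly positive.
#' @return An object of class `individual_parameters` with fields `CL`, `V`
#'   and the derived elimination rate constant `k = CL/V` (1/h).
#' @export
individual_parameters <- function(CL, V) {
  if (!is.numeric(CL) || length(CL) != 1L || !is.finite(CL) || CL <= 0)
    stop("CL must be a single finite positive number (L/h)")
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
    stop("V must be a single finite positive number (L)")
  structure(list(CL = CL, V = V, k = CL / V),
            class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf("Individual PK parameters: CL = %.4g L/h, V = %.4g L, k = %.4g 1/h\n",
              x$CL, x$V, x$k))
  invisible(x)
}

#' @export
print.regimen <- function(x, ...) {
  amt <- vapply(x$events, `[[`, numeric(1), "amount")
  cat(sprintf("Regimen: %d dose(s), total %.4g mg", x$n_doses, sum(amt)))
  if (is.finite(x$interval)) cat(sprintf(", nominal interval %g h", x$interval))
  cat("\n")
  invisible(x)
}

## Per-event closed forms ----------------------------------------------------
## Concentration contribution of one zero-order infusion at elapsed time te
## (te = t - start): rising R0/CL*(1 - exp(-k te)) during the infusion, then
## mono-exponential decay from the end-of-infusion concentration.

.event_conc <- function(amount, duration, CL, k, te) {
  R0 <- amount / duration
  css <- R0 / CL
  conc <- numeric(length(te))
  during <- te > 0 & te <= duration
  after <- te > duration
  conc[during] <- css * (1 - exp(-k * te[during]))
  cend <- css * (1 - exp(-k * duration))
  conc[after] <- cend * exp(-k * (te[after] - duration))
  conc
}

## Cumulative AUC of one event from its own start to elapsed time te (>= 0).
.event_auc <- function(amount, duration, CL, k, te) {
  R0 <- amount / duration
  css <- R0 / CL
  auc <- numeric(length(te))
  during <- te > 0 & te <= duration
  after <- te > duration
  auc[during] <- css * (te[during] - (1 - exp(-k * te[during])) / k)
  auc_inf_end <- css * (duration - (1 - exp(-k * duration)) / k)
  cend <- css * (1 - exp(-k * duration))
  auc[after] <- auc_inf_end +
    cend / k * (1 - exp(-k * (te[after] - duration)))
  auc
}

#' Predict busulfan concentrations under a regimen
#'
#' Closed-form one-compartment prediction with zero-order infusion input and
#' first-order elimination, superposed over all dose events of the regimen.
#' Concentrations are in mg/L.
#'
#' @param params [individual_parameters()] object.
#' @param regimen [regimen()] object.
#' @param times Numeric vector of times (h since start of first dose), all
#'   non-negative.
#' @return Numeric vector of concentrations (mg/L), same length as `times`.
#' @examples
#' p <- individual_parameters(CL = 2.18, V = 6.62)
#' r <- standard_regimen(10.9, n_doses = 1)
#' predict_concentration(p, r, c(0, 0.5, 2, 2.5, 4, 6))
#' @export
predict_concentration <- function(params, regimen, times) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(regimen, "regimen"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("prediction times must be finite and non-negative")
  conc <- numeric(length(times))
  for (ev in regimen$events) {
    conc <- conc + .event_conc(ev$amount, ev$duration, params$CL, params$k,
                               times - ev$start)
  }
  conc
}

#' Area under the concentration-time curve over a time window
#'
#' Exact integral of the superposed closed-form concentration curve over
#' `[t0, t1]`, in mg.h/L. `t1 = Inf` gives the integral to infinity.
#'
#' @inheritParams predict_concentration
#' @param t0,t1 Window bounds (h), `0 <= t0 < t1`.
#' @return AUC over the window (mg.h/L).
#' @examples
#' p <- individual_parameters(CL = 2.18, V = 11.26)
#' r <- standard_regimen(10.9, n_doses = 1)
#' auc_interval(p, r, 0, 6)    # AUC over the first 6 h
#' auc_interval(p, r, 0, Inf)  # equals dose/CL = 5 mg.h/L
#' @export
auc_interval <- function(params, regimen, t0, t1) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(regimen, "regimen"))
  if (!is.numeric(t0) || !is.numeric(t1) || length(t0) != 1L ||
      length(t1) != 1L || is.na(t0) || is.na(t1))
    stop("t0 and t1 must be single numbers")
  if (t0 < 0 || t1 <= t0) stop("need 0 <= t0 < t1")
  total <- 0
  for (ev in regimen$events) {
    if (is.infinite(t1)) {
      a1 <- ev$amount / params$CL     # per-event AUC to infinity
    } else {
      a1 <- .event_auc(ev$amount, ev$duration, params$CL, params$k,
                       t1 - ev$start)
    }
    a0 <- .event_auc(ev$amount, ev$duration, params$CL, params$k,
                     t0 - ev$start)
    total <- total + (a1 - a0)
  }
  total
}

#' Cumulative AUC of the whole course
#'
#' Total exposure from time zero to infinity under linear elimination:
#' total administered dose divided by clearance.
#'
#' @inheritParams predict_concentration
#' @return Cumulative AUC (mg.h/L).
#' @examples
#' p <- individual_parameters(CL = 2.18, V = 11.26)
#' auc_cumulative(p, standard_regimen(10.9))  # 16 x 10.9 / 2.18 = 80
#' @export
auc_cumulative <- function(params, regimen) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(regimen, "regimen"))
  total_dose <- sum(vapply(regimen$events, `[[`, numeric(1), "amount"))
  total_dose / params$CL
}

#' Convert AUC values between µM·min and mg·h/L
#'
#' The conventional busulfan per-dose target of 900–1500 µM·min corresponds
#' to 3.7–6.1 mg·h/L: mg·h/L = µM·min × molar mass / 60000.
#'
#' @param value Numeric AUC value(s).
#' @param from,to Units, each one of `"uM.min"` or `"mg.h/L"`.
#' @param molar_mass Molar mass (g/mol); default 246.30 for busulfan.
#' @return Converted value(s).
#' @examples
#' convert_auc(900, "uM.min", "mg.h/L")   # 3.69
#' convert_auc(1500, "uM.min", "mg.h/L")  # 6.16
#' @export
convert_auc <- function(value, from, to, molar_mass = 246.30) {
  units <- c("uM.min", "mg.h/L")
  if (!(from %in% units) || !(to %in% units))
    stop("units must be one of 'uM.min', 'mg.h/L'")
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be positive")
  if (from == to) return(value)
  if (from == "uM.min") value * molar_mass / 60000 else value * 60000 / molar_mass
}
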