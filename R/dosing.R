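#' Dose per administration to reach a target cumulative AUC
#'
#' Under linear elimination the cumulative AUC of the whole course is total
#' dose / CL, so the per-administration dose attaining a target cumulative
#' AUC is target x CL / n_doses. The recommendation is verified by
#' re-simulating the recommended regimen through the PK engine.
#'
#' @param CL Individual clearance (L/h); for a nonparametric fit, the
#'   posterior-mean clearance.
#' @param target Target cumulative AUC (mg.h/L), non-negative. The
#'   conventional conditioning target is 80 mg.h/L over 16 doses.
#' @param n_doses Number of administrations (>= 1).
#' @param interval Inter-dose interval (h); metadata only — the cumulative
#'   AUC depends on total dose and CL, not on the schedule.
#' @param duration Infusion duration (h); metadata only, as above.
#' @param round_to Optional practical rounding increment (mg), e.g. 0.5;
#'   `NULL` (default) leaves the raw dose, which is what model comparisons
#'   use.
#' @param model Optional model identity label carried into the record.
#' @return An object of class `dose_recommendation`: `dose` (mg per
#'   administration), `n_doses`, `interval`, `duration`, `target`,
#'   `predicted_auc_cum` (re-simulated, mg.h/L), `model`.
#' @examples
#' dose_for_target_auc(CL = 2.18, target = 80)  # 10.9 mg per dose
#' @export
dose_for_target_auc <- function(CL, target = 80, n_doses = 16L, interval = 6,
                                duration = 2, round_to = NULL,
                                model = NA_character_) {
  if (!is.numeric(CL) || length(CL) != 1L || !is.finite(CL) || CL <= 0)
    stop("CL must be a single positive number (L/h)")
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target < 0)
    stop("target cumulative AUC must be non-negative (mg.h/L)")
  stopifnot(n_doses >= 1L)
  dose <- target * CL / n_doses
  if (!is.null(round_to)) dose <- round(dose / round_to) * round_to
  predicted <- if (dose > 0) {
    auc_cumulative(individual_parameters(CL, V = 1),
                   standard_regimen(dose, n_doses = n_doses,
                                    interval = interval, duration = duration))
  } else 0
  structure(list(dose = dose, n_doses = as.integer(n_doses),
                 interval = interval, duration = duration, target = target,
                 predicted_auc_cum = predicted, model = model),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "Dose recommendation%s: %.2f mg per dose x %d (q%gh, %g-h infusion)\n",
    if (is.na(x$model)) "" else sprintf(" [%s]", x$model),
    x$dose, x$n_doses, x$interval, x$duration))
  cat(sprintf("  target AUC_cum %.4g mg.h/L; re-simulated AUC_cum %.6g mg.h/L\n",
              x$target, x$predicted_auc_cum))
  invisible(x)
}

#' Convert between per-dose and cumulative AUC target ranges
#'
#' The conventional per-dose target of 3.7-6.1 mg.h/L over a 16-dose course
#' corresponds to a cumulative target of roughly 60-100 mg.h/L. Division by
#' the number of doses (and its inverse) is exact; the published cumulative
#' bounds involve rounding.
#'
#' @param range Numeric length-2 vector (lower, upper).
#' @param n_doses Number of doses in the course.
#' @param direction `"cum_to_per_dose"` or `"per_dose_to_cum"`.
#' @return Numeric length-2 converted range.
#' @examples
#' per_dose_target_range(c(60, 100), 16)                  # 3.75 - 6.25 per dose
#' per_dose_target_range(c(5, 5), 16, "per_dose_to_cum")  # 80 cumulative
#' @export
per_dose_target_range <- function(range, n_doses = 16L,
                                  direction = c("cum_to_per_dose",
                                                "per_dose_to_cum")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(range), length(range) == 2L, n_doses >= 1L)
  if (direction == "cum_to_per_dose") range / n_doses else range * n_doses
}
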