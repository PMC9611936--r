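#' Read a NONMEM-style event dataset
#'
#' One flat CSV per cohort with one row per event. Required columns
#' (case-insensitive): `ID`, `TIME` (h), `TYPE` (`dose` or `observation`),
#' `AMT` (mg, dose rows), `DUR` (h, dose rows), `DV` (concentration,
#' observation rows), `BW` (kg). Optional: `DVUNIT` (`ng/mL`, the TDM
#' reporting default, or `mg/L`), `HT` (cm), `AGE` (yr), `SEX`. Dose rows
#' must not carry DV and observation rows must not carry AMT; covariates are
#' taken from each patient's first row (later conflicting values are
#' reported).
#'
#' @param path CSV file path.
#' @param dv_unit Default unit for `DV` when no `DVUNIT` column is present;
#'   concentrations are stored internally in mg/L (1 mg/L = 1000 ng/mL).
#' @return A list of class `cohort`: per patient `id`, `covariates`,
#'   `regimen`, `observations` (`time`, `conc` in mg/L).
#' @export
read_dataset <- function(path, dv_unit = "ng/mL") {
  if (!file.exists(path)) stop("dataset not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  needed <- c("ID", "TIME", "TYPE", "AMT", "DUR", "DV", "BW")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (opt in c("DVUNIT", "HT", "AGE", "SEX"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  raw$TYPE <- tolower(raw$TYPE)
  if (!all(raw$TYPE %in% c("dose", "observation")))
    stop("TYPE must be 'dose' or 'observation'")
  if (any(!is.finite(raw$TIME)) || any(raw$TIME < 0))
    stop("TIME must be finite and non-negative at row(s): ",
         paste(which(!is.finite(raw$TIME) | raw$TIME < 0), collapse = ", "))

  is_dose <- raw$TYPE == "dose"
  bad <- which(is_dose & !is.na(raw$DV))
  if (length(bad)) stop("dose row carries DV at row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!is_dose & !is.na(raw$AMT))
  if (length(bad)) stop("observation row carries AMT at row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(is_dose & (is.na(raw$AMT) | raw$AMT < 0))
  if (length(bad)) stop("dose row with missing/negative AMT at row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!is_dose & (is.na(raw$DV) | raw$DV < 0))
  if (length(bad)) stop("observation row with missing/negative DV at row(s): ",
                        paste(bad, collapse = ", "))

  unit <- ifelse(is.na(raw$DVUNIT) | raw$DVUNIT == "", dv_unit, raw$DVUNIT)
  if (!all(unit %in% c("ng/mL", "mg/L")))
    stop("DV unit must be 'ng/mL' or 'mg/L'")
  dv_mgL <- ifelse(unit == "ng/mL", raw$DV / 1000, raw$DV)

  patients <- lapply(split(seq_len(nrow(raw)), raw$ID), function(idx) {
    sub <- raw[idx, ]
    first <- sub[1, ]
    for (colname in c("BW", "HT", "AGE", "SEX")) {
      vals <- unique(sub[[colname]][!is.na(sub[[colname]])])
      if (length(vals) > 1)
        message("patient ", first$ID, ": conflicting ", colname,
                " values; first row wins")
    }
    cov <- patient_covariates(
      body_weight = first$BW,
      height = if (is.na(first$HT)) NA_real_ else first$HT,
      age = if (is.na(first$AGE)) NA_real_ else first$AGE,
      sex = if (is.na(first$SEX)) NA_character_ else tolower(first$SEX))
    drows <- sub[sub$TYPE == "dose", ]
    if (nrow(drows) == 0) stop("patient ", first$ID, " has no dose events")
    ev <- lapply(seq_len(nrow(drows)), function(j)
      dose_event(drows$AMT[j], start = drows$TIME[j],
                 duration = drows$DUR[j]))
    orows <- which(sub$TYPE == "observation")
    list(id = as.character(first$ID), covariates = cov,
         regimen = regimen(ev),
         observations = data.frame(time = sub$TIME[orows],
                                   conc = dv_mgL[idx][orows]))
  })
  structure(unname(patients[order(names(patients))]), class = "cohort")
}

#' Write a cohort as a NONMEM-style event dataset
#'
#' Inverse of [read_dataset()]: emits one dose row per infusion event and
#' one observation row per concentration, with covariates repeated on every
#' row of the patient.
#'
#' @param cohort A `cohort` object.
#' @param path Output CSV path.
#' @param dv_unit Unit to write `DV` in (`"ng/mL"` default, or `"mg/L"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path, dv_unit = "ng/mL") {
  stopifnot(inherits(cohort, "cohort"), dv_unit %in% c("ng/mL", "mg/L"))
  rows <- lapply(cohort, function(p) {
    cov <- p$covariates
    dose_rows <- do.call(rbind, lapply(p$regimen$events, function(ev)
      data.frame(ID = p$id, TIME = ev$start, TYPE = "dose", AMT = ev$amount,
                 DUR = ev$duration, DV = NA_real_, DVUNIT = dv_unit)))
    obs <- p$observations
    obs_rows <- if (nrow(obs)) {
      dv <- if (dv_unit == "ng/mL") obs$conc * 1000 else obs$conc
      data.frame(ID = p$id, TIME = obs$time, TYPE = "observation",
                 AMT = NA_real_, DUR = NA_real_, DV = dv, DVUNIT = dv_unit)
    } else NULL
    out <- rbind(dose_rows, obs_rows)
    out <- out[order(out$TIME, out$TYPE), ]
    out$BW <- cov$body_weight
    out$HT <- cov$height
    out$AGE <- cov$age
    out$SEX <- cov$sex
    out
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-patient fit results as JSON lines
#'
#' One JSON object per patient per line: parameters, eta or posterior-weight
#' summary, predictions, AUCs, dose recommendation and convergence
#' diagnostics.
#'
#' @param results Per-patient result list (each element a named list of
#'   scalars/vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_jsonl <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in results)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Write a provenance record for a run
#'
#' Every run directory gets a provenance file echoing the configuration,
#' seed and model constants actually used (including the ideal-body-weight
#' formula variant and residual-error rules), so results are auditable.
#'
#' @param dir Run directory (created if needed).
#' @param seed Seed used.
#' @param config Optional configuration object to echo.
#' @param extra Optional named list of additional entries.
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, seed, config = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "provenance.json")
  pspec <- parametric_model_spec()
  npspec <- nonparametric_model_spec()
  record <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("busmipd")),
    seed = seed,
    ibw_formula = "height^2 * 1.65 / 1000 (Traub-Johnson default variant)",
    parametric_model = unclass(pspec)[setdiff(names(unclass(pspec)), "type")],
    nonparametric_model = unclass(npspec)[setdiff(names(unclass(npspec)), "type")],
    np_prior_note = "discrete prior is an approximate reconstruction from published summaries",
    config = if (!is.null(config)) unclass(config) else NULL),
    extra)
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE), path)
  invisible(path)
}
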