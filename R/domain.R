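# Domain vocabulary and record validators.
#
# A cohort is a tibble with one row per clinic attendance; multi-valued
# fields (medication classes, investigations) are list-columns of character
# sets. Follow-up is optional: patients lost to follow-up carry
# followed_up = FALSE and empty outcome columns, and are excluded from
# concordance denominators.

#' Controlled vocabularies
#'
#' Category levels used throughout the package: pain typicality, risk level,
#' the three secondary-prevention medication classes the decision support
#' system may recommend, recommendable investigations, and the (wider) set of
#' qualifying investigations that may be observed at follow-up.
#'
#' @name vocabulary
#' @keywords internal
NULL

TYPICALITY_LEVELS <- c("typical", "atypical", "non_anginal")
RISK_LEVELS <- c("low", "high")
SEX_LEVELS <- c("male", "female")
GROUP_LEVELS <- c("before", "after")
MED_CLASSES <- c("antiplatelet", "beta_blocker", "statin")
INVESTIGATIONS <- c("none", "ct_calcium_scoring", "functional_imaging",
                    "invasive_angiography")
FOLLOWUP_INVESTIGATIONS <- c("ct_calcium_scoring", "ct_angiography",
                             "functional_imaging", "invasive_angiography",
                             "other")
AGE_VALID_RANGE <- c(18L, 120L)

#' Construct a patient-presentation record
#'
#' One clinic attendance: demographics, the three binary cardiovascular risk
#' factors plus resting-ECG status, the three pain-characteristic answers on
#' which typicality is classified, and the medication classes current at the
#' clinic date.
#'
#' @param patient_id opaque identifier string.
#' @param age age in whole years, within `[18, 120]`.
#' @param sex `"male"` or `"female"`.
#' @param smoker,diabetes,hyperlipidaemia,ecg_abnormal logical risk flags.
#' @param pain_constricting,pain_exertional,pain_relieved_by_rest_or_gtn
#'   logical answers to the three pain-characteristic questions; must not be
#'   missing.
#' @param baseline_med_classes character vector, a subset of
#'   `c("antiplatelet", "beta_blocker", "statin")`.
#' @param group study group, `"before"` or `"after"`.
#' @param site opaque site label.
#' @param cdss_used whether the decision support system was used at the
#'   consultation.
#' @return a one-row cohort tibble (see [read_cohort()] for the full schema).
#' @export
patient_presentation <- function(patient_id, age, sex,
                                 smoker = FALSE, diabetes = FALSE,
                                 hyperlipidaemia = FALSE, ecg_abnormal = FALSE,
                                 pain_constricting, pain_exertional,
                                 pain_relieved_by_rest_or_gtn,
                                 baseline_med_classes = character(0),
                                 group = "before", site = "site_a",
                                 cdss_used = FALSE) {
  row <- tibble::tibble(
    patient_id = as.character(patient_id),
    age = as.integer(age),
    sex = as.character(sex),
    smoker = as.logical(smoker),
    diabetes = as.logical(diabetes),
    hyperlipidaemia = as.logical(hyperlipidaemia),
    ecg_abnormal = as.logical(ecg_abnormal),
    pain_constricting = as.logical(pain_constricting),
    pain_exertional = as.logical(pain_exertional),
    pain_relieved_by_rest_or_gtn = as.logical(pain_relieved_by_rest_or_gtn),
    baseline_meds = list(unique(as.character(baseline_med_classes))),
    group = as.character(group),
    site = as.character(site),
    cdss_used = as.logical(cdss_used),
    followed_up = FALSE,
    investigations_6m = list(character(0)),
    meds_6m = list(character(0))
  )
  validate_cohort(row)
}

#' Attach a six-month follow-up outcome to a patient row
#'
#' @param patient a one-row cohort tibble (e.g. from
#'   [patient_presentation()]).
#' @param investigations_done character vector of qualifying investigations
#'   performed within six months of the clinic (may be empty).
#' @param followup_med_classes medication classes current at six months.
#' @return the row with follow-up fields populated and `followed_up = TRUE`.
#' @export
with_followup <- function(patient, investigations_done = character(0),
                          followup_med_classes = character(0)) {
  patient$followed_up <- TRUE
  patient$investigations_6m <- list(unique(as.character(investigations_done)))
  patient$meds_6m <- list(unique(as.character(followup_med_classes)))
  validate_cohort(patient)
}

COHORT_COLUMNS <- c("patient_id", "age", "sex", "smoker", "diabetes",
                    "hyperlipidaemia", "ecg_abnormal", "pain_constricting",
                    "pain_exertional", "pain_relieved_by_rest_or_gtn",
                    "baseline_meds", "group", "site", "cdss_used",
                    "followed_up", "investigations_6m", "meds_6m")

#' Validate a cohort table
#'
#' Checks the structural invariants of a cohort: required columns, age inside
#' the validity range, known category levels, all three pain answers present,
#' medication classes drawn from the three-class vocabulary, and follow-up
#' investigations drawn from the qualifying list. Errors name the offending
#' rows.
#'
#' @param cohort a cohort tibble.
#' @return the cohort, invisibly unchanged, if valid.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    cdss_abort(paste0("cohort is missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "cdss_schema_error")
  }
  bad <- function(rows, what) {
    if (any(rows)) {
      cdss_abort(paste0("invalid ", what, " in row(s): ",
                        paste(which(rows), collapse = ", ")),
                 "cdss_validation_error")
    }
  }
  bad(is.na(cohort$age) | cohort$age < AGE_VALID_RANGE[1] |
        cohort$age > AGE_VALID_RANGE[2], "age (must be in [18, 120])")
  bad(!(cohort$sex %in% SEX_LEVELS), "sex")
  bad(!(cohort$group %in% GROUP_LEVELS), "group")
  for (f in c("smoker", "diabetes", "hyperlipidaemia", "ecg_abnormal",
              "cdss_used", "followed_up")) {
    bad(is.na(cohort[[f]]), f)
  }
  for (f in c("pain_constricting", "pain_exertional",
              "pain_relieved_by_rest_or_gtn")) {
    bad(is.na(cohort[[f]]), paste0(f, " (pain answers must not be missing)"))
  }
  bad(!vapply(cohort$baseline_meds,
              function(v) all(v %in% MED_CLASSES) && !anyDuplicated(v),
              logical(1)), "baseline_meds")
  bad(!vapply(cohort$meds_6m,
              function(v) all(v %in% MED_CLASSES) && !anyDuplicated(v),
              logical(1)), "meds_6m")
  bad(!vapply(cohort$investigations_6m,
              function(v) all(v %in% FOLLOWUP_INVESTIGATIONS),
              logical(1)), "investigations_6m")
  bad(!cohort$followed_up &
        (lengths(cohort$investigations_6m) > 0 | lengths(cohort$meds_6m) > 0),
      "follow-up fields on a patient marked not followed up")
  bad(duplicated(cohort$patient_id), "patient_id (duplicate)")
  invisible(cohort)
}

#' Validate a recommendation table
#'
#' A recommendation row carries the engine output for one patient: pain
#' typicality, risk level, pre-test probability (percent), the recommended
#' investigation and medication-class set, plus the optional clinician
#' agreement fields. A guideline config may be supplied to additionally check
#' that each investigation is consistent with the band containing the
#' patient's pre-test probability (or with the expert-panel override above
#' the panel threshold).
#'
#' @param recs a recommendations tibble (as produced by [run_cdss()]).
#' @param config optional [load_guideline_config()] result for band
#'   consistency checking.
#' @return the table, invisibly, if valid.
#' @export
validate_recommendations <- function(recs, config = NULL) {
  needed <- c("patient_id", "typicality", "risk_level", "ptp",
              "investigation", "recommended_meds")
  missing_cols <- setdiff(needed, names(recs))
  if (length(missing_cols) > 0) {
    cdss_abort(paste0("recommendations missing column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "cdss_schema_error")
  }
  if (!all(recs$typicality %in% TYPICALITY_LEVELS) ||
      !all(recs$risk_level %in% RISK_LEVELS) ||
      !all(recs$investigation %in% INVESTIGATIONS) ||
      any(recs$ptp < 0 | recs$ptp > 100)) {
    cdss_abort("recommendation fields outside their controlled vocabularies",
               "cdss_validation_error")
  }
  if (any(lengths(recs$recommended_meds) > 3) ||
      !all(unlist(recs$recommended_meds) %in% MED_CLASSES)) {
    cdss_abort("recommended_meds must be a subset of the three classes",
               "cdss_validation_error")
  }
  if (!is.null(config)) {
    band_inv <- investigation_for_band(recs$ptp, config)
    panel <- recs$ptp > config$panel_threshold
    ok <- (recs$investigation == band_inv & !panel) |
      (panel & recs$investigation == "invasive_angiography")
    if (!all(ok)) {
      cdss_abort(paste0("investigation inconsistent with PTP band in row(s): ",
                        paste(which(!ok), collapse = ", ")),
                 "cdss_validation_error")
    }
  }
  invisible(recs)
}
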