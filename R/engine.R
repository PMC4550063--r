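# The decision engine: pain classification, risk stratification, pre-test
# probability lookup, and investigation / medication recommendations.
#
# All functions are vectorised and pure: identical inputs always give
# identical outputs, so whole cohorts are scored by one call.

#' Classify chest pain typicality from the three question answers
#'
#' The three-question scheme: pain is *typical* when all three features are
#' present (constricting quality; precipitated by exertion; relieved within
#' minutes by rest or glyceryl trinitrate), *atypical* when exactly two are
#' present, and *non-anginal* when one or none is.
#'
#' @param constricting,exertional,relieved logical vectors (no missing
#'   values), recycled to common length.
#' @return character vector of `"typical"`, `"atypical"`, `"non_anginal"`.
#' @export
#' @examples
#' classify_pain(TRUE, TRUE, TRUE)   # typical
#' classify_pain(TRUE, TRUE, FALSE)  # atypical
classify_pain <- function(constricting, exertional, relieved) {
  if (anyNA(constricting) || anyNA(exertional) || anyNA(relieved)) {
    cdss_abort("pain answers must not be missing", "cdss_validation_error")
  }
  n_features <- as.integer(constricting) + as.integer(exertional) +
    as.integer(relieved)
  c("non_anginal", "non_anginal", "atypical", "typical")[n_features + 1L]
}

#' Stratify cardiovascular risk from binary risk flags
#'
#' A patient is high risk if any of the configured risk flags is present;
#' otherwise low risk. By default the flags are smoking, diabetes,
#' hyperlipidaemia and an abnormal resting ECG; the set is configurable
#' (`risk_flags` in the guideline file), in particular the resting-ECG flag
#' can be excluded.
#'
#' @param smoker,diabetes,hyperlipidaemia,ecg_abnormal logical vectors.
#' @param risk_flags character vector naming the flags that count.
#' @return character vector of `"low"` / `"high"`.
#' @export
stratify_risk <- function(smoker, diabetes, hyperlipidaemia, ecg_abnormal,
                          risk_flags = c("smoker", "diabetes",
                                         "hyperlipidaemia", "ecg_abnormal")) {
  flags <- list(smoker = smoker, diabetes = diabetes,
                hyperlipidaemia = hyperlipidaemia, ecg_abnormal = ecg_abnormal)
  if (anyNA(unlist(flags[risk_flags]))) {
    cdss_abort("risk flags must not be missing", "cdss_validation_error")
  }
  any_flag <- Reduce(`|`, flags[risk_flags])
  ifelse(any_flag, "high", "low")
}

age_band_index <- function(age, config) {
  # findInterval over the cut-points; ages below the first edge fall in band
  # 1 and ages at/above the last edge in the last band (clamping).
  findInterval(age, config$age_band_edges) + 1L
}

#' Look up pre-test probability of coronary artery disease
#'
#' Returns the guideline-table percentage for the patient's sex, age band,
#' pain typicality and risk level. Ages outside the tabulated bands clamp to
#' the nearest band.
#'
#' @param age years.
#' @param sex `"male"` / `"female"`.
#' @param typicality `"typical"` / `"atypical"` / `"non_anginal"`.
#' @param risk_level `"low"` / `"high"`.
#' @param config a [load_guideline_config()] result.
#' @return numeric vector of percentages in `[0, 100]`.
#' @export
lookup_ptp <- function(age, sex, typicality, risk_level,
                       config = load_guideline_config()) {
  n <- max(length(age), length(sex), length(typicality), length(risk_level))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  typicality <- rep_len(typicality, n); risk_level <- rep_len(risk_level, n)
  if (!all(sex %in% SEX_LEVELS) || !all(typicality %in% TYPICALITY_LEVELS) ||
      !all(risk_level %in% RISK_LEVELS)) {
    cdss_abort("unknown sex/typicality/risk level in lookup_ptp",
               "cdss_validation_error")
  }
  band <- config$age_band_labels[age_band_index(age, config)]
  vapply(seq_len(n), function(i) {
    as.numeric(config$ptp_table[[sex[i]]][[band[i]]][[typicality[i]]][[risk_level[i]]])
  }, numeric(1))
}

# Band lookup shared by recommend_investigation and validation: the unique
# half-open band [lo, hi) containing ptp (top band closed at 100).
band_index_for_ptp <- function(ptp, config) {
  if (any(ptp < 0 | ptp > 100)) {
    cdss_abort("ptp must be in [0, 100]", "cdss_validation_error")
  }
  idx <- findInterval(ptp, config$investigation_bands$lo)
  idx  # ptp = 100 falls in the last band since its lo <= 100
}

investigation_for_band <- function(ptp, config) {
  config$investigation_bands$investigation[band_index_for_ptp(ptp, config)]
}

#' Recommend a diagnostic investigation from the pre-test probability
#'
#' Below the panel threshold the recommendation is the guideline band's
#' investigation (no investigation below 10%, CT calcium scoring 10-29%,
#' functional imaging 30-60%, invasive coronary angiography 61-90% in the
#' packaged config). Strictly above the panel threshold (default 90%) the
#' expert-panel rule applies: invasive angiography, overriding the guideline
#' band. A probability of exactly 90 falls in the guideline band.
#'
#' @param ptp percent in `[0, 100]`.
#' @param typicality pain typicality (carried for rule tables that condition
#'   on it; the packaged investigation bands do not).
#' @param config a [load_guideline_config()] result.
#' @return character vector of investigation recommendations.
#' @export
recommend_investigation <- function(ptp, typicality = NULL,
                                    config = load_guideline_config()) {
  inv <- investigation_for_band(ptp, config)
  inv[ptp > config$panel_threshold] <- "invasive_angiography"
  inv
}

#' Recommend secondary-prevention medication classes
#'
#' Reads the medication-rule table keyed by (typicality, PTP band); the
#' result is a subset of antiplatelet / beta-blocker / statin (at most three
#' classes). Baseline medications do not alter the recommendation; they enter
#' only the downstream change classification ([medication_delta()]).
#'
#' @inheritParams recommend_investigation
#' @param typicality pain typicality vector.
#' @return a list of character vectors (one medication-class set per input).
#' @export
recommend_medications <- function(typicality, ptp,
                                  config = load_guideline_config()) {
  n <- max(length(typicality), length(ptp))
  typicality <- rep_len(typicality, n); ptp <- rep_len(ptp, n)
  band <- config$investigation_bands$name[band_index_for_ptp(ptp, config)]
  lapply(seq_len(n), function(i) {
    sort(as.character(unlist(config$medication_rules[[typicality[i]]][[band[i]]])))
  })
}

#' Run the decision support engine over a cohort
#'
#' Composes [classify_pain()], [stratify_risk()], [lookup_ptp()],
#' [recommend_investigation()] and [recommend_medications()] for every
#' patient. Deterministic: identical cohort and config give an identical
#' recommendation table.
#'
#' @param cohort a validated cohort tibble (one or more rows).
#' @param config a [load_guideline_config()] result.
#' @param typicality_override optional character vector (recycled) of
#'   clinician-entered typicality labels that replace the computed ones;
#'   `NA` entries keep the computed label. Default: computed only.
#' @return recommendations tibble: `patient_id`, `typicality`, `risk_level`,
#'   `ptp`, `investigation`, `recommended_meds` (list-column),
#'   `clinician_agrees`, `disagreement_reason`.
#' @export
#' @examples
#' cfg <- load_guideline_config()
#' pt <- patient_presentation("p1", 55, "male", diabetes = TRUE,
#'                            pain_constricting = TRUE, pain_exertional = TRUE,
#'                            pain_relieved_by_rest_or_gtn = TRUE)
#' run_cdss(pt, cfg)
run_cdss <- function(cohort, config = load_guideline_config(),
                     typicality_override = NULL) {
  validate_cohort(cohort)
  typicality <- classify_pain(cohort$pain_constricting,
                              cohort$pain_exertional,
                              cohort$pain_relieved_by_rest_or_gtn)
  if (!is.null(typicality_override)) {
    ov <- rep_len(as.character(typicality_override), nrow(cohort))
    if (!all(ov[!is.na(ov)] %in% TYPICALITY_LEVELS)) {
      cdss_abort("typicality_override contains unknown labels",
                 "cdss_validation_error")
    }
    typicality[!is.na(ov)] <- ov[!is.na(ov)]
  }
  risk <- stratify_risk(cohort$smoker, cohort$diabetes, cohort$hyperlipidaemia,
                        cohort$ecg_abnormal, risk_flags = config$risk_flags)
  ptp <- lookup_ptp(cohort$age, cohort$sex, typicality, risk, config)
  recs <- tibble::tibble(
    patient_id = cohort$patient_id,
    typicality = typicality,
    risk_level = risk,
    ptp = ptp,
    investigation = recommend_investigation(ptp, typicality, config),
    recommended_meds = recommend_medications(typicality, ptp, config),
    clinician_agrees = rep(NA, nrow(cohort)),
    disagreement_reason = rep(NA_character_, nrow(cohort))
  )
  validate_recommendations(recs, config)
  recs
}
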