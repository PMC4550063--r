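# Synthetic cohort generation and clinic-pathway simulation.
#
# The generator reproduces the marginal structure of a chest-pain clinic
# cohort: truncated-normal ages, Bernoulli risk factors and baseline
# medication classes, and pain-question triples drawn conditionally on a
# sampled typicality category so the typicality marginals can be calibrated
# exactly. Risk-factor correlations are not modelled (only marginals are
# targeted). One global seed drives a named sub-stream per stage so the
# generation and pathway stages can be re-run independently.

#' Cohort generator configuration
#'
#' Defaults are calibrated to the baseline characteristics of a real
#' chest-pain clinic population: mean age 59.4 (SD 11.0) years, 49% male,
#' smoking 41%, diabetes 8%, hyperlipidaemia 32%, typicality split
#' typical/atypical/non-anginal = 19/16/65%, baseline medication prevalences
#' antiplatelet 22%, beta-blocker 5%, statin 25%. The prevalence of an
#' abnormal resting ECG is not reported for that population; the default of
#' 5% is a documented assumption. `p_cdss_used` defaults to 0.86, the usage
#' rate observed where the tool was available.
#'
#' @param n cohort size (non-negative integer).
#' @param age_mean,age_sd normal age distribution parameters (years); draws
#'   are truncated to `[18, 120]`.
#' @param p_male probability of male sex.
#' @param p_smoker,p_diabetes,p_hyperlipidaemia,p_ecg_abnormal risk-factor
#'   prevalences.
#' @param typicality_probs named 3-vector of probabilities for
#'   typical/atypical/non_anginal, summing to 1.
#' @param baseline_med_probs named per-class prevalences for
#'   antiplatelet/beta_blocker/statin.
#' @param p_cdss_used probability the decision tool was used at the visit.
#' @param group,site labels stamped on every generated patient.
#' @param seed integer RNG seed.
#' @return a validated `cohort_gen_config` list.
#' @export
cohort_gen_config <- function(n,
                              age_mean = 59.4, age_sd = 11.0,
                              p_male = 0.49,
                              p_smoker = 0.41, p_diabetes = 0.08,
                              p_hyperlipidaemia = 0.32,
                              p_ecg_abnormal = 0.05,
                              typicality_probs = c(typical = 0.19,
                                                   atypical = 0.16,
                                                   non_anginal = 0.65),
                              baseline_med_probs = c(antiplatelet = 0.22,
                                                     beta_blocker = 0.05,
                                                     statin = 0.25),
                              p_cdss_used = 0.86,
                              group = "before", site = "site_a",
                              seed = 1L) {
  probs <- c(p_male, p_smoker, p_diabetes, p_hyperlipidaemia, p_ecg_abnormal,
             p_cdss_used, typicality_probs, baseline_med_probs)
  if (any(probs < 0 | probs > 1)) {
    cdss_abort("all probabilities must lie in [0, 1]", "cdss_config_error")
  }
  if (abs(sum(typicality_probs) - 1) > 1e-8) {
    cdss_abort("typicality_probs must sum to 1", "cdss_config_error")
  }
  if (!setequal(names(typicality_probs), TYPICALITY_LEVELS)) {
    cdss_abort("typicality_probs must be named typical/atypical/non_anginal",
               "cdss_config_error")
  }
  if (!setequal(names(baseline_med_probs), MED_CLASSES)) {
    cdss_abort("baseline_med_probs must be named antiplatelet/beta_blocker/statin",
               "cdss_config_error")
  }
  if (n < 0 || n != round(n)) {
    cdss_abort("n must be a non-negative integer", "cdss_config_error")
  }
  if (age_sd <= 0) {
    cdss_abort("age_sd must be positive", "cdss_config_error")
  }
  structure(
    list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
         p_male = p_male, p_smoker = p_smoker, p_diabetes = p_diabetes,
         p_hyperlipidaemia = p_hyperlipidaemia,
         p_ecg_abnormal = p_ecg_abnormal,
         typicality_probs = typicality_probs[TYPICALITY_LEVELS],
         baseline_med_probs = baseline_med_probs[MED_CLASSES],
         p_cdss_used = p_cdss_used, group = group, site = site,
         seed = as.integer(seed)),
    class = "cohort_gen_config"
  )
}

# Boolean pain-answer triples compatible with each typicality category:
# typical = all three features, atypical = exactly two, non-anginal = at most
# one. Sampling a category first, then a uniform triple within it, calibrates
# the typicality marginals exactly.
pain_triples_for <- function(typicality) {
  switch(typicality,
    typical = matrix(c(TRUE, TRUE, TRUE), nrow = 1),
    atypical = matrix(c(TRUE, TRUE, FALSE,
                        TRUE, FALSE, TRUE,
                        FALSE, TRUE, TRUE), nrow = 3, byrow = TRUE),
    non_anginal = matrix(c(FALSE, FALSE, FALSE,
                           TRUE, FALSE, FALSE,
                           FALSE, TRUE, FALSE,
                           FALSE, FALSE, TRUE), nrow = 4, byrow = TRUE)
  )
}

# Truncated-normal sampling by inverse-CDF (exact, no rejection loop).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` independent patients: truncated-normal ages (rounded to
#' whole years within `[18, 120]`), Bernoulli sex, risk factors and baseline
#' medication classes, and pain-answer triples drawn conditionally on a
#' typicality category sampled from `typicality_probs` (a uniformly random
#' boolean triple consistent with the category). Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_gen_config()].
#' @return a validated cohort tibble with `followed_up = FALSE` throughout
#'   (outcomes come from [simulate_pathway()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_gen_config(n = 5, seed = 42))
#' cohort$age
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_gen_config")) {
    config <- do.call(cohort_gen_config, config)
  }
  n <- config$n
  if (n == 0) return(empty_cohort())
  set.seed(substream_seed(config$seed, "cohort"))

  age <- as.integer(round(rtruncnorm(n, config$age_mean, config$age_sd,
                                     AGE_VALID_RANGE[1] - 0.5,
                                     AGE_VALID_RANGE[2] + 0.49)))
  age <- pmin(pmax(age, AGE_VALID_RANGE[1]), AGE_VALID_RANGE[2])
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  typ <- sample(TYPICALITY_LEVELS, n, replace = TRUE,
                prob = config$typicality_probs)
  pain <- t(vapply(typ, function(ty) {
    m <- pain_triples_for(ty)
    m[sample.int(nrow(m), 1L), ]
  }, logical(3)))
  dimnames(pain) <- NULL
  meds <- lapply(seq_len(n), function(i) {
    MED_CLASSES[stats::runif(3) < config$baseline_med_probs]
  })
  cohort <- tibble::tibble(
    patient_id = sprintf("%s_%06d", config$group, seq_len(n)),
    age = age,
    sex = sex,
    smoker = stats::runif(n) < config$p_smoker,
    diabetes = stats::runif(n) < config$p_diabetes,
    hyperlipidaemia = stats::runif(n) < config$p_hyperlipidaemia,
    ecg_abnormal = stats::runif(n) < config$p_ecg_abnormal,
    pain_constricting = pain[, 1],
    pain_exertional = pain[, 2],
    pain_relieved_by_rest_or_gtn = pain[, 3],
    baseline_meds = meds,
    group = config$group,
    site = config$site,
    cdss_used = stats::runif(n) < config$p_cdss_used,
    followed_up = FALSE,
    investigations_6m = rep(list(character(0)), n),
    meds_6m = rep(list(character(0)), n)
  )
  validate_cohort(cohort)
  cohort
}

#' Adherence model for the clinic-pathway simulation
#'
#' Parameterises the behaviours the concordance audit measures. Defaults are
#' the observed post-intervention rates: an investigation was done for 59%
#' of patients recommended one and 14% of patients recommended none; a
#' recommended medication class was adopted half the time; the tool was used
#' in 86% of consultations.
#'
#' @param p_follow_investigation_recommended probability a recommended
#'   investigation is done.
#' @param p_investigate_when_not_recommended probability an investigation is
#'   done despite a "none" recommendation.
#' @param p_follow_medication per-class probability a recommended medication
#'   class is adopted by follow-up.
#' @param p_cdss_used probability the tool was used (carried for
#'   completeness; outcomes do not depend on it).
#' @return an `adherence_model` list.
#' @export
adherence_model <- function(p_follow_investigation_recommended = 0.59,
                            p_investigate_when_not_recommended = 0.14,
                            p_follow_medication = 0.50,
                            p_cdss_used = 0.86) {
  probs <- c(p_follow_investigation_recommended,
             p_investigate_when_not_recommended,
             p_follow_medication, p_cdss_used)
  if (any(probs < 0 | probs > 1)) {
    cdss_abort("adherence probabilities must lie in [0, 1]", "cdss_config_error")
  }
  structure(
    list(p_follow_investigation_recommended = p_follow_investigation_recommended,
         p_investigate_when_not_recommended = p_investigate_when_not_recommended,
         p_follow_medication = p_follow_medication,
         p_cdss_used = p_cdss_used),
    class = "adherence_model"
  )
}

#' Simulate six-month outcomes for a cohort under an adherence model
#'
#' For each patient: if an investigation was recommended it is done with
#' probability `p_follow_investigation_recommended` (the recommended
#' modality); if none was recommended an investigation (recorded as
#' `"other"`) is done with probability
#' `p_investigate_when_not_recommended`. Follow-up medications are the
#' baseline classes (assumed continued) plus each recommended class adopted
#' independently with probability `p_follow_medication`. Reproducible from
#' `seed`.
#'
#' @param cohort a validated cohort tibble.
#' @param recommendations recommendations for the same patients, same order.
#' @param model an [adherence_model()].
#' @param seed integer RNG seed (a named sub-stream of the global seed).
#' @return outcomes tibble: `patient_id`, `investigations_done`,
#'   `followup_meds` (list-columns).
#' @export
simulate_pathway <- function(cohort, recommendations,
                             model = adherence_model(), seed = 1L) {
  if (nrow(cohort) != nrow(recommendations) ||
      !identical(cohort$patient_id, recommendations$patient_id)) {
    cdss_abort("cohort and recommendations must match row-for-row by patient_id",
               "cdss_linkage_error")
  }
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::tibble(patient_id = character(0),
                          investigations_done = list(),
                          followup_meds = list()))
  }
  set.seed(substream_seed(seed, "pathway"))
  recommended <- recommendations$investigation != "none"
  p_do <- ifelse(recommended, model$p_follow_investigation_recommended,
                 model$p_investigate_when_not_recommended)
  done <- stats::runif(n) < p_do
  investigations <- lapply(seq_len(n), function(i) {
    if (!done[i]) character(0)
    else if (recommended[i]) recommendations$investigation[i]
    else "other"
  })
  meds <- lapply(seq_len(n), function(i) {
    rec <- recommendations$recommended_meds[[i]]
    adopted <- rec[stats::runif(length(rec)) < model$p_follow_medication]
    sort(unique(c(cohort$baseline_meds[[i]], adopted)))
  })
  tibble::tibble(patient_id = cohort$patient_id,
                 investigations_done = investigations,
                 followup_meds = meds)
}

#' Attach simulated outcomes to a cohort
#'
#' Convenience: merges [simulate_pathway()] output back into the cohort's
#' six-month columns, marking every patient followed up.
#'
#' @param cohort a validated cohort tibble.
#' @param outcomes result of [simulate_pathway()] for the same patients.
#' @return the cohort with `followed_up = TRUE` and outcome columns filled.
#' @export
attach_outcomes <- function(cohort, outcomes) {
  idx <- match(cohort$patient_id, outcomes$patient_id)
  if (anyNA(idx)) {
    cdss_abort("outcomes missing for some patients", "cdss_linkage_error")
  }
  cohort$followed_up <- TRUE
  cohort$investigations_6m <- outcomes$investigations_done[idx]
  cohort$meds_6m <- outcomes$followup_meds[idx]
  validate_cohort(cohort)
  cohort
}
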