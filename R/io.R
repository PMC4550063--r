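# Cohort and recommendation file input/output.
#
# Cohort files are UTF-8 CSV with a header row and the fixed column set
# documented in read_cohort(). Categorical values are lower-case tokens,
# booleans are 0/1, multi-valued fields are semicolon-separated with ""
# meaning the empty set. The schema has no dedicated lost-to-follow-up
# column, so the convention is: a literal `NA` in BOTH investigations_6m and
# meds_6m marks a patient with no six-month follow-up; an empty string is a
# real observation of "none".

COHORT_FILE_COLUMNS <- c("patient_id", "age", "sex", "smoker", "diabetes",
                         "hyperlipidaemia", "ecg_abnormal", "pain_constricting",
                         "pain_exertional", "pain_relieved_by_rest_or_gtn",
                         "baseline_meds", "group", "site", "cdss_used",
                         "investigations_6m", "meds_6m")

BOOL_COLUMNS <- c("smoker", "diabetes", "hyperlipidaemia", "ecg_abnormal",
                  "pain_constricting", "pain_exertional",
                  "pain_relieved_by_rest_or_gtn", "cdss_used")

#' Read a cohort file
#'
#' Reads and validates a delimited cohort file. Columns:
#' `patient_id, age, sex, smoker, diabetes, hyperlipidaemia, ecg_abnormal,
#' pain_constricting, pain_exertional, pain_relieved_by_rest_or_gtn,
#' baseline_meds, group, site, cdss_used, investigations_6m, meds_6m`.
#' Booleans are encoded 0/1; `baseline_meds`, `investigations_6m` and
#' `meds_6m` are semicolon-separated sets with the empty string meaning
#' "none"; a literal `NA` in both six-month columns marks a patient lost to
#' follow-up (`followed_up = FALSE`), who is excluded from concordance
#' denominators downstream.
#'
#' @param path CSV file path.
#' @return a validated cohort tibble (row order preserved) with list-columns
#'   for the multi-valued fields and a logical `followed_up` column.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    cdss_abort(paste0("cohort file not found: ", path), "cdss_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  missing_cols <- setdiff(COHORT_FILE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    cdss_abort(paste0("cohort file missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "cdss_schema_error")
  }
  if (nrow(df) == 0) {
    return(empty_cohort())
  }
  parse_bool <- function(x, col) {
    if (!all(x %in% c("0", "1"))) {
      cdss_abort(paste0("column ", col, ": booleans must be 0/1; bad row(s): ",
                        paste(which(!x %in% c("0", "1")), collapse = ", ")),
                 "cdss_validation_error")
    }
    x == "1"
  }
  age <- suppressWarnings(as.integer(df$age))
  if (anyNA(age)) {
    cdss_abort(paste0("column age: non-integer value(s) in row(s): ",
                      paste(which(is.na(age)), collapse = ", ")),
               "cdss_validation_error")
  }
  lost <- df$investigations_6m == "NA" & df$meds_6m == "NA"
  inv6 <- split_multi(df$investigations_6m)
  med6 <- split_multi(df$meds_6m)
  inv6[lost] <- list(character(0))
  med6[lost] <- list(character(0))
  cohort <- tibble::tibble(
    patient_id = df$patient_id,
    age = age,
    sex = df$sex,
    smoker = parse_bool(df$smoker, "smoker"),
    diabetes = parse_bool(df$diabetes, "diabetes"),
    hyperlipidaemia = parse_bool(df$hyperlipidaemia, "hyperlipidaemia"),
    ecg_abnormal = parse_bool(df$ecg_abnormal, "ecg_abnormal"),
    pain_constricting = parse_bool(df$pain_constricting, "pain_constricting"),
    pain_exertional = parse_bool(df$pain_exertional, "pain_exertional"),
    pain_relieved_by_rest_or_gtn =
      parse_bool(df$pain_relieved_by_rest_or_gtn, "pain_relieved_by_rest_or_gtn"),
    baseline_meds = split_multi(df$baseline_meds),
    group = df$group,
    site = df$site,
    cdss_used = parse_bool(df$cdss_used, "cdss_used"),
    followed_up = !lost,
    investigations_6m = inv6,
    meds_6m = med6
  )
  validate_cohort(cohort)
  cohort
}

#' Write a cohort file
#'
#' Inverse of [read_cohort()]: a written file read back yields an identical
#' cohort (multi-valued sets compare up to ordering; they are written
#' sorted).
#'
#' @param cohort a validated cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- data.frame(
    patient_id = cohort$patient_id,
    age = cohort$age,
    sex = cohort$sex,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (col in BOOL_COLUMNS) df[[col]] <- as.integer(cohort[[col]])
  df$baseline_meds <- join_multi(cohort$baseline_meds)
  df$group <- cohort$group
  df$site <- cohort$site
  df$investigations_6m <- ifelse(cohort$followed_up,
                                 join_multi(cohort$investigations_6m), "NA")
  df$meds_6m <- ifelse(cohort$followed_up, join_multi(cohort$meds_6m), "NA")
  utils::write.csv(df[, COHORT_FILE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(0), age = integer(0), sex = character(0),
    smoker = logical(0), diabetes = logical(0), hyperlipidaemia = logical(0),
    ecg_abnormal = logical(0), pain_constricting = logical(0),
    pain_exertional = logical(0), pain_relieved_by_rest_or_gtn = logical(0),
    baseline_meds = list(), group = character(0), site = character(0),
    cdss_used = logical(0), followed_up = logical(0),
    investigations_6m = list(), meds_6m = list()
  )
}

#' Write a recommendations file
#'
#' One row per patient: `patient_id, typicality, risk_level, ptp,
#' investigation, recommended_meds, clinician_agrees, disagreement_reason`.
#' `recommended_meds` is semicolon-separated; `clinician_agrees` is 0/1 or
#' empty when unrecorded.
#'
#' @param recs recommendations tibble from [run_cdss()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(recs, path) {
  validate_recommendations(recs)
  df <- data.frame(
    patient_id = recs$patient_id,
    typicality = recs$typicality,
    risk_level = recs$risk_level,
    ptp = recs$ptp,
    investigation = recs$investigation,
    recommended_meds = join_multi(recs$recommended_meds),
    clinician_agrees = ifelse(is.na(recs$clinician_agrees %||%
                                      rep(NA, nrow(recs))), "",
                              as.integer(recs$clinician_agrees)),
    disagreement_reason = ifelse(is.na(recs$disagreement_reason %||%
                                         rep(NA_character_, nrow(recs))), "",
                                 recs$disagreement_reason),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recommendations file
#'
#' @param path CSV written by [write_recommendations()].
#' @return a validated recommendations tibble.
#' @export
read_recommendations <- function(path) {
  if (!file.exists(path)) {
    cdss_abort(paste0("recommendations file not found: ", path), "cdss_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = character(0))
  recs <- tibble::tibble(
    patient_id = df$patient_id,
    typicality = df$typicality,
    risk_level = df$risk_level,
    ptp = as.numeric(df$ptp),
    investigation = df$investigation,
    recommended_meds = split_multi(df$recommended_meds),
    clinician_agrees = ifelse(df$clinician_agrees == "", NA,
                              df$clinician_agrees == "1"),
    disagreement_reason = ifelse(df$disagreement_reason == "", NA_character_,
                                 df$disagreement_reason)
  )
  validate_recommendations(recs)
  recs
}

#' Extract six-month outcomes from a cohort
#'
#' Returns one row per followed-up patient with the investigations performed
#' and the medication classes current at six months; patients lost to
#' follow-up are omitted (they do not enter concordance denominators).
#'
#' @param cohort a validated cohort tibble.
#' @return tibble with columns `patient_id`, `investigations_done`
#'   (list-column), `followup_meds` (list-column).
#' @export
cohort_outcomes <- function(cohort) {
  validate_cohort(cohort)
  kept <- cohort[cohort$followed_up, ]
  tibble::tibble(
    patient_id = kept$patient_id,
    investigations_done = kept$investigations_6m,
    followup_meds = kept$meds_6m
  )
}
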