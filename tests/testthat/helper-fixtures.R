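# Shared fixture builders: cohorts, recommendation/outcome tables with
# prescribed concordance counts, and the independent per-patient oracle.

default_config <- function() load_guideline_config()

# Recommendations + outcomes constructed to exact concordance counts:
# n_rec patients recommended an investigation (n_rec_done of them had one),
# n_none recommended none (n_none_done had one anyway).
concordance_fixture <- function(n_rec, n_rec_done, n_none, n_none_done) {
  n <- n_rec + n_none
  ids <- sprintf("p%04d", seq_len(n))
  recommended <- c(rep(TRUE, n_rec), rep(FALSE, n_none))
  done <- c(rep(TRUE, n_rec_done), rep(FALSE, n_rec - n_rec_done),
            rep(TRUE, n_none_done), rep(FALSE, n_none - n_none_done))
  recs <- tibble::tibble(
    patient_id = ids,
    typicality = ifelse(recommended, "atypical", "non_anginal"),
    risk_level = "low",
    ptp = ifelse(recommended, 45, 5),
    investigation = ifelse(recommended, "functional_imaging", "none"),
    recommended_meds = lapply(recommended, function(r) {
      if (r) c("antiplatelet", "statin") else character(0)
    }),
    clinician_agrees = NA,
    disagreement_reason = NA_character_
  )
  outcomes <- tibble::tibble(
    patient_id = ids,
    investigations_done = lapply(done, function(d) {
      if (d) "functional_imaging" else character(0)
    }),
    followup_meds = rep(list(character(0)), n)
  )
  list(recs = recs, outcomes = outcomes)
}

# Independent oracle: classify each patient one at a time with an explicit
# loop, no shared code with investigation_concordance().
oracle_concordance_counts <- function(recs, outcomes) {
  n_rec <- 0; n_rec_done <- 0; n_none <- 0; n_none_done <- 0; n_followed <- 0
  for (i in seq_len(nrow(outcomes))) {
    j <- which(recs$patient_id == outcomes$patient_id[i])
    rec <- recs$investigation[j] != "none"
    done <- length(outcomes$investigations_done[[i]]) > 0
    if (rec) {
      n_rec <- n_rec + 1
      if (done) n_rec_done <- n_rec_done + 1
      if (done) n_followed <- n_followed + 1
    } else {
      n_none <- n_none + 1
      if (done) n_none_done <- n_none_done + 1
      if (!done) n_followed <- n_followed + 1
    }
  }
  list(n_rec = n_rec, n_rec_done = n_rec_done, n_none = n_none,
       n_none_done = n_none_done, n_followed = n_followed)
}

# A random cohort with simulated outcomes attached, for property tests.
random_scored_cohort <- function(n, seed, model = adherence_model()) {
  cohort <- generate_cohort(cohort_gen_config(n = n, seed = seed))
  recs <- run_cdss(cohort, default_config())
  outcomes <- simulate_pathway(cohort, recs, model, seed = seed + 1)
  list(cohort = attach_outcomes(cohort, outcomes), recs = recs,
       outcomes = outcomes)
}

# Normalise list-column sets for order-insensitive comparison.
sorted_sets <- function(lst) lapply(lst, sort)
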