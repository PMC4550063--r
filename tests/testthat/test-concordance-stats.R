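# Evaluation statistics: Wald intervals, two-proportion difference,
# concordance counting, medication deltas, sample size.

test_that("Wald intervals reproduce published audit values after round-half-up", {
  cases <- list(
    # k, n, expected (estimate, lower, upper) in integer percent
    list(18, 36, c(50, 34, 66)),
    list(154, 179, c(86, 81, 91)),
    list(36, 106, c(34, 25, 43)),
    list(78, 106, c(74, 65, 82)),
    list(8, 25, c(32, 14, 50)),
    list(17, 34, c(50, 33, 67)),
    list(15, 25, c(60, 41, 79))
  )
  for (cs in cases) {
    got <- round_half_up(wald_ci(cs[[1]], cs[[2]]))
    expect_equal(unname(got), cs[[3]],
                 info = sprintf("%d/%d", cs[[1]], cs[[2]]))
  }
})

test_that("Wald interval edge behaviour: clamping, zero successes, errors", {
  ci <- wald_ci(0, 10)
  expect_equal(ci[["lower"]], 0)  # clamped at 0
  expect_equal(ci[["estimate"]], 0)
  # unclamped variant can go negative (as some published tables print)
  expect_lt(wald_ci(2, 25, clamp = FALSE)[["lower"]], 0)
  expect_equal(unname(round_half_up(wald_ci(2, 25, clamp = FALSE))),
               c(8, -3, 19))
  expect_error(wald_ci(3, 0), class = "cdss_undefined_proportion_error")
  expect_error(wald_ci(5, 4), class = "cdss_validation_error")
})

test_that("intervals stay in range and widen with the confidence level", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    ci90 <- wald_ci(k, n, 0.90)
    ci95 <- wald_ci(k, n, 0.95)
    ci99 <- wald_ci(k, n, 0.99)
    expect_true(ci95[["lower"]] >= 0 && ci95[["upper"]] <= 100)
    expect_lte(ci95[["lower"]], ci90[["lower"]])
    expect_gte(ci95[["upper"]], ci90[["upper"]])
    expect_lte(ci99[["lower"]], ci95[["lower"]])
    expect_gte(ci99[["upper"]], ci95[["upper"]])
    expect_true(ci95[["lower"]] <= ci95[["estimate"]] &&
                  ci95[["estimate"]] <= ci95[["upper"]])
  }
})

test_that("two-proportion difference CI: published value, symmetry, antisymmetry", {
  got <- round_half_up(two_proportion_diff_ci(73, 79, 81, 100))
  expect_equal(unname(got), c(11, 2, 21))
  same <- two_proportion_diff_ci(30, 60, 30, 60)
  expect_equal(same[["diff"]], 0)
  expect_equal(same[["lower"]], -same[["upper"]])
  ab <- two_proportion_diff_ci(25, 40, 10, 50)
  ba <- two_proportion_diff_ci(10, 50, 25, 40)
  expect_equal(ab[["diff"]], -ba[["diff"]])
  expect_equal(ab[["lower"]], -ba[["upper"]])
  expect_equal(ab[["upper"]], -ba[["lower"]])
  expect_error(two_proportion_diff_ci(1, 0, 1, 2),
               class = "cdss_undefined_proportion_error")
})

test_that("concordance counting matches its definition on constructed fixtures", {
  fx <- concordance_fixture(36, 18, 70, 10)
  s <- investigation_concordance(fx$recs, fx$outcomes, group = "before")
  expect_equal(s$n_total, 106)
  expect_equal(s$n_followed, 78)  # 18 done + (70 - 10) spared
  expect_equal(s$n_total, s$n_recommended_investigation + s$n_recommended_none)
  expect_equal(s$n_followed,
               s$n_recommended_done + (s$n_recommended_none - s$n_none_but_done))
  # perfect adherence -> 100% followed
  fx2 <- concordance_fixture(20, 20, 30, 0)
  s2 <- investigation_concordance(fx2$recs, fx2$outcomes)
  expect_equal(s2$proportions$estimate[s2$proportions$quantity == "followed"], 100)
  # unmatched outcome id -> linkage error
  bad <- fx$outcomes
  bad$patient_id[1] <- "ghost"
  expect_error(investigation_concordance(fx$recs, bad),
               class = "cdss_linkage_error")
})

test_that("concordance counts equal the per-patient oracle on random cohorts", {
  for (seed in c(21, 22, 23)) {
    n <- c(50, 400, 1000)[seed - 20]
    sim <- random_scored_cohort(n, seed = seed)
    s <- investigation_concordance(sim$recs, sim$outcomes)
    o <- oracle_concordance_counts(sim$recs, sim$outcomes)
    expect_equal(s$n_recommended_investigation, o$n_rec)
    expect_equal(s$n_recommended_done, o$n_rec_done)
    expect_equal(s$n_recommended_none, o$n_none)
    expect_equal(s$n_none_but_done, o$n_none_done)
    expect_equal(s$n_followed, o$n_followed)
  }
})

test_that("patients without follow-up are excluded from concordance denominators", {
  sim <- random_scored_cohort(100, seed = 31)
  cohort <- sim$cohort
  cohort$followed_up[1:20] <- FALSE
  cohort$investigations_6m[1:20] <- list(character(0))
  cohort$meds_6m[1:20] <- list(character(0))
  s <- investigation_concordance(sim$recs, cohort_outcomes(cohort))
  expect_equal(s$n_total, 80)
})

test_that("medication delta classifies count changes (and set changes behind the flag)", {
  expect_equal(medication_delta(list("statin"), list(c("statin", "antiplatelet"))),
               "increase")
  expect_equal(medication_delta(list("statin"), list("antiplatelet")),
               "unchanged")  # equal cardinality, count-based rule
  expect_equal(medication_delta(list(c("statin", "antiplatelet")), list("statin")),
               "decrease")
  expect_equal(medication_delta(list("statin"), list("antiplatelet"),
                                method = "set"),
               "unchanged")  # one added, one removed
  expect_equal(medication_delta(list(character(0)), list("statin"),
                                method = "set"), "increase")
})

test_that("medication delta summary partitions the recommended-increase group", {
  set.seed(55)
  for (rep in 1:5) {
    sim <- random_scored_cohort(120, seed = 60 + rep)
    s <- medication_delta_summary(sim$cohort, sim$recs)
    expect_equal(s$n_increased + s$n_decreased + s$n_unchanged,
                 s$n_recommended_increase)
    expect_true(all(c(s$n_increased, s$n_decreased, s$n_unchanged) >= 0))
  }
})

test_that("medication delta summary reproduces a constructed 8/2/15 split", {
  # 25 followed-up patients recommended an increase: 8 gained a class,
  # 2 lost one, 15 unchanged
  n <- 25
  baseline <- rep(list("statin"), n)
  followup <- c(rep(list(c("statin", "antiplatelet")), 8),
                rep(list(character(0)), 2),
                rep(list("statin"), 15))
  cohort <- do.call(rbind, lapply(seq_len(n), function(i) {
    with_followup(
      patient_presentation(sprintf("m%02d", i), 55, "male",
                           pain_constricting = TRUE, pain_exertional = TRUE,
                           pain_relieved_by_rest_or_gtn = FALSE,
                           baseline_med_classes = baseline[[i]]),
      followup_med_classes = followup[[i]]
    )
  }))
  recs <- run_cdss(cohort, default_config())
  # the engine recommends >= 2 classes here, i.e. an increase for everyone
  expect_true(all(lengths(recs$recommended_meds) > lengths(cohort$baseline_meds)))
  s <- medication_delta_summary(cohort, recs)
  expect_equal(s$n_recommended_increase, 25)
  expect_equal(c(s$n_increased, s$n_decreased, s$n_unchanged), c(8, 2, 15))
  pr <- s$proportions
  expect_equal(round_half_up(pr$estimate[pr$quantity == "increased"]), 32)
  expect_equal(round_half_up(pr$estimate[pr$quantity == "decreased"]), 8)
  expect_equal(round_half_up(pr$estimate[pr$quantity == "unchanged"]), 60)
  # published intervals for the 8/25 and 15/25 splits
  expect_equal(unname(round_half_up(
    c(pr$lower[pr$quantity == "increased"], pr$upper[pr$quantity == "increased"]))),
    c(14, 50))
  expect_equal(unname(round_half_up(
    c(pr$lower[pr$quantity == "unchanged"], pr$upper[pr$quantity == "unchanged"]))),
    c(41, 79))
})

test_that("sample-size calculator reproduces the planned 354 per group and is monotone", {
  res <- sample_size_two_proportions(0.75, 0.85, 0.05, 0.90,
                                     continuity_correction = TRUE)
  expect_equal(res$n_per_group, 354L)
  expect_equal(res$n_total, 708L)
  raw <- sample_size_two_proportions(0.75, 0.85, 0.05, 0.90,
                                     continuity_correction = FALSE)
  # independent implementation of the uncorrected two-proportion formula
  expect_equal(raw$n_per_group,
               as.integer(ceiling(power.prop.test(p1 = 0.75, p2 = 0.85,
                                                  sig.level = 0.05,
                                                  power = 0.90)$n)))
  expect_lt(raw$n_per_group, res$n_per_group)  # correction inflates n
  # monotone in power
  n_lo <- sample_size_two_proportions(0.75, 0.85, 0.05, 0.80)$n_per_group
  expect_gte(res$n_per_group, n_lo)
  expect_error(sample_size_two_proportions(0.5, 0.5),
               class = "cdss_validation_error")
  expect_error(sample_size_two_proportions(0, 0.5),
               class = "cdss_validation_error")
})

test_that("the uncorrected sample size achieves the requested power by simulation", {
  raw <- sample_size_two_proportions(0.75, 0.85, 0.05, 0.90,
                                     continuity_correction = FALSE)
  pw <- simulate_two_proportion_power(raw$n_per_group, 0.75, 0.85,
                                      alpha = 0.05, nsim = 20000, seed = 7)
  mc_se <- sqrt(0.90 * 0.10 / 20000)
  expect_gte(pw, 0.90 - 3 * mc_se)
})
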