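# Descriptive evaluation statistics: Wald binomial confidence intervals,
# two-proportion difference intervals, investigation-concordance counts,
# medication-class delta classification, and the continuity-corrected
# two-proportion sample-size formula.
#
# Only descriptive statistics are provided (no hypothesis tests or models),
# matching the audit design these summaries support.

#' Wald binomial confidence interval
#'
#' Normal-approximation interval for a binomial proportion on the percent
#' scale: `p +/- z * sqrt(p (1 - p) / n)` with `p = k / n`. Bounds are
#' clamped to `[0, 100]` unless `clamp = FALSE`. The interval is returned
#' unrounded; rounding to integer percent for presentation is a separate
#' step (round half up, see [round_half_up()]).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `> 0`.
#' @param level confidence level (default 0.95).
#' @param clamp clamp the bounds to `[0, 100]`? Default `TRUE`.
#' @return named numeric vector `c(estimate, lower, upper)` in percent.
#' @export
#' @examples
#' round_half_up(wald_ci(18, 36))  # 50 (34, 66)
wald_ci <- function(k, n, level = 0.95, clamp = TRUE) {
  if (length(n) != 1 || n <= 0) {
    cdss_abort("wald_ci: n must be a single positive count (proportion undefined for n = 0)",
               "cdss_undefined_proportion_error")
  }
  if (k < 0 || k > n) {
    cdss_abort("wald_ci: k must satisfy 0 <= k <= n", "cdss_validation_error")
  }
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  lo <- 100 * (p - half)
  hi <- 100 * (p + half)
  if (clamp) {
    lo <- max(0, lo)
    hi <- min(100, hi)
  }
  c(estimate = 100 * p, lower = lo, upper = hi)
}

#' Wald confidence interval for a difference of two proportions
#'
#' `diff = p1 - p2` in percent with interval
#' `diff +/- z * sqrt(p1 q1 / n1 + p2 q2 / n2)` (unpooled).
#'
#' @param k1,n1 successes and trials in the first group.
#' @param k2,n2 successes and trials in the second group.
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(diff, lower, upper)` in percent,
#'   unrounded.
#' @export
#' @examples
#' round_half_up(two_proportion_diff_ci(73, 79, 81, 100))  # 11 (2, 21)
two_proportion_diff_ci <- function(k1, n1, k2, n2, level = 0.95) {
  if (n1 <= 0 || n2 <= 0) {
    cdss_abort("two_proportion_diff_ci: denominators must be positive",
               "cdss_undefined_proportion_error")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- p1 - p2
  c(diff = 100 * d, lower = 100 * (d - z * se), upper = 100 * (d + z * se))
}

#' Investigation concordance with the decision support recommendations
#'
#' A patient's management is *followed* when either an investigation was
#' recommended and at least one qualifying investigation was done within the
#' follow-up window, or no investigation was recommended and none was done.
#' The question is recommended-versus-any-done, not modality matching.
#' Patients without a follow-up outcome are excluded from all denominators.
#'
#' @param recommendations recommendations tibble (from [run_cdss()] or
#'   [read_recommendations()]).
#' @param outcomes outcomes tibble (from [cohort_outcomes()] or
#'   [simulate_pathway()]); every `patient_id` must appear in
#'   `recommendations`, otherwise a linkage error is raised.
#' @param group label carried into the summary (e.g. `"before"`).
#' @param level confidence level for the Wald intervals.
#' @return a `concordance_summary` object: counts
#'   (`n_total`, `n_recommended_investigation`, `n_recommended_done`,
#'   `n_recommended_none`, `n_none_but_done`, `n_followed`) and a
#'   `proportions` tibble with unrounded percent estimates and Wald bounds.
#' @export
investigation_concordance <- function(recommendations, outcomes,
                                      group = NA_character_, level = 0.95) {
  unmatched <- setdiff(outcomes$patient_id, recommendations$patient_id)
  if (length(unmatched) > 0) {
    cdss_abort(paste0("outcomes refer to unknown patient_id(s): ",
                      paste(utils::head(unmatched, 5), collapse = ", ")),
               "cdss_linkage_error")
  }
  idx <- match(outcomes$patient_id, recommendations$patient_id)
  recommended <- recommendations$investigation[idx] != "none"
  done <- lengths(outcomes$investigations_done) > 0

  n_total <- length(idx)
  n_rec <- sum(recommended)
  n_rec_done <- sum(recommended & done)
  n_none <- sum(!recommended)
  n_none_done <- sum(!recommended & done)
  n_followed <- n_rec_done + (n_none - n_none_done)

  if (n_total == 0) {
    cdss_abort("no linked patients: concordance proportions are undefined",
               "cdss_undefined_proportion_error")
  }
  prop_row <- function(what, k, n) {
    if (n == 0) {
      return(tibble::tibble(quantity = what, k = k, n = n,
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    }
    ci <- wald_ci(k, n, level)
    tibble::tibble(quantity = what, k = k, n = n, estimate = ci[["estimate"]],
                   lower = ci[["lower"]], upper = ci[["upper"]])
  }
  props <- rbind(
    prop_row("followed", n_followed, n_total),
    prop_row("recommended_investigation", n_rec, n_total),
    prop_row("done_when_recommended", n_rec_done, n_rec),
    prop_row("done_when_not_recommended", n_none_done, n_none)
  )
  structure(
    list(group = group, n_total = n_total,
         n_recommended_investigation = n_rec, n_recommended_done = n_rec_done,
         n_recommended_none = n_none, n_none_but_done = n_none_done,
         n_followed = n_followed, level = level, proportions = props),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>", if (!is.na(x$group)) paste0("group: ", x$group),
      "\n")
  cat(sprintf("  recommendation followed in %d of %d cases (%g%%, %g CI %g-%g%%)\n",
              x$n_followed, x$n_total,
              round_half_up(100 * x$n_followed / x$n_total),
              100 * x$level,
              round_half_up(x$proportions$lower[1]),
              round_half_up(x$proportions$upper[1])))
  pr <- x$proportions
  for (i in seq_len(nrow(pr))[-1]) {
    if (is.na(pr$estimate[i])) next
    cat(sprintf("  %-26s %3d/%3d  %g%% (%g-%g)\n", pr$quantity[i], pr$k[i],
                pr$n[i], round_half_up(pr$estimate[i]),
                round_half_up(pr$lower[i]), round_half_up(pr$upper[i])))
  }
  invisible(x)
}

#' Classify the change in medication-class count
#'
#' Compares the number of medication classes at follow-up with the number at
#' baseline (the default, count-based rule): more classes is an `increase`,
#' fewer a `decrease`, the same number `unchanged` — even if the composition
#' changed. `method = "set"` instead classifies by set difference: classes
#' added with none removed is an increase, removed with none added a
#' decrease, anything else unchanged.
#'
#' @param baseline_meds,followup_meds lists of medication-class sets (or a
#'   single character vector each).
#' @param method `"count"` (default) or `"set"`.
#' @return character vector of `"increase"` / `"decrease"` / `"unchanged"`.
#' @export
#' @examples
#' medication_delta(list(c("statin")), list(c("statin", "antiplatelet")))
medication_delta <- function(baseline_meds, followup_meds,
                             method = c("count", "set")) {
  method <- match.arg(method)
  if (!is.list(baseline_meds)) baseline_meds <- list(baseline_meds)
  if (!is.list(followup_meds)) followup_meds <- list(followup_meds)
  n <- max(length(baseline_meds), length(followup_meds))
  baseline_meds <- rep_len(baseline_meds, n)
  followup_meds <- rep_len(followup_meds, n)
  if (method == "count") {
    b <- lengths(baseline_meds)
    f <- lengths(followup_meds)
    ifelse(f > b, "increase", ifelse(f < b, "decrease", "unchanged"))
  } else {
    vapply(seq_len(n), function(i) {
      added <- length(setdiff(followup_meds[[i]], baseline_meds[[i]]))
      removed <- length(setdiff(baseline_meds[[i]], followup_meds[[i]]))
      if (added > 0 && removed == 0) "increase"
      else if (removed > 0 && added == 0) "decrease"
      else "unchanged"
    }, character(1))
  }
}

#' Summarise medication changes among patients recommended an increase
#'
#' Restricts to followed-up patients for whom the engine recommended more
#' medication classes than they had at baseline, classifies each patient's
#' observed six-month change with [medication_delta()], and reports counts
#' with Wald intervals, together with the proportion of the whole cohort
#' that was recommended an increase.
#'
#' @param cohort a validated cohort tibble (baseline medications and
#'   follow-up medications come from here).
#' @param recommendations recommendations tibble for the same patients.
#' @param method change rule passed to [medication_delta()].
#' @param level confidence level.
#' @return a `med_delta_summary` object with counts
#'   (`n_recommended_increase`, `n_increased`, `n_decreased`,
#'   `n_unchanged`, `n_total`) and a `proportions` tibble.
#' @export
medication_delta_summary <- function(cohort, recommendations,
                                     method = c("count", "set"),
                                     level = 0.95) {
  method <- match.arg(method)
  validate_cohort(cohort)
  idx <- match(cohort$patient_id, recommendations$patient_id)
  if (anyNA(idx)) {
    cdss_abort("cohort contains patient_id(s) with no recommendation",
               "cdss_linkage_error")
  }
  fu <- cohort$followed_up
  rec_increase <- lengths(recommendations$recommended_meds[idx]) >
    lengths(cohort$baseline_meds)
  sel <- fu & rec_increase
  delta <- medication_delta(cohort$baseline_meds[sel], cohort$meds_6m[sel],
                            method = method)
  n_ri <- sum(sel)
  n_inc <- sum(delta == "increase")
  n_dec <- sum(delta == "decrease")
  n_unc <- sum(delta == "unchanged")
  n_total <- sum(fu)
  prop_row <- function(what, k, n) {
    if (n == 0) {
      return(tibble::tibble(quantity = what, k = k, n = n,
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    }
    ci <- wald_ci(k, n, level)
    tibble::tibble(quantity = what, k = k, n = n, estimate = ci[["estimate"]],
                   lower = ci[["lower"]], upper = ci[["upper"]])
  }
  props <- rbind(
    prop_row("recommended_increase", n_ri, n_total),
    prop_row("increased", n_inc, n_ri),
    prop_row("decreased", n_dec, n_ri),
    prop_row("unchanged", n_unc, n_ri)
  )
  structure(
    list(n_total = n_total, n_recommended_increase = n_ri,
         n_increased = n_inc, n_decreased = n_dec, n_unchanged = n_unc,
         level = level, method = method, proportions = props),
    class = "med_delta_summary"
  )
}

#' @export
print.med_delta_summary <- function(x, ...) {
  cat("<med_delta_summary> (", x$method, "-based rule)\n", sep = "")
  cat(sprintf("  increase recommended for %d of %d patients\n",
              x$n_recommended_increase, x$n_total))
  pr <- x$proportions
  for (i in seq_len(nrow(pr))) {
    if (is.na(pr$estimate[i])) next
    cat(sprintf("  %-22s %3d/%3d  %g%% (%g-%g)\n", pr$quantity[i], pr$k[i],
                pr$n[i], round_half_up(pr$estimate[i]),
                round_half_up(pr$lower[i]), round_half_up(pr$upper[i])))
  }
  invisible(x)
}

#' Sample size for comparing two independent proportions
#'
#' Two-sided two-proportion sample-size formula with pooled variance under
#' the null:
#' `n = (z_{1-alpha/2} sqrt(2 p. q.) + z_{power} sqrt(p1 q1 + p2 q2))^2 / (p1 - p2)^2`
#' with `p. = (p1 + p2) / 2`, rounded up. With
#' `continuity_correction = TRUE` (the default) the Fleiss adjustment
#' `n_cc = n/4 (1 + sqrt(1 + 4 / (n |p1 - p2|)))^2` is applied before
#' rounding.
#'
#' @param p1,p2 the two proportions (in `(0, 1)`, unequal).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param continuity_correction apply the Fleiss correction? Default `TRUE`.
#' @return a list with `n_per_group` (integer), `n_total`, and the unrounded
#'   `n_raw`.
#' @export
#' @examples
#' sample_size_two_proportions(0.75, 0.85, 0.05, 0.90)  # 354 per group
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.90,
                                        continuity_correction = TRUE) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1) ||
      alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    cdss_abort("p1, p2, alpha and power must all lie strictly in (0, 1)",
               "cdss_validation_error")
  }
  if (p1 == p2) {
    cdss_abort("p1 must differ from p2 (no finite sample size otherwise)",
               "cdss_validation_error")
  }
  d <- abs(p1 - p2)
  pbar <- (p1 + p2) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / d^2
  if (continuity_correction) {
    n <- n / 4 * (1 + sqrt(1 + 4 / (n * d)))^2
  }
  list(n_per_group = as.integer(ceiling(n)),
       n_total = 2L * as.integer(ceiling(n)),
       n_raw = n)
}

#' Monte-Carlo power of the two-proportion z-test
#'
#' Simulates binomial outcomes in two groups of size `n` and applies the
#' two-sided pooled z-test, returning the rejection rate. Used to
#' cross-validate the closed-form sample-size calculation.
#'
#' @param n per-group sample size.
#' @param p1,p2 true proportions.
#' @param alpha two-sided significance level.
#' @param nsim number of simulation replicates.
#' @param seed RNG seed.
#' @return estimated power (a single number in `[0, 1]`).
#' @export
simulate_two_proportion_power <- function(n, p1, p2, alpha = 0.05,
                                          nsim = 20000, seed = 1) {
  set.seed(seed)
  k1 <- stats::rbinom(nsim, n, p1)
  k2 <- stats::rbinom(nsim, n, p2)
  pp <- (k1 + k2) / (2 * n)
  se <- sqrt(pp * (1 - pp) * 2 / n)
  z <- (k1 / n - k2 / n) / se
  z[se == 0] <- 0
  mean(abs(z) > stats::qnorm(1 - alpha / 2))
}
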