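---
title: "Methods: the chest-pain decision engine and its concordance evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chest-pain decision engine and its concordance evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anginacdss)
```

## The clinical problem

Patients referred to a chest pain clinic with suspected new-onset stable
angina are assessed, investigated and started on secondary prevention on the
basis of how likely obstructive coronary artery disease (CAD) is. UK
guidance (NICE CG95) structures that assessment around a *pre-test
probability* (PTP) of CAD looked up from four inputs: age, sex, the
*typicality* of the pain, and a binary risk-factor status. This package
implements that decision logic as a rule engine, the descriptive statistics
used to audit whether clinic behaviour follows its recommendations, and a
synthetic cohort generator so the whole audit can be exercised without any
patient data.

## The decision engine

**Pain typicality.** Three yes/no questions are asked: is the discomfort
constricting; is it precipitated by exertion; is it relieved within minutes
by rest or glyceryl trinitrate. Pain with all three features is *typical*
angina, with exactly two *atypical*, and with one or none *non-anginal*.
`classify_pain()` is a total function on the eight boolean triples, with
preimage sizes 1, 3 and 4 respectively.

**Risk stratification.** A patient is *high risk* if any configured risk
flag is present (smoking, diabetes, hyperlipidaemia, and by default an
abnormal resting ECG), otherwise *low risk*. Whether the resting ECG
contributed to risk stratification in the original tool is not documented,
so the flag set is part of the guideline config (`risk_flags`) and the ECG
flag can be removed without touching code; the default includes it, which is
the more conservative choice (it never lowers a PTP).

**PTP lookup.** The packaged table transcribes NICE CG95 Table 1: percent
probabilities by sex, four age bands (under 45, 45–54, 55–64, 65+),
typicality and risk level. Ages outside the tabulated range clamp to the
nearest band. The engine enforces only structure: the table must be total
over its 48-cell domain, high-risk values must not be below low-risk values,
and PTP must not decrease along non-anginal → atypical → typical. The
numbers themselves live in an editable YAML file
(`default_guideline_path()`), because the engine is agnostic to them.

**Investigation recommendation.** Bands are half-open `[lo, hi)` with the
top band closed at 100, so they partition `[0, 100]` exactly; this is
validated at load time. The packaged bands follow CG95: below 10% no
diagnostic investigation; 10–29% CT calcium scoring; 30–60% functional
imaging; 61–90% invasive coronary angiography. CG95 makes no diagnostic
recommendation above 90%; the original tool resolved this with an expert
panel decision that such patients should all be offered angiography. That
rule is encoded as `panel_threshold`: strictly above 90 the band is
overridden by invasive angiography, while a PTP of exactly 90 stays in the
61–90 guideline band. Keeping the >90 band in the config as "none" and
letting the panel rule override it keeps the override observable and
testable rather than baking it into the band table.

**Medication recommendation.** Up to three secondary-prevention classes
(antiplatelet, statin, beta-blocker) are recommended from a table keyed by
(typicality, PTP band). The original panel's rules were never published, so
the packaged table is an explicit, documented stand-in that scales therapy
with the likelihood of CAD; it is marked as such in the config file. The two
behaviours the evaluation depends on — no drugs for low-probability
non-anginal pain, all three classes for high-probability typical angina —
are pinned by tests. Baseline medications never alter the recommendation;
they only enter the downstream change classification.

**Clinician override.** Observed practice included clinicians recording a
typicality label that differed from the three answers. `run_cdss()`
therefore accepts an optional `typicality_override` so both behaviours are
testable; the default is always the computed label.

## The concordance evaluation

A patient's management is **followed** when an investigation was recommended
and at least one qualifying investigation was done within six months, or
none was recommended and none was done — recommended-versus-any-done, not
modality matching, which is how the audit tables are defined. Patients with
no six-month linkage are excluded from every denominator.

**Confidence intervals** are Wald normal-approximation intervals on the
percent scale, *p* ± *z*·√(*p*(1−*p*)/*n*), clamped to [0, 100] (an
unclamped variant exists because published tables sometimes print negative
lower bounds, e.g. −3 for 2/25). The choice of Wald over Wilson or exact
intervals reproduces the published audit tables this package re-derives.
Rounding to integer percent is a separate presentation step and rounds half
away from zero (`round_half_up()`), not half-to-even.

Two published bounds cannot be reproduced by any single deterministic rule:
for 44/74 the unrounded Wald upper bound is 70.65 (prints 71, published 70)
and for 15/105 the lower bound is 7.59 (prints 8, published 7). Those rows
are consistent with the formula having been applied to the integer-rounded
proportion (59%, 14%), but other published rows (e.g. 78/106 → 65–82) are
consistent only with the exact proportion. The package follows the exact
formula everywhere and documents these one-unit presentation discrepancies
rather than matching them case by case.

**Medication change** is count-based: the number of classes at follow-up
versus baseline, because the audited quantity is the *number* of medication
classes. A swap (statin → antiplatelet) is therefore "unchanged". A
set-based variant (`method = "set"`) is available but not the default.
`medication_delta_summary()` restricts to patients for whom the engine
recommended more classes than they had at baseline, mirroring the audit's
"recommended an increase" denominator.

**Sample size.** `sample_size_two_proportions()` implements the pooled
two-sided two-proportion formula with the Fleiss continuity correction by
default: n = n₀/4 · (1 + √(1 + 4/(n₀·|p₁−p₂|)))², rounded up. For 75% vs
85% at α = 0.05 and 90% power it returns 354 per group (708 in all); the
uncorrected value (335) is cross-validated in the tests against
`power.prop.test()` and a 20,000-replicate Monte-Carlo power simulation of
the pooled z-test, which achieves the nominal power within Monte-Carlo
error.

## The synthetic cohort generator

`generate_cohort()` emulates the *marginal* structure of a chest-pain clinic
population. Defaults are the pre-intervention baseline characteristics: age
~ Normal(59.4, 11.0²) truncated to [18, 120] and rounded to whole years;
49% male; smoking 41%, diabetes 8%, hyperlipidaemia 32%; typicality
19/16/65% typical/atypical/non-anginal; baseline medication prevalences
22/5/25% for antiplatelet/beta-blocker/statin. Two quantities those tables
do not report are documented assumptions: abnormal-resting-ECG prevalence
(default 5%) and the tool-usage probability (default 0.86, the observed
usage rate where the tool was available).

Pain answers are generated *conditionally on a sampled typicality category*
(category from the 3-vector of probabilities, then a uniformly random
boolean triple consistent with it). Independent Bernoulli answers could not
hit the typicality marginals exactly, and typicality is the calibration
target. Risk factors are drawn independently: only marginals are reported
for the reference population, so no correlation structure is modelled. This
is the main respect in which the generator is simpler than real data —
real risk factors cluster, ages correlate with risk burden, and clinicians
game data entry; passing calibration tests here demonstrates the pipeline's
statistical correctness, not realism of joint distributions.

`simulate_pathway()` models six-month behaviour with four probabilities: a
recommended investigation is done with probability
`p_follow_investigation_recommended` (default 0.59, the observed
post-intervention rate); an investigation happens despite a "none"
recommendation with `p_investigate_when_not_recommended` (default 0.14);
each recommended medication class is adopted independently with
`p_follow_medication` (default 0.5, from the observed 17/34), on top of
baseline classes which are assumed continued. Under this model the overall
followed rate is analytically the mixture
w·p_follow + (1−w)·(1−p_not), with w the recommendation prevalence — a
closed form the acceptance tests check at n = 10,000.

One global seed drives a named sub-stream per stage (`cohort`, `pathway`),
so stages re-run independently and the whole generate → recommend →
simulate → evaluate pipeline is bit-reproducible from (config, seed).

## Numerical and design choices

* Band membership uses `findInterval` on the lower edges; brute-force band
  scans serve as the oracle in tests.
* The recommendation prevalence of the synthetic cohort under the packaged
  guideline table is substantially higher than in the audited clinics
  (most non-anginal high-risk patients at the cohort's median age exceed the
  10% threshold). This is expected: the generator is calibrated to the
  baseline *characteristics* table, not to the recommendation mix, which
  depends on unmodelled joint structure. The adherence-recovery tests are
  therefore phrased in terms of the configured conditional probabilities,
  which are identifiable regardless of the prevalence.
* Problem sizes in the test suite: marginal calibration and adherence
  recovery at n = 10,000 with 3-standard-error bands; oracle equivalence on
  cohorts up to n = 1,000; the power simulation uses 20,000 replicates.
* Degenerate inputs: n = 0 cohorts are legal everywhere except the
  concordance summary, whose proportions are undefined and raise a typed
  error; `wald_ci` refuses n = 0; sample size refuses p₁ = p₂.

## Known limitations

* Class-level medication modelling only (no drugs, doses, or
  contraindications); contraindications to the >90% angiography rule
  surface only as the clinician-disagreement field.
* The exercise tolerance test is deliberately absent from the engine, as it
  was from the original algorithm, although it demonstrably influenced real
  decisions — one of the reasons observed concordance was far from 100%.
* The medication rule table is a stand-in; conclusions about medication
  concordance transfer to the original tool only in structure, not in the
  specific recommended sets.
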