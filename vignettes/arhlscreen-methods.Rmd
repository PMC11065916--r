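---
title: "Methods: the ARHL screening protocol and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ARHL screening protocol and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arhlscreen)
```

## The screening protocol

Age-related hearing loss is common, under-recognised and consequential;
pure-tone audiometry (PTA) diagnoses it reliably but is too expensive for
population screening. The protocol implemented here triangulates three
cheap components and validates them against PTA.

**Risk-factor score.** Eighteen binary indicators — demographic (male
sex, living alone, widowed/divorced), behavioural (non-light diet, no
exercise habit, smoking, drinking, headset habit, occupational noise
history), anthropometric (BMI ≥ 24.0 kg/m², boundary inclusive) and
comorbid (hypertension, diabetes, hyperlipidemia, cardio-/cerebrovascular
disease, hyperuricemia, hypothyroidism, ototoxic drug history, family
history of deafness) — are summed with unit weights. Age is deliberately
*not* an indicator: in a population restricted to 60+, it would dominate
the count while being unmodifiable; it still drives risk inside the
simulator's generative model. The score is dichotomised at ≥ 4, the
ceiling of the Youden-optimal midpoint cutoff 3.5 obtained from ROC
analysis of the score against PTA. The threshold is a configuration value
(`threshold` argument everywhere), not re-derived at run time.

Behavioural indicators reach the package as already-resolved yes/no
answers (e.g. smoking "> 1 piece/day for 6 consecutive or cumulative
months"): a questionnaire front-end applies the duration arithmetic, this
package does not. Missing booleans are a hard error by default;
`assume_absent = TRUE` imputes `FALSE` with a warning, because a silent
"no risk factor" default would bias a screen towards false negatives.

**HHIE-s.** Ten items scored 4/2/0 (yes/sometimes/never), total 0–40,
always even. Totals 0–8, 10–22, 24–40 map to no-obvious,
mild-to-moderate and severe handicap; abnormal ⇔ total ≥ 10. An odd
total is unreachable under the weights, so it is rejected as corrupted
input rather than rounded — a deliberate fail-fast choice. Items 1–5 and
6–10 are the conventional emotional/situational subscales; no decision
uses them, only the total.

**Two-step audiometry.** Per ear: 2 kHz at 42 dB HL twice; fewer than two
perceptions fails the ear outright and the second tone is never
administered (the validators enforce this short-circuit structurally).
Otherwise 0.5 kHz at 47 dB HL twice; fewer than two perceptions fails.
Only the (2, 2) pattern passes. "Failed" is designed to flag
moderate-or-worse loss (> 40 dB HL better-ear average). **Binaural
combination is pass-if-either-ear-passes**: the reference standard is the
*better-ear* PTA average, so a single passing ear is evidence the better
ear is not moderately impaired. The protocol literature leaves this
combination unstated; the either-ear rule is this package's documented
choice, and the only one consistent with a validation reporting 100%
sensitivity and 100% NPV.

**Triage.** All-negative → screen negative, self-re-screen in 6 months.
Any positive component → screen positive, re-screen in 3 months; a failed
audiometry additionally refers to the general practitioner. Mixed
patterns are only specified for the two pure corners in the protocol
description; the OR rule for the six mixed cells is again a documented
design choice that maximises sensitivity, the stated purpose of a
community screen.

**Reference classification.** PTA reference = better (lower) ear's
arithmetic mean of the 0.5/1/2/4 kHz air-conduction thresholds. Grades:
normal ≤ 25 < mild ≤ 40 < moderate ≤ 55 < moderately-severe ≤ 70 <
severe ≤ 90 < profound. The conventional integer bands (26–40, 41–55, …)
leave gaps for non-integer averages such as 25.25; the bands here extend
each lower band up to the next edge, which preserves the two binary
decisions (> 25, > 40) exactly and assigns every real-valued average a
unique grade. Averages are compared to edges unrounded.

## Validation statistics

`confusion()`/`matrix_metrics()` give sensitivity, specificity, PPV, NPV
and accuracy; a zero denominator yields an explicit `NA` ("undefined"),
never `NaN`. `cohen_kappa()` is (po − pe)/(1 − pe) on the 2×2 table.
`spearman_rho()` is the Pearson correlation of mid-ranks (average ranks
on ties), computed directly. `roc_curve()` uses midpoints between
consecutive distinct scores as cutoffs (plus sentinels beyond both
extremes), calls a subject positive when its score exceeds the cutoff,
integrates the trapezoidal AUC, and picks the Youden-maximal cutoff,
breaking ties toward the smallest (most sensitive) cutoff with a message.
The trapezoidal AUC equals the pairwise concordance statistic
P(score⁺ > score⁻) + ½P(tie); the test suite verifies this equivalence on
random instances and cross-checks against independent implementations
(pROC, caret).

When only rounded percentages of a published validation are available,
`reconstruct_matrix()` enumerates every non-negative integer 2×2 table
with the stated total and keeps those whose metrics round (half-up, one
decimal — the reporting convention; base R's `round()` is half-to-even,
hence the exported `round_half_up()`) to the published values, declaring
uniqueness when a single table survives. For n = 109 with sensitivity
100.0%, specificity 65.5% and PPV 71.8% the unique solution is
tp = 51, fp = 20, fn = 0, tn = 38, whose kappa is 0.640 and NPV exactly
100.0%.

## The synthetic cohort generator

No subject-level dataset accompanies the protocol, so the generator
emulates the population the screen targets; it is first-class, tested
code, and the basis of all end-to-end validation.

Per subject, with one seed fixing the entire stream:

* **Age** ~ Normal(71.0, 6.1) years, truncated at 60, rounded to years.
* **Factors** ~ independent Bernoulli with the observed community
  prevalences (hypertension 0.643, diabetes 0.307, no exercise 0.481,
  male 0.454, non-light diet 0.279, cardio 0.244, smoking 0.177,
  hyperuricemia 0.170, widowed/divorced 0.105, drinking 0.102,
  hyperlipidemia 0.092, living alone 0.075; factors without a reliable
  published prevalence default to 0.05). Independence is a simplification:
  no covariance structure for these factors is published. A Gaussian-copula
  `factor_correlation` hook exists for sensitivity analyses. The
  documented consequence: the risk score's AUC on simulated cohorts
  (≈ 0.62–0.70) need not reproduce the ≈ 0.78 achievable on real,
  correlated data, and the score–PTA Spearman correlation is likewise
  weaker than on real cohorts.
* **Hearing loss** ~ Bernoulli(inverse-logit(α + 0.104·(age − 71) +
  Σβ·x)), with factor log-odds from the published multivariate model
  (diabetes 1.461, hypothyroidism 1.645, noise history 1.357,
  hyperuricemia 1.155, non-light diet 0.894, drinking 0.741, hypertension
  0.609, cardio 0.362, hyperlipidemia 0.246, widowed/divorced 0.148; the
  non-significant negative estimates male −0.056, overweight −0.081, no
  exercise −0.385 are kept as printed). Factors whose published
  univariate estimates were unstable (headset, ototoxic drugs, family
  deafness, living alone, smoking) get β = 0 by default; everything is
  configurable. Continuous BMI is not a generative covariate — it would
  double-count the overweight indicator.
* **Intercept α** is calibrated by bisection (`uniroot`) so the mean
  simulated risk equals `target_prevalence` (default 0.798) over a seeded
  quasi-population of `calib_n` = 500,000 linear predictors, accurate to
  1e−4 on the prevalence scale; the calibration stream is derived from
  the cohort seed and restores the caller's RNG state. A closed-form
  expectation over all 2¹⁸ factor combinations with age quadrature was
  rejected as needlessly heavy for the same accuracy.
* **Grade**, given loss, is drawn from the renormalised mix
  48.5/23.4/7.8/1.3/0.7 (mild…profound); the **better-ear average** is
  uniform within the grade's dB band (normal 0–25, profound capped at
  110 dB HL — only band membership, not a within-band distribution, is
  ever published). The worse ear adds an exponential offset (mean 8 dB,
  capped at 110), the better ear's side is random, and per-frequency
  thresholds add a centred tilt rising with frequency (±1.5 × 4.5 dB plus
  ±1 dB uniform noise, re-centred), emulating the high-frequency-sloping
  audiogram typical of presbycusis while preserving each ear's
  four-frequency mean exactly — so `pta_classify()` on the written
  thresholds reproduces the latent average and grade bit-for-bit.
* **HHIE-s items**: cumulative ordinal draw per item with shared severity
  term; P(≥ sometimes) = logistic((avg − 42)/5), P(yes) =
  logistic((avg − 54)/5). The triple (midpoint 42 dB, yes-gap 12 dB,
  slope 5 dB) was chosen once, by exact convolution of the 10-item total,
  so that a 40 dB better-ear average yields P(total ≥ 10) = 0.497 ≈ 50% —
  a convention anchoring "abnormal questionnaire" at the moderate-loss
  boundary, not an empirical fit.
* **Tone trials**: each presentation is heard with probability
  logistic((level − threshold)/`tone_slope`), default slope 3 dB, a
  typical psychometric-function spread near threshold; `tone_slope ≤ 0`
  is the noiseless mode in which a tone at or above threshold is always
  heard (useful for structural tests). The 0.5 kHz tone is drawn only for
  ears that heard the 2 kHz tone twice, preserving the decision tree's
  administration structure in the data itself.

Simulated subjects pass every downstream validator, and the truth columns
(`true_hearing_loss`, `true_better_ear_avg`, `true_grade`,
`true_linpred`) are retained for diagnostics.

### What the simulator does and does not show

Calibration and recovery are tested: empirical prevalence within 3
Monte-Carlo SE of 0.798 at n = 100,000, and every non-zero generative β
recovered by a logistic refit within 3 pooled SE at n = 5,000 averaged
over 5 seeds. Severity monotonicity (mean HHIE-s total and audiometry
failure rate non-decreasing across grades) is asserted on a cohort of
2,000. These sizes were chosen to make the Monte-Carlo error comfortably
smaller than the tolerances while keeping the default suite fast.

Passing these tests shows the pipeline is internally coherent under the
stated generative model. It does **not** show field performance: real
factor correlations, measurement error in questionnaires, ambient noise
during phone audiometry, and selection effects in who completes a
community screen are all outside the model. Published cohort-dependent
results (a score AUC of 0.777, screen sensitivity 70.9%/specificity 75.3%
at the 3.5 cutoff, Spearman correlations near 0.7) arise from such real
data and are intentionally not reproduction targets for the simulator.

## Numerical conventions and edge cases

* Published-value matching: half-up rounding at one decimal (percent) and
  kappa compared at one decimal.
* Youden ties: smallest cutoff wins, with a message.
* Degenerate inputs: single-class labels are an error for ROC and
  validation; constant vectors make Spearman `NA`; zero-denominator
  metrics are `NA`; a `pe = 1` kappa is `NA`.
* CSV serialisation: booleans 0/1, `.` decimal separator, blank for a
  not-administered 0.5 kHz tone; outputs are written atomically (temp
  file + rename) so failures never leave partial files; identical inputs
  give byte-identical outputs.
* All RNG flows from the single cohort seed; the intercept calibration
  uses a derived stream and restores the caller's RNG state.

## Known limitations

* Factor independence (by default) understates the real score AUC, as
  discussed above.
* The within-grade uniform dB distribution and the exponential worse-ear
  offset are conventions; real audiometric distributions are skewed
  within bands.
* The HHIE-s link ignores item-specific difficulty (all ten items share
  one ordinal model).
* Confidence intervals are not emitted; where needed, the
  normal-approximation interval is the intended addition.
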