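---
title: "Predictive triage for low-sensitivity diagnostic tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive triage for low-sensitivity diagnostic tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagedx)
```

## The decision problem

A diagnostic test with high specificity but low sensitivity is informative
almost exclusively through its positive results. When such a test is also
expensive or burdensome, the question is not "is the test accurate?" but
"for which patients is the expected benefit worth the cost?". `triagedx`
answers it in two stages:

1. **Inference.** Estimate, for each candidate patient, the posterior
   probability `p(C1 | x)` that the test will come back positive, from a
   vector of predictors `x` already available before testing.
2. **Decision.** Select the patient for testing iff `p(C1 | x) > p*`, where
   the threshold `p*` is determined by a 2×2 loss matrix
   `L[true][assigned]`:
   `p* = (L01 − L00) / ((L01 − L00) + (L10 − L11))`.
   In cost–benefit terms, with test cost `C` and outcome benefits
   `B_neg < B_pos`, this is `p* = (C − B_neg)/(B_pos − B_neg)`; for a
   low-sensitivity test `B_neg ≈ 0` is a reasonable simplification and `p*`
   becomes the cost–benefit ratio `C/B_pos`.

The worked domain is the glycerol test for Menière's disease. The
predictors are pure-tone audiogram thresholds (dB HL) at the 10-frequency
grid 125–8000 Hz; the outcome criterion is an aggregate threshold
reduction (ATR) of at least 30 dB between the pre- and post-glycerol
audiograms.

## Posterior models

**K-nearest neighbours.** The posterior is the fraction of positive
outcomes among the `K` nearest previous patients in Euclidean predictor
space, `p = K1/K`. Two conventions matter:

* *Tie expansion.* All training points tied with the K-th distance enter
  the vote (with the denominator enlarged accordingly). This makes the
  posterior independent of record order — a requirement for reproducibility,
  since audiometric predictors are quantised in 5 dB steps and exact
  distance ties are common.
* *No standardisation by default.* All audiometric predictors share the dB
  scale, so the raw Euclidean metric is meaningful; a z-scaling flag exists
  for heterogeneous predictors.

The default `K = 10` is a package choice, not a canonical value: a moderate
`K` keeps the posterior grid `0, 1/K, …, 1` fine enough for threshold
analysis at cohort sizes of a few hundred without washing out local
structure. Results for other `K` are one argument away.

**Logistic regression.** `p(C1 | x) = sigmoid(w0 + w·x)`, optionally with
each predictor's square appended (no cross terms), fitted by maximum
likelihood via iteratively reweighted least squares (`stats::glm.fit`,
relative deviance tolerance `1e-8`, at most 100 iterations). Complete
separation makes the Bernoulli likelihood attain its supremum only in the
limit of infinite weights; it is detected after the fit — residual deviance
below `1e-6` (every case fitted perfectly) or coefficient norm above
`1e4` — and raised as an error rather than returning meaningless weights.
A single-class outcome vector is likewise an error.

**Evaluation.** All performance claims use leave-one-out cross-validation:
record *i*'s posterior comes from a model trained on all records except
*i*. The resulting posterior set is a "virtual screening test" score that
can be fed to every downstream analysis.

## ROC and likelihood-ratio machinery

The decision rule is strictly `posterior > τ` everywhere in the package;
ties go to "do not test". ROC curves tabulate the confusion counts at every
attained posterior value (plus a sentinel above the maximum and a test-all
point below the minimum, so both corners of ROC space are always present).
The AUC is computed as the Mann–Whitney rank statistic with half credit for
ties, which equals the trapezoidal area under the empirical staircase and is
well defined under the heavy ties of KNN posteriors.

Predictive values are masked (`NA`) unless based on strictly more than
`min_count = 20` predictions; undefined rates (zero denominators) are `NA`
markers, never exceptions, so curves can carry masks without corrupting
downstream arithmetic.

The binormal layer supplies the closed forms
`AUC = Φ((μ1 − μ0)/√(σ0² + σ1²))`, the area-related index
`d_a = √2·Φ⁻¹(AUC)` (reducing to the detectability index d′ under equal
variances), and the parametric ROC `tpr = Φ(d′ − Φ⁻¹(1 − fpr))`.

## Expected-loss curves

Two designs are implemented.

* **Clinical design** (per candidate patient): losses are anchored by the
  postulate that a perfect classifier has zero loss, giving
  `L = [[0, C], [B − C, 0]]` and the per-patient estimate
  `E[loss](τ) = (FP·C + FN·(B − C))/N`. Only loss *differences* matter when
  comparing thresholds; constants added per true-class row cancel, which the
  test suite verifies on random tables.
* **Screening design** (per tested subject, for a study that recruits until
  a fixed number of subjects has been tested): screening `1/RPP` candidates
  per tested subject at cost `C_screen` each, paying `C_test` per test and
  receiving `B_pos` for the PPV fraction,
  `E[loss](τ) = C_screen/RPP + C_test − B_pos·PPV`.

The default threshold grid is the set of attained posterior values plus the
endpoints — KNN posteriors are discrete, so no other threshold changes any
decision. Two conventions are worth stating explicitly:

* The `τ = 0` grid point represents the *test-all* policy. Under the strict
  `p > τ` rule alone, records with posterior exactly 0 would be excluded at
  `τ = 0`; defining the endpoint as test-all preserves the endpoint algebra
  — at `τ = 0` the loss is `(1 − prevalence)·C` irrespective of the assumed
  benefit, and at `τ = 1` it is `prevalence·(B − C)`; the two coincide at
  `1 − prevalence` exactly when `B = 1/prevalence` and `C = 1`.
* Argmin ties are broken toward the *larger* threshold (test fewer
  patients), a conservative and deterministic default.

On calibrated posteriors the empirical argmin converges to the analytic
`p* = C/B`; the acceptance suite checks this at `n = 100 000` on a
0.01-step grid.

**Net benefit.** Decision-curve analysis' net benefit
`NB = TP/N − (FP/N)·p_t/(1 − p_t)` is an affine transform of the expected
loss: with `L00 = L10 = 0`, `L01 = c`, `L11 = c − b` and `p_t = c/b`, the
expected loss equals `−(b − c)·NB` exactly, so both rank thresholds
identically. The suite verifies the identity symbolically on random
confusion tables.

A remark on the screening design: it is tempting to expect the loss curve
to be minimised at the test-all end whenever `C_screen ≥ C_test`. That is
not forced — with a sufficiently predictive posterior, the PPV gain from
selectivity can outweigh a screening cost equal to the test cost. What does
hold, and what the tests assert, is the monotone direction (the optimal
threshold is non-increasing in `C_screen`) and the test-all limit once the
screening cost clearly dominates (about four times the test cost on the
default synthetic cohort).

## ATR, predictor spaces and the region search

**ATR.** The aggregate threshold reduction is the maximum, over all
contiguous frequency windows, of the summed per-frequency reduction
(pretest − posttest), floored at 0 — a maximum-subarray with the empty
window allowed. A window may contain frequencies at which hearing worsened
if its total still wins; this is the most direct reading of "aggregate
reduction in a contiguous frequency range" and degrades gracefully for
noisy audiograms. The ATR is computed over the full grid, not only over the
frequencies used as predictors, because the outcome criterion predates any
predictor-space restriction. The implementation (Kadane's scan) is checked
against full window enumeration. The default 30 dB criterion is inclusive
("at least 30 dB") and carries a test–retest false-positive rate of about
5 %.

**Predictor spaces.** `kF` uses the `k` lowest frequencies; `LH` the mean
low-band (125–1500 Hz) and high-band (2000–8000 Hz) losses; `LH-` replaces
the high mean by the high-minus-low difference (responders sit below the
zero line); `7F3d` reduces the 7 lowest frequencies to 3 averaged
predictors. The 125-vs-150 Hz ambiguity in the low band's lower edge is
resolved by making the grid fully configurable; the default grid starts at
125 Hz.

**Rule of thumb.** Eligibility iff the mean low-frequency loss lies in
[30, 70] dB (inclusive — "between 30 and 70" and "does not exceed" read as
closed bounds) and the high mean does not exceed the low mean.

**Region search.** All rectangles whose four bounds lie on a `step_db`
grid (anchored at multiples of the step, default 5 dB, matching the
quantisation of audiometric data) spanning the data range are enumerated;
bounds are inclusive on all edges; the inclusion constraint uses
`ceiling(min_fraction·N)`. Ties in the positive rate are broken by larger
inclusion count, then smaller area, then lexicographically smallest bounds,
making the optimum unique. The enumeration is O(G⁴) in the grid-line count
G and refuses G > 60 without `force = TRUE`. Correctness is established
against an independently coded brute-force enumerator.

## The synthetic cohort generator

`gen_cohort_audiograms()` emulates the structure of the glycerol study:

* 356 patients, latent responder prevalence 0.39;
* responders' low-band loss centred at 55 dB (sd 14) with high-minus-low
  offset −10 dB (sd 16): intermediate, low-frequency-dominant loss;
* non-responders broader and symmetric (45 ± 26 dB; offset 0 ± 20 dB);
* within-band per-frequency spread 6 dB; all values clipped to
  [−20, 140] dB HL;
* responders receive a non-negative post-test improvement of
  12 ± 4 dB per low-band frequency (aggregate ≈ 60 dB, so the 30 dB
  criterion is met with probability ≈ 1);
* every patient receives test–retest jitter of sd 4.92 dB per frequency.
  This value was calibrated once by simulating the maximum-subarray
  distribution of 10 i.i.d. normal reductions: its 95th percentile is
  6.097·sd, so sd = 30/6.097 makes `P(ATR ≥ 30) ≈ 0.05` for a case with no
  true improvement, anchoring the criterion's 5 % false-positive rate.

The `outcome` column is always derived by running the generated audiograms
through the real ATR pipeline, never copied from the latent class; latent
class and derived outcome agree for ≈ 97 % of records, and the outcome
prevalence lands near 0.39. The class-location/spread defaults were chosen
so that the emulated cohort reproduces the *qualitative* anatomy of the real
data — LOOCV KNN AUC in the high 0.6s to low 0.7s, a 5 %-inclusion optimal
region with a positive rate near 0.85, a rule-of-thumb subgroup of ~130–145
patients with a rate near 0.57.

What the generator does **not** emulate: audiometer quantisation to 5 dB
steps, frequency-to-frequency correlation beyond the shared band mean,
asymmetric or notched audiogram shapes, disease progression, and any
dependence of glycerol response on factors outside the audiogram.
Consequently, passing tests demonstrate the correctness and calibration of
the machinery under a plausible data-generating process — not the clinical
performance figures to be expected on real patients.

Generators use an explicit seed contract: the scenario seed fully
determines the output and the caller's RNG state is saved and restored.

## Problem sizes and tolerances in the test suite

Property suites run at desk scale: 100–500 random instances for the
AUC/pair-count, KNN/brute-force and ATR/enumeration oracles; region-search
oracle instances of ≤ 200 points; binormal closed-form agreement at
n = 50 000 (3 standard errors, Hanley–McNeil variance); d_a parameter
recovery through the full pipeline (scores → LOOCV KNN with
K = ⌊√n⌋ → AUC → d_a) at n = 2 000 over 20 seeded replicates with a
|bias| < 0.1 band; loss-curve argmin consistency at n = 100 000 on a
0.01-step threshold grid. The K = ⌊√n⌋ choice in the recovery pipeline is
the usual bias–variance compromise: at fixed K the posterior noise floor
depresses the AUC of the posterior scores, while K growing with n (but
slower than n) makes the posterior consistent for the monotone true
`p(x)`, whose AUC equals that of the underlying scores.

## Known limitations

* The exact `K` and ATR windowing convention of the original glycerol
  analysis are not recoverable from the published text; defaults are
  documented package choices, and reproduction of the original patient-level
  tables requires the original cohort data, which is not redistributable
  with the package (the corresponding acceptance check runs only when a
  local copy is present).
* No AUC confidence intervals, partial AUC, or weighted/kernel KNN.
* The region optimiser considers bounded rectangles only; the rule of
  thumb's unbounded-below region is a fixed classifier, not a search
  output.
* Costs and benefits are abstract units; no monetary calibration is
  attempted, and only the binary test/don't-test decision is modelled.
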