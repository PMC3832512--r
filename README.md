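# triagedx

Decision-analytic triage for expensive diagnostic tests with high
specificity but low sensitivity.

## The problem

Some confirmatory tests are informative when positive and nearly
uninformative when negative: the glycerol test for Menière's disease is the
canonical example. The test is time-consuming and uncomfortable, and among
candidate patients only about 39 % come back positive, so testing everyone
can be wasteful — yet a blanket decision not to test throws away the benefit
for the patients who *would* have tested positive. `triagedx` implements the
middle road: estimate, per patient, the posterior probability
*p(positive outcome | pre-test data)* from previous patients' records, and
test a patient only when that probability exceeds a threshold derived from
the costs and benefits at stake.

For the glycerol test the pre-test data are pure-tone audiograms (hearing
level in dB HL at up to 10 frequencies) and the outcome criterion is an
aggregate threshold reduction (ATR) of at least 30 dB over a contiguous
frequency range between the pre- and post-glycerol audiograms.

## What the package provides

* **Posterior prediction** — K-nearest-neighbour posteriors
  (`p = K1/K`, tie-expanded neighbourhoods) and linear/quadratic logistic
  regression, both evaluated honestly by leave-one-out cross-validation
  (`loocv_posteriors()`).
* **Predictor spaces** — the named audiogram reductions `1F`–`10F`, `LH`,
  `LH-` and `7F3d` (`make_predictors()`), plus the 30–70 dB low-frequency
  rule of thumb (`rule_of_thumb()`).
* **ROC machinery** — confusion counts with a strict `p > τ` rule, FPR/TPR,
  rate of positive predictions, PPV/NPV with a minimum-count mask, AUC as the
  tie-aware Mann–Whitney statistic, LR⁺ = TPR/FPR, odds transforms, and the
  binormal indices AUC = Φ((μ₁−μ₀)/√(σ₀²+σ₁²)) and d_a = √2·Φ⁻¹(AUC).
* **Decision analysis** — loss matrices L[true][assigned], the optimal
  threshold p\* = (L01−L00)/((L01−L00)+(L10−L11)) (equivalently
  (C−B_neg)/(B_pos−B_neg), the cost–benefit ratio when B_neg = 0),
  expected-loss-vs-threshold curves for a clinical and a screening-study
  design (`loss_curve()`), and the net-benefit formulation of decision-curve
  analysis with its exact affine equivalence to the expected loss
  (`net_benefit()`).
* **Region search** — exhaustive optimisation of axis-aligned rectangles in
  a 2-D predictor space maximising the positive-outcome rate under a
  minimum-inclusion constraint (`search_regions()`).
* **Synthetic cohorts** — seeded generators for binormal score cohorts and
  for full audiogram cohorts emulating the glycerol study (356 patients,
  ~0.39 prevalence, low-frequency-dominant loss in responders, ATR
  false-positive rate ≈ 5 %), with the outcome always derived through the
  real ATR pipeline (`gen_cohort_audiograms()`).

A thin command-line wrapper (`exec/triage`) chains the same functions:
`simulate`, `loocv`, `roc`, `loss-curve`, `region-search`, `report`.

## Worked example

```r
library(triagedx)

co <- gen_cohort_audiograms(audiogram_scenario(seed = 1))
co
#> cohort: 356 records, 10 frequencies
#>   fields present: posttest, atr, outcome
#>   outcome prevalence: 0.382

ps <- loocv_posteriors(make_predictors(co, "7F"), co$data$outcome,
                       knn_config(k = 10), ids = co$data$patient_id)
auc(ps$posterior, ps$outcome)
#> [1] 0.6625668

cm <- confusion_at_threshold(ps$posterior, ps$outcome, 0.5)
cm
#> confusion at tau = 0.5: TP 44, FP 39, TN 181, FN 92 (N = 356)
r <- rates(cm)
c(rpp = r$rpp, lr_plus = lr_plus(r$tpr, r$fpr))
#>       rpp   lr_plus
#> 0.2331461 1.8250377

loss_curve(ps, design = "clinical", cost = 1, benefit = 3)
#> loss_curve (clinical design): 11 thresholds; minimum 0.488764 at tau = 0.3

lhm <- make_predictors(co, "LH-")
search_regions(lhm[, 1], lhm[, 2], co$data$outcome,
               min_fraction = 0.05, step_db = 5)
#> region x: [50, 55]  y: [-50, 0]  (52.5±2.5 / -25±25)
#>   n inside: 23, positive: 18, rate: 0.783
```

Reading the output: leave-one-out KNN on the seven lowest audiogram
frequencies separates future positives from negatives with AUC 0.66. At the
default threshold 0.5 about 23 % of candidates would be selected for
testing, and a positive prediction multiplies the odds of a positive
glycerol test by 1.8. If the benefit of a positive outcome is worth three
times the cost of the test, the expected loss is minimised near τ = 0.3 —
close to the analytic threshold C/B = 1/3, as it should be when the
posteriors are well calibrated. Independently, the exhaustive region search
finds that patients whose mean low-frequency loss is 50–55 dB and whose
high-frequency loss does not dominate have a 78 % probability of a positive
test, versus the 38 % cohort prevalence.

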