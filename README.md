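# asthmon

Multi-sensor home monitoring of paediatric asthma control: a complete,
tested R pipeline from raw wearable sensor streams to a multivariate
classification of asthma control, together with a first-class synthetic
cohort generator calibrated to a two-week paediatric monitoring study
(27 uncontrolled / 32 controlled asthmatic and 30 non-asthmatic children).

## The problem and the model

Asthma control in children is assessed in clinic from four symptom-control
items over the past four weeks plus an exercise bronchoprovocation
challenge: a child is **uncontrolled** when at least three items are present
*or* the maximal post-exercise FEV1 fall exceeds 12%. `asthmon` implements
the home-monitoring alternative end to end:

* **ECG** (single-lead, 250 Hz): Kaiser-window FIR band-pass 0.45–39 Hz,
  derivative-energy QRS detection, ECG-derived respiration from the RS
  amplitude (R minus S, spline-resampled at 50 Hz), daytime/night-time
  heart- and respiratory-rate means, and post-exertion recovery times
  (first sustained return of the 10-s moving median to within 5% of the
  excursion above the pre-bout baseline).
* **Actigraphy** (60-s wrist epochs): Evenson intensity minutes, activity
  bouts and their Weibull scale (profile MLE), Cole-Kripke sleep scoring,
  main-sleep-period detection, wake-up time, efficiency, awakenings and
  pre-wake restlessness.
* **Home spirometry**: acceptability QC, percent-predicted conversion,
  pre-exercise means, FEV1 variation (max − min pre-exercise %pred), and
  exercise/symptom FEV1 changes.
* **Smart inhalers**: controller adherence and reliever counts, including
  use within ±30 min of activity.
* **Statistics**: exact MCAR/monotone missingness injection, multiple
  imputation (monotone sequential regression or multivariate-normal
  data-augmentation MCMC under physiological bounds, m = 5), Rubin pooling,
  collinearity screening (|r| > 0.8), stepwise forward likelihood-ratio
  logistic regression (entry 0.10 / removal 0.20) optimised by Nagelkerke
  R², odds ratios `exp(β)` with Wald intervals, and the 2×2 diagnostic
  validity measures.

The final classifier has the familiar logistic form
`logit P(uncontrolled) = β0 + Σ βj xj`; a reference four-parameter model
(FEV1 variation 0.292, wake-up time −0.053, reliever use 0.100,
respiratory-rate recovery time 0.113 per raw unit) ships with the package
for scoring, with a clearly-labelled synthetic-calibration default
intercept.

## Worked example

```r
library(asthmon)
cfg  <- cohort_config(seed = 1)                   # 27/32/30 children
sim  <- simulate_cohort(cfg)                      # renders all raw streams (~1 min)
labs <- label_cohort(sim$profiles)                # symptom-OR-challenge rule
feats <- apply_missingness(sim$features, 0.115, seed = 2)
fit  <- fit_control_pipeline(feats, labels = labs$label == "uncontrolled",
                             config = cfg, seed = 3)
print(fit)
```

```
<control_model> 5 feature(s), Nagelkerke R^2 = 0.92 [Firth-penalised]
                           coef    or lower  upper
fev1_change_exercise_pct -0.276 0.759 0.422  1.364
fev1_change_symptom_pct  -0.075 0.928 0.852  1.011
night_rr                  0.759 2.136 0.266 17.145
reliever_total            0.212 1.236 0.897  1.704
rr_recovery_s             0.027 1.027 0.987  1.069
              truth
predicted      uncontrolled controlled
  uncontrolled           25          0
  controlled              2         32
sensitivity 92.6%  specificity 100.0%  PPV 100.0%  NPV 94.1%
```

Read: on this synthetic cohort the stepwise-selected pooled model explains
92% of the outcome variation (Nagelkerke) and classifies 25 of 27
uncontrolled and all 32 controlled children in-sample; separation triggered
the flagged Firth-penalised refit. Selection is seed-dependent — the
synthetic groups separate on several correlated parameters.

The reference model's odds-ratio arithmetic:

```r
odds_ratios(reference_control_model())
```

```
                     coef    or lower upper inverse_or
fev1_variation_pct  0.292 1.339 1.066 1.682      0.747
wakeup_min         -0.053 0.948 0.910 0.988      1.054
reliever_total      0.100 1.105 1.029 1.187      0.905
rr_recovery_s       0.113 1.120 1.046 1.198      0.893
```

Per percent-predicted point of FEV1 variation the odds of uncontrolled
asthma rise by a factor 1.34; per minute *earlier* wake-up by 1.05; per
reliever inhalation by 1.11 (+10.5%); per second of respiratory-rate
recovery by 1.12.

A thin command-line front end over the same functions is installed at
`inst/scripts/asthmon.R` (`simulate`, `extract`, `fit`, `score`).

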