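# myomapr

Quantitative multiparametric cardiovascular MRI (CMR) analysis for
suspected acute myocarditis.

Myocardial inflammation is focal: small high-T2 (edematous) lesions sit
inside mostly normal tissue, so global mean T2 separates patients from
controls poorly. This package implements, end to end, an analysis built
around **tissue-inhomogeneity statistics** instead:

- **T2 mapping** — pixel-wise mono-exponential fitting of multi-echo
  magnitude images by maximum likelihood under a Rician noise model
  (log-likelihood per echo
  `ln(m/σ²) − (m² + ν²)/(2σ²) + ln I₀(mν/σ²)`, `ν = S₀·e^(−TE/T₂)`),
  with a log-linear least-squares comparator and per-slice background
  noise estimation.
- **AHA 16-segment parcellation** of three short-axis slices, segmental
  mean T2 and pixel-SD, and the subject statistics **maxT2** (highest
  segmental T2) and **madSD** (mean absolute deviation of the 16
  segmental pixel-SDs, `madSD = (1/K) Σ |SDₖ − mean(SD)|`).
- **Feature-tracking strain** — endocardial contour propagation through
  the cine cycle by normalized cross-correlation block matching with
  subpixel refinement and cyclic drift correction; Lagrangian perimeter
  strain, strain rate, global circumferential/longitudinal peaks (GCS,
  GLS).
- **Quantitative Lake Louise criteria** — T2-ratio (≥ 1.9), early
  gadolinium enhancement ratio (≥ 4), and the 2-of-3 diagnosis rule.
- **Diagnostic modelling** — logistic models compared by AIC, rank-based
  ROC/AUC, classification-tree cut-off discovery (exhaustive Gini scan),
  strict k-of-k combined rules, and confusion-matrix metrics.
- **Seeded synthetic-data generators** for every input: Rician decay
  signals, annular heart phantoms with focal lesions, deforming cine
  phantoms with prescribed strain, and two-group cohorts calibrated to
  reference group statistics (17 controls vs 67 patients by default).

## Worked example

```r
library(myomapr)
res <- run_pipeline(pipeline_config(seed = 11,
                                    cine = list(n_frames = 12),
                                    cohort = list(n_controls = 17,
                                                  n_patients = 67)))
print(res)
```

```
Pipeline result (seed 11)
T2 summary over 16 segments: meanT2 57.9 ms, maxT2 66.6 ms, meanSD 6.43 ms, madSD 4.32 ms
LV strain summary: GCS -26.2%, GLS NA%, peak SR circ -1.92/s, long NA/s
Combined rule (madSD + GCS):
TP 52  FP 2  TN 15  FN 15
sens 78%  spec 88%  PPV 96%  NPV 50%  acc 80%  AUC 0.90
Combined rule (madSD + GCS + LGE):
TP 23  FP 0  TN 17  FN 44
sens 34%  spec 100%  PPV 100%  NPV 28%  acc 48%  AUC 0.94
```

Reading this: the heart phantom (which carries one focal subepicardial
lesion) yields an elevated madSD of 4.3 ms — a lesion-free phantom sits
near 0.1 ms — and the tracked global circumferential strain (−26.2%)
recovers the prescribed −26% peak. On the simulated 17/67 cohort the
tree-derived madSD cut-off lands at 1.85 ms with direction "≥ abnormal",
and the combined madSD + GCS rule reaches 78% sensitivity at 88%
specificity (AUC of the matching logistic model 0.90). The rule that
additionally requires LGE positivity is perfectly specific but loses
sensitivity, because only about half the simulated patients are
LGE-positive and the generator draws parameters independently.

```r
res$cohort$model_report[, c("model", "aic", "auc")]
#>          model      aic       auc
#>  madSD+GCS+LGE 47.73547 0.9429324
#>      madSD+GCS 57.51785 0.9016681
#>          madSD 62.27609 0.8542581
#>          maxT2 78.83796 0.7559263
#>            GCS 81.41308 0.6821773
```

Lower AIC is better: adding strain (and LGE) to madSD improves the model,
and madSD alone beats maxT2 or strain alone.

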