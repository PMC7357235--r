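# radsurv

Survival-time prediction and treatment-strategy simulation for
radiotherapy cohorts, built around the analysis pattern used for
malignant glioma: predict each patient's post-radiotherapy survival
time (days) from clinical features and dose-volume histogram (DVH)
features, and then ask, patient by patient, how the prediction would
change under a different prescription dose or treatment duration.

The package is aimed at medical-physics and biostatistics researchers
who want a tested, reproducible implementation of this pipeline — and a
synthetic-cohort generator with a known ground truth, because clinical
datasets of this kind are typically private.

## What it implements

* **DVH features.** Cumulative DVH curves per target structure
  (PTV/CTV, local and extended) with D_X (minimum dose to the hottest
  X % or X cm³), V_X (volume receiving ≥ X Gy), max/min/mean dose, and
  the linear-quadratic biologically effective dose
  BED = D·(1 + d/(α/β)).
* **ε-SVR with an RBF kernel** for survival regression
  (f(x) = Σᵢ βᵢ K(xᵢ, x) + b), solved by an in-package SMO routine
  fast enough for wrapper feature selection.
* **GA feature/hyperparameter selection.** A binary chromosome encodes
  (C, ε, γ) in log-uniform bit segments plus one mask bit per feature;
  the fitness is AIC = n·ln(RSS/n) + 2(k+1) computed from leave-one-out
  residuals, so parsimonious, well-generalizing models win.
* **Model comparison** of clinical-only, DVH-only and combined feature
  groups: mean ± sd LOOCV residual error, exact paired Wilcoxon
  signed-rank tests, Kaplan–Meier curves of actual vs predicted
  survival with a log-rank test, and a median-split classification AUC.
* **What-if simulation.** Prescription dose is changed, the selected
  DVH features are recomputed from dose-rescaled curves (BED included),
  and the model re-predicts; sweeping dose × duration yields a
  per-patient treatment-strategy surface.
* **Synthetic cohorts.** Seeded generator producing clinical tables,
  per-structure DVH curves and survival times from a sparse, documented
  ground-truth model with a per-patient optimal dose.

## Worked example

```r
library(radsurv)

# a seeded 35-patient synthetic cohort with DVH curves and survival
co <- generate_cohort(cohort_config(n_patients = 35, seed = 1))
co
#> <rs_cohort> 35 patients (seed 1), median survival 443 days

# DVH metrics of one structure
cv <- co$dvh[["P001"]][["PTV_local"]]
round(c(D98 = dose_at_volume(cv, 98), D50 = dose_at_volume(cv, 50),
        V50 = volume_at_dose(cv, 50), mean = summary_doses(cv)[["mean"]]), 1)
#>  D98  D50  V50 mean
#> 44.0 60.7 82.4 58.1

# GA selection of features + SVR parameters (reduced search budget)
ds  <- as_rs_dataset(co)
cfg <- ga_config(n_features = ncol(ds$x), profile = "ci", seed = 1)
sel <- ga_select(ds, cfg)
sel
#> <ga_result> best AIC 376.489 with 7 features after 40 generations (830 evaluations)
#>   features: PTVlocal_D75cc, PTVlocal_V65pct, PTVlocal_V50cc, CTVlocal_V45pct, ...

# leave-one-out evaluation of the selected model
cvres <- loocv_predict(ds, sel$best_features, sel$best_record$params)
unlist(summarize_residuals(cvres)[c("mean", "sd")])
#>     mean       sd
#> 128.4897 116.6251

# what-if: sweep prescription dose for patient 1
model <- svr_train(ds, sel$best_features, sel$best_record$params)
surf <- dose_duration_surface(co$cohort[1, ], co$features[1, , drop = FALSE],
                              co$dvh[["P001"]], model,
                              doses = seq(30, 80, by = 10))
round(surf$predicted_days)
#> [1] 257 361 453 510 550 575
argmax_dose(surf)
#> [1] 80
```

The reduced-budget run selected seven DVH features. Because those
features are dose-linked (they rescale when the prescription changes),
the what-if sweep responds strongly to dose — for this patient the
predicted survival rises from 257 days at 30 Gy to 575 at 80 Gy, so
the model sees no benefit plateau within the sweep range. The mean
LOOCV residual error (about 128 days here) is the headline performance
index; smaller is better. With the study-faithful GA budget
(`profile = "paper"`: population 500, 1000 generations) the search is
far deeper but takes correspondingly longer.

The methods vignette (`vignettes/radsurv-methods.Rmd`) documents the
model, the fitness, every tunable with units and defaults, the
synthetic generator's ground truth, and the package's numerical
conventions.

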