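# gliomid

Parameter- and model-identifiability analysis for a family of eleven
image-based models of high-grade glioma growth and response to
chemoradiation, on fully synthetic virtual-patient cohorts.

## What it does

Patient-specific tumour forecasting needs two things to be true before any
clinical use: the model's parameters must be recoverable from realistic,
noisy longitudinal imaging, and the *right* member of a model family must be
distinguishable from its siblings. `gliomid` tests both by construction:

1. **Virtual patients.** `make_anatomy()` builds a seeded voxel brain
   (0.5 × 0.5 × 2 mm, 3 axial slices) with white/grey labels, an enhancing
   tumour core derived through a pseudo-ADC map, a non-enhancing rim at
   fixed density 0.16, an enhancement-ratio map, and the 60/50 Gy, 30-
   fraction weekday radiotherapy plan with concurrent chemotherapy
   (`make_schedule()`).
2. **Forward model.** `simulate_tumour()` integrates a two-species
   reaction–diffusion model (enhancing + non-enhancing disease, logistic
   competition) whose diffusion is damped exponentially by von Mises stress
   from a quasi-static linear-elastic solve, and applies each fraction as a
   discrete linear-quadratic survival event. Eleven variants (M1–M11) vary
   how treatment efficacy couples to space: uniform, vasculature (oxygen
   enhancement ratio), cell density, combined RT/CT terms, or no treatment.
3. **Cohorts and noise.** `generate_cohort()` samples ground-truth
   parameters per tumour, grows the truth at the five imaging visits
   (planning; weeks 1–3 of RT; 4 weeks post-RT) and attaches Gaussian
   observation noise at 5/10/15%.
4. **Calibration.** `calibrate_tumour()` fits any variant to one patient's
   noisy observations by bounded Levenberg–Marquardt least squares
   (midpoint-of-bounds start, 250-iteration cap, 0.01% parameter-change
   stop), returning a `tumour_fit` with `coef()`, `predict()`,
   `residuals()`, `logLik()` and `summary()` methods.
5. **Selection and scoring.** `aicc()` + `select_model()` pick the most
   parsimonious adequate variant; `tally_selections()` builds the
   confusion matrix; `metrics_report()` scores Dice overlap, Lin's
   concordance correlation and total-tumour-cellularity error at the
   calibration (week 3) and prediction (4 weeks post-RT) time points.
   `run_parameter_identifiability()` and `run_model_identifiability()`
   orchestrate whole experiments.

## Worked example

```r
library(gliomid)

an  <- make_anatomy(1, dims = c(16, 16, 3))
sch <- make_schedule(an)
v   <- model_variant("M3")            # RT coupled to vasculature
p   <- sample_parameters(v, seed = 7)
truth <- simulate_tumour(v, p, an, sch, c(0, 7, 14, 21, 67))
obs   <- add_noise(truth, 0.05, seed = 5)

fit <- calibrate_tumour(obs, v, an, sch)
print(fit)
#> <tumour_fit M3>  RSS = 2.68873 on 2952 points, k = 12
#>   converged after 24 iterations (param_tol)
#>             kpE             kpN             D_w             D_g            f_NE
#>        0.098750        0.048030        0.066570        0.024420        1.194000
#>         beta_NE         beta_EN         lambda1        alpha_RT alpha_RT_prolif
#>        2.000000        0.751000        1.000000        0.023390        0.008163
#>        alpha_CT      alpha_beta
#>        0.005000        5.974000

pred <- predict(fit, days = c(0, 21, 67))
m <- an$grid$brain_mask
metrics_report(pred$states[[2]], truth$states[[4]], m)
#>        dsc       ccc   pe_ttc  time_label
#> 1 0.971246 0.9974109 2.712108 calibration
```

The fitted week-3 field overlaps the ground truth almost perfectly
(Dice 0.97), agrees voxelwise (CCC 0.997) and misses total cellularity by
under 3% for this single tumour; medians across a cohort are tighter. A
full selection round (`calibrate_tumour` for all eleven variants followed
by `select_model`) identifies the generating variant M3 with a large AICc
margin.

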