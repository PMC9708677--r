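# nwuct

Quantitative admission-CT analysis for acute ischemic stroke: **net water
uptake (NWU) densitometry**, **CT-perfusion core volumetrics**, **lesion
growth**, and the statistical machinery linking low baseline NWU to
CT-perfusion core overestimation ("ghost infarct core") — together with a
synthetic phantom and cohort generator so the whole pipeline can be
validated end-to-end against known ground truth, without patient data.

## Who this is for

Stroke-imaging researchers and methodologists who want a reproducible,
tested implementation of:

* mirror-ROI densitometric NWU from non-contrast CT,
* threshold-based core/penumbra volumetrics from perfusion maps,
* the core-overestimation outcome definition and its relative-risk models,

and anyone who needs a ground-truthed digital phantom to validate such a
pipeline.

## The quantities at the core

**Net water uptake.** The ischemic lesion on admission non-contrast CT is
hypoattenuated in proportion to its ionic edema. With `D_ischemic` the mean
density (HU) of the lesion ROI and `D_normal` the mean density of the same
ROI mirrored onto the contralateral hemisphere — both restricted to the
20–80 HU parenchymal window, excluding CSF and calcification —

```
%NWU = (1 − D_ischemic / D_normal) × 100
```

**Volumetrics.** The perfusion-predicted core (pCore) is brain tissue with
relative CBF ≤ 20% of contralateral normal; hypoperfusion is Tmax ≥ 6 s;
penumbra (mismatch) is their difference. With FIV the final infarct volume
on follow-up CT,

```
lesion growth = FIV − pCore          (mL)
core overestimated  ⇔  growth < −10 mL
```

**Statistics.** Binary outcomes (overestimation; 90-day functional
independence, mRS 0–2) are modelled with log-binomial regression, whose
exponentiated coefficients are *relative risks* per unit predictor (with a
robust-Poisson fallback when the log-binomial likelihood misbehaves).
Lesion growth is modelled by OLS on its signed cube root. Univariable
screening at p < 0.05 builds the multivariable models, and a sensitivity
analysis stratifies at pCore 50 mL.

## Worked example

```r
library(nwuct)

# a ground-truthed phantom: 7.2% true water uptake, 1.5 HU noise
b <- generate_phantom(phantom_spec(true_nwu_pct = 7.2, noise_sd_hu = 1.5,
                                   seed = 11))
run_case(b, pipeline_config(seed = 11), case_id = "demo")
#> # A tibble: 1 × 16
#>   case_id nwu_pct d_ischemic d_normal pcore_ml penumbra_ml fiv_ml ...
#> 1 demo       7.17       32.5     35.0     7.10        41.0   29.7
```

The measured NWU (7.17%) recovers the generative truth (7.2%) to within
noise; `pcore_ml`, `fiv_ml` and the derived growth match the phantom's
sidecar truth exactly in the noise-free case. On the cohort side, the
simulator draws outcomes from a multiplicative-risk model so the fitted RR
is the recoverable truth:

```r
cfg <- effect_config(n_subjects = 50000, rr_nwu_per_pct = 0.94,
                     rr_pcore_per_ml = 1, rr_aspects_per_point = 1,
                     seed = 11)
co  <- simulate_cohort(cfg)
tidy(fit_rr(co, "overestimated", "nwu_pct"))
#> # A tibble: 1 × 9
#>   term    predictor estimate conf.low conf.high   p.value n_used model_tag
#> 1 nwu_pct nwu_pct      0.937    0.934     0.940 1.91e-300  50000 univariable
```

The fitted RR per %NWU (0.937) recovers the generative 0.94: each percent
of admission water uptake *lowers* the risk of core overestimation by
about 6% — the low-NWU/overestimation relationship the pipeline exists to
quantify. `run_study()` produces the full table set (descriptive,
univariable/multivariable RR tables, growth models, stratified screen) in
one call; `autoplot()` on any fit gives a forest plot, and
`plot_risk_curve()` the predicted-probability curve.

## Package tour

| Area | Functions |
|---|---|
| Phantom generation | `phantom_spec()`, `generate_phantom()`, `write_phantom()`, `read_phantom()` |
| Densitometry | `ct_volume()`, `mirror_roi()`, `roi_set()`, `filter_hu()`, `compute_nwu()` |
| Volumetrics | `perfusion_maps()`, `volume_ml()`, `compute_pcore()`, `compute_penumbra()`, `lesion_growth()`, `classify_overestimation()`, `cubic_root_transform()` |
| Cohort simulation | `effect_config()`, `simulate_cohort()`, `write_cohort()`, `read_cohort()` |
| Statistics | `fit_rr()`, `fit_linear()`, `screen_univariable()`, `build_multivariable()`, `stratified_sensitivity()`, `describe_cohort()`, `tidy()`, `glance()` |
| Pipeline | `pipeline_config()`, `run_case()`, `run_study()`, `write_study()` |
| Plots | `autoplot()`, `plot_phantom_slice()`, `plot_growth_vs_nwu()`, `plot_risk_curve()` |

See the methods vignette (`vignettes/nwu-core-overestimation.Rmd`) for the
models, their assumptions, and every numerical convention.
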