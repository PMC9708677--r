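---
title: "Net water uptake, perfusion core volumetrics and the overestimation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net water uptake, perfusion core volumetrics and the overestimation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwuct)
```

## The problem

CT perfusion (CTP) is widely used at stroke admission to estimate the
irreversibly injured "core" and the salvageable penumbra, and patients can
be excluded from endovascular treatment when the predicted core looks too
large. But threshold-based core prediction is known to *overestimate* the
final infarct, especially early after onset — the "ghost infarct core".
Net water uptake (NWU), a densitometric measure of ionic edema on plain
CT, indexes how far infarction has actually progressed: tissue that has
taken up little water may still be salvageable even when its perfusion
values cross the core threshold. The pipeline in this package quantifies
both measures, defines overestimation, and fits the models that relate
them — with a synthetic phantom and cohort generator supplying known
ground truth for every stage.

## Densitometric net water uptake

The lesion ROI on admission non-contrast CT has mean density
$D_{ischemic}$; the same ROI reflected across the midsagittal plane onto
the unaffected hemisphere has mean density $D_{normal}$. Percent net water
uptake is

$$\%NWU = \left(1 - \frac{D_{ischemic}}{D_{normal}}\right) \times 100.$$

Conventions, each chosen once and exposed as a parameter:

* **HU window 20–80, inclusive.** Voxels below 20 HU (CSF) or above 80 HU
  (calcification) are excluded from both ROIs before averaging, so the
  densities reflect parenchyma only. Bounds are inclusive; an ROI whose
  windowed sample is empty raises an error rather than averaging nothing.
* **Mirroring is a pure grid reflection** about a configured voxel plane
  (`midline_axis`, `midline_index`), the deterministic analog of manually
  placing a symmetric contralateral ROI. No registration is performed; an
  off-centre head is accommodated by moving the plane index. A mask that
  touches or crosses the plane is rejected, since its mirror would overlap
  ischemic tissue, and `mirror(mirror(mask))` is exactly `mask`.
* **Arithmetic mean** is the ROI statistic (volumetric, over all surviving
  voxels); a median mode is available since the densitometric statistic is
  a convention rather than a law, and the choice between slice-wise and
  volumetric sampling is likewise not standardised — we implement the
  volumetric form.
* **Negative NWU is returned as computed.** With noise a nearly isodense
  lesion can yield a slightly negative estimate; clipping at zero would
  bias parameter-recovery studies.

## Volumetrics and the overestimation outcome

From the perfusion maps, restricted to the brain mask:

* predicted core **pCore** = volume with relative CBF $\le$ 20% of
  contralateral normal (inclusive boundary; threshold configurable in
  (0, 100]);
* **hypoperfusion** = volume with Tmax $\ge$ 6 s. The field uses both
  "at least 6 s" and "> 6 s" phrasings; we default to inclusive and expose
  the convention as a flag;
* **penumbra** = hypoperfusion − pCore, floored at 0 with a warning if the
  core extends outside the Tmax lesion (possible with discordant maps);
* **lesion growth** = FIV − pCore, signed; **core overestimation** is
  growth strictly below −10 mL (−10.0 is *not* overestimation). The 10 mL
  margin absorbs segmentation error.

Growth is heavily right-skewed and negative in a meaningful minority, so
regression uses the **signed cube root** $\mathrm{sign}(x)|x|^{1/3}$ — the
standard odd monotone transform; an unsigned root would be undefined for
negative growth.

## The phantom generator

`generate_phantom()` builds an ellipsoidal "brain" of uniform parenchymal
density (default 35 HU) on an axial grid whose left-right extent is odd,
so the midsagittal plane is a voxel plane and reflection is exact. Inside
one hemisphere sits an ellipsoidal lesion whose density encodes the truth
exactly: lesion HU $= 35 \times (1 - NWU_{true}/100)$. To exercise the HU
window, a CSF pocket (10 HU) and a calcification speck (200 HU) are
embedded *inside* the lesion ROI, and symmetric paramedian ventricles are
placed outside it. An inner core region carries rCBF = 10%, a larger
region Tmax = 8 s, and the follow-up volume an infarct region of
configurable size, so pCore, hypoperfusion, penumbra, FIV, growth and the
overestimation flag all have voxel-count ground truth in the JSON sidecar.
Optional Gaussian HU noise is added last; it leaves the expected ROI means
unchanged.

The default grid is 61 × 73 × 61 voxels at 2 mm — small enough that a
hundred phantoms generate in seconds, large enough that the lesion ROI
holds ~2,600 voxels and ROI-mean noise cancels to well under half a
percentage point of NWU. What the phantom deliberately does **not** model:
CT texture and beam hardening, the skull (the brain window is assumed
pre-stripped, which keeps mirroring exact), partial-volume effects at
tissue boundaries, time-resolved CTP source data, hemorrhage. Passing the
phantom suite therefore validates the *estimator* — windowing, mirroring,
averaging, thresholding, unit conversion — not robustness to real-scanner
artifacts, which require real data.

## The cohort generator

`simulate_cohort()` draws patient records whose outcomes follow the
models the analysis assumes, so fitted coefficients have a recoverable
truth. Binary outcomes use a **multiplicative (log-link) risk model** —
chosen because the analysis reports relative risks, and only a log-link
binomial model has coefficients that *are* RRs:

$$P(\text{overestimated}) = \mathrm{clip}\left(p_0 \cdot
RR_{NWU}^{(NWU - 7.2)} \cdot RR_{pCore}^{(pCore - 11.9)} \cdot
RR_{ASPECTS}^{(ASPECTS - 7)},\; 0, 1\right)$$

with defaults $p_0 = 0.16$ (the overestimation rate of a typical
endovascular cohort), $RR_{NWU} = 0.94$ per %, $RR_{pCore} = 1.02$ per mL
and $RR_{ASPECTS} = 1.28$ per point; the reference values 7.2% / 11.9 mL /
7 are the covariate medians, so $p_0$ is the risk of a median patient.
Cube-root growth is linear with defaults 0.06 per %NWU, −0.33 per ASPECTS
point, −0.01 per mL pCore, −0.87 for successful reperfusion, residual SD
0.5, intercept placed so the median growth is ~18 mL. A second risk model
drives 90-day functional independence (age 0.97/yr, NIHSS 0.93/pt,
ASPECTS 1.2, reperfusion 1.61, baseline 0.25), with mRS90 missing for 25%
of subjects to exercise complete-case handling.

Covariate laws emulate admission-imaging summaries: NWU ~ exponential
(median 7.2%), pCore ~ exponential (median 11.9 mL) truncated at 100 mL,
ASPECTS ~ Binomial(10, 0.72) (median 7), age ~ truncated normal (74 ± 12),
NIHSS ~ rounded normal (15 ± 6), log-normal workflow times, reperfusion
(eTICI 2c/3) probability 0.49. The pCore truncation reflects that very
large cores rarely reach endovascular treatment, and it keeps the
unbounded log-link risk inside [0, 1] over essentially the whole support —
a requirement for the generative RR to be exactly recoverable. Clipping is
counted and warned about whenever it touches more than 1% of subjects;
with the good-outcome defaults a few percent of young, mildly affected
subjects do clip, which is an inherent property of log-link risk models
with published effect sizes over wide covariate ranges, and is reported
rather than hidden.

**Coupled versus independent outcomes.** In reality the overestimation
flag is a function of the same FIV that defines growth; the analysis-level
joint law is not standardised, so the simulator exposes both modes. By
default (`consistency = FALSE`) the flag and growth are drawn
independently from their respective models — each marginally faithful, but
the flag is not `growth < −10`. With `consistency = TRUE` the flag is
drawn first and growth is sampled from the cube-root normal *truncated* to
the matching interval, computed in log-probability space because the two
models are independent and the interval can sit many standard deviations
into a tail; a flagged subject additionally requires pCore > 10 mL, since
FIV ≥ 0 makes overestimation by more than 10 mL impossible below that.
Reconstructed FIV = pCore + growth is floored at zero.

## Regression machinery

* `fit_rr()` fits the binomial GLM with log link (start: log of the
  outcome rate, zero slopes). If the IRLS fit errors or fails to converge
  — common near the boundary where fitted risks approach 1 — it falls back
  to modified Poisson regression with HC0 sandwich variance, a standard
  consistent RR estimator, and flags `fallback = TRUE` in the output. An
  odds-ratio mode exists for comparison; ORs overstate RRs at these
  outcome rates, which is precisely why the log link is the primary model.
* `fit_linear()` is OLS on the transformed response with t-based CIs.
* `screen_univariable()` then `build_multivariable()` implement the
  univariable-to-multivariable convention: predictors with univariable
  p < 0.05 enter the adjusted model, plus forced adjustments (sex, for the
  functional-outcome model). No multiple-testing correction is applied, by
  design, matching the convention of this analysis style.
* `stratified_sensitivity()` repeats the screen within pCore < 50 mL and
  ≥ 50 mL strata (upper stratum inclusive; 50 mL mirrors trial inclusion
  boundaries).
* `describe_cohort()` chooses mean (SD) versus median (IQR) by
  Shapiro–Wilk at 0.05 (on at most 5000 sampled values, the test's
  domain), compares groups by Wilcoxon rank-sum for continuous variables,
  reports n (%) for categorical ones, and reports per-variable n wherever
  values are missing. All model fits are complete-case per model, with
  `n_used` in every output row.

## Problem sizes and tolerances

The validation suite uses sizes chosen to make Monte-Carlo error small
relative to the effect being recovered: 50,000 subjects for RR recovery
(SE of the fitted log-RR ≲ 0.004, against generative effects 0.90–1.28),
10,000 for the growth slope (SE ≈ 0.0007 against slope 0.06), 100 noisy
phantoms at noise SD 2 HU for NWU recovery (ROI-mean noise ≈ 0.04 HU, so
mean absolute NWU error sits near 0.1 against a 0.5-point band), and a
200-subject fixture where the log-binomial fit is checked against an
independent brute-force maximum-likelihood optimisation to three decimals.
Everything stochastic is seeded; identical spec/config + seed gives
bit-identical output.

## Known limitations

* The phantom validates estimator correctness, not robustness to scanner
  physics; mirroring assumes a symmetric, pre-stripped head.
* The log-binomial likelihood is genuinely awkward near the boundary;
  multivariable fits on strongly clipped cohorts will often take the
  (well-behaved, flagged) robust-Poisson path, whose point estimates are
  consistent but whose CIs are sandwich-based rather than likelihood-based.
* Under the default independent outcome mode, adjusted multivariable RRs
  on fully loaded cohorts are mildly attenuated wherever risk clipping
  occurs; single-effect recovery, which is what the validation targets,
  is unaffected.
* Wald CIs are used throughout for RRs; other software may report
  profile-likelihood intervals that differ slightly in small samples.
* No imputation, propensity adjustment, or ordinal outcome modelling —
  complete-case analysis mirrors the per-variable-n reporting convention.
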