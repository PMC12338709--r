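---
title: "How segmentation variability propagates into MRS concentrations"
author: "mrsq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How segmentation variability propagates into MRS concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsq)
```

## The quantification model

Water-referenced single-voxel MRS estimates a molar metabolite
concentration from the ratio of the fitted metabolite amplitude $S_M$ to
the unsuppressed water amplitude $S_{H_2O}$. Because the acquisition
voxel (a cm-scale box, here 3×3×3 cm³) mixes gray matter, white matter
and CSF — compartments with different water content and relaxation — the
ratio must be corrected for voxel composition:

$$
[M] \;=\; \frac{S_M}{S_{H_2O}}\;
\frac{f_{GM} d_{GM} R_{GM} + f_{WM} d_{WM} R_{WM} + f_{CSF} d_{CSF} R_{CSF}}
     {(1 - f_{CSF})\, R_M}\;[H_2O]
$$

with fractional volumes $f_x$ summing to 1, relative water densities
$d_{GM} = 0.78$, $d_{WM} = 0.65$, $d_{CSF} = 0.97$, pure-water molarity
$[H_2O] = 55.51$ mol/L, and attenuation factors
$R = e^{-TE/T_2}\,(1 - e^{-TR/T_1})$ for each water compartment and for
the metabolite. The $(1 - f_{CSF})$ denominator excludes CSF from the
metabolite-bearing volume — which is why the CSF fraction has an outsized
influence: it enters both the water-signal composition and the volume
normalization, and CSF relaxation differs far more from parenchyma than
GM and WM differ from each other. `csfSensitivity()` exposes
$\partial [M] / \partial f_{CSF}$ (closed form and finite difference) to
make that leverage quantitative.

Assumptions worth stating plainly:

* **Proton counts are upstream.** The number of protons per metabolite is
  assumed absorbed into $S_M$ by the fitting basis set; no proton-count
  division is applied here.
* **No tissue-specific metabolite concentrations or relaxation.** $R_M$
  is a single factor averaged over GM and WM. Tissue-resolved metabolite
  corrections exist but are deliberately out of scope.
* **Exponential relaxation model.** The specific form
  $e^{-TE/T_2}(1-e^{-TR/T_1})$ is the standard saturation-recovery /
  echo-decay expression; all $T_1/T_2$ values live in `QuantConfig` and
  can be replaced wholesale, so a variant model can be emulated by
  supplying effective relaxation times.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| TE / TR | 35 / 2000 | ms | common 3 T sLASER protocol |
| $d_{GM}, d_{WM}, d_{CSF}$ | 0.78 / 0.65 / 0.97 | — | literature water densities |
| water $T_1$ (GM/WM/CSF) | 1.331 / 0.832 / 4.163 | s | 3 T literature values |
| water $T_2$ (GM/WM/CSF) | 0.110 / 0.0799 / 0.503 | s | 3 T literature values |
| tCr $T_1$, $T_2$ | 1.35, 0.166 | s | GM/WM-averaged literature values |
| $[H_2O]$ | 55.51 | mol/L | pure water |

The relaxation defaults are representative literature substitutes, not
measurements from any particular cohort; studies with their own values
should supply them through `quantConfig()` or a JSON/YAML config
(`inst/extdata/quant_config.json` shows the schema). TE/TR are accepted
in milliseconds (`teMS`) or seconds (`teS`) with explicit, mutually
exclusive argument names — a deliberate guard against the classic
unit-mix bug.

One numerical policy deserves emphasis: compositions printed to two
decimals (e.g. 0.43/0.30/0.26, which sums to 0.99) are accepted *as
printed* by `correctionFactor()` and `molarConcentration()` (row-sum
tolerance 0.02, no silent rescaling). Rescaling rounded literature values
changes the correction by about 1%, which matters when the quantity of
interest is itself a few percent.

## Voxel-mask extraction

`buildVoxelMask()` computes, for every image voxel on the *native* grid
of the probability maps (never resampled), the fraction of its volume
inside the possibly oblique MRS box, by testing `supersample`³ regularly
spaced subpoints per voxel. Coordinates are world mm (RAS), with the
affine taken verbatim from the NIfTI header and 0-based voxel indices.
`extractFractions()` then takes weighted mean probabilities and
normalizes them to sum to one.

Design choices made here, where the field's pipelines genuinely differ:

* **Partial-volume weighting, not binary masking.** A nearest-center
  binary mask has an O(voxel/edge) bias that does not shrink; subvoxel
  supersampling bounds the quadrature error by roughly
  (voxel size / box edge) / supersample per face, which the tests verify
  against analytic phantoms. Default supersample = 3; 5 brings fraction
  errors below 0.01 for 2 mm maps and a 30 mm voxel.
* **Failure over rescaling.** If the probabilities inside the mask sum to
  less than 0.5 of the mask weight, the voxel is mostly non-brain and
  normalization would amplify noise; `extractFractions()` refuses
  ("insufficient brain coverage"), as does `normalizeFractions()` below a
  pre-normalization sum of 0.5 ("degenerate fractions").
* **No inter-session registration.** Each session's maps and geometry
  are taken as co-registered by the upstream pipeline.

## The statistical battery

The test–retest design (participant × 2 sessions × 3 methods, complete
and balanced) is analyzed with the model
`response ~ Method * Session + (1 | participant)`. For this balanced
design the mixed model *is* the classical repeated-measures ANOVA, so
`methodSessionModel()` computes it in closed form: every fixed effect is
tested against the pooled within-participant error stratum with
$(n-1)(\text{cells}-1)$ denominator degrees of freedom — F(2, 60) at
n = 13 — all derived from the design, never hard-coded. Estimated
marginal means combine the participant and residual variance components,
$SE^2 = \sigma^2_p/n + \sigma^2_e/(n\,l)$, with containment df $(n-1)$
for their CIs; Tukey HSD contrasts are within-participant, so their SE
uses the residual stratum only, with studentized-range adjustment.
Incomplete designs are rejected outright rather than approximated by
REML: deterministic, closed-form, and checkable against an independent
OLS/aov oracle to 1e-8, which the test suite does on random fixtures
(and cross-checks against `nlme::lme` + `emmeans`).

Supporting tests delegate to `stats`: Shapiro–Wilk screens (Bonferroni
over the groups tested), paired session t-tests (Bonferroni factor 3 by
default — the three quality metrics typically screened), Pearson
correlations of age with the CSF-independent normalized GM fraction
$f_{GM}/(f_{GM}+f_{WM})$ and with concentration. Steiger's Z for
comparing two dependent correlations sharing a variable is implemented
directly (no installed package provides it): the Fisher-z difference is
scaled by the asymptotic SE using the pooled correlation in the
covariance term, giving an antisymmetric statistic with a two-sided
normal p-value. Its frozen reference value and a Monte-Carlo calibration
check live in the test suite.

Percent differences use the symmetric pair-mean denominator
$100\,|a-b| / \tfrac{a+b}{2}$, reported as per-participant mean ± SD;
because summaries in the field are ambiguous about averaging order, the
group-level variant (percent difference of the two method means) is
reported alongside. Magnitudes are the default; a `signed` flag keeps
direction.

## What the synthetic study emulates — and what it does not

`simulateStudy()` generates the cohort the analysis assumes: 13
participants aged 19–66, two sessions, three methods with mean
compositions ANTs (0.45, 0.33, 0.22), FSL (0.43, 0.30, 0.26) and
SPM (0.56, 0.27, 0.17) (renormalized onto the simplex). Each participant
gets a latent anatomical deviation shared across methods and sessions,
built from two zero-sum axes: a GM↔WM exchange tied to age (targeting
r ≈ −0.7 between age and normalized GM, the well-replicated atrophy
trend) and an independent CSF↔parenchyma axis. Rows add small
per-row noise and renormalize. Session has no systematic effect by
construction (an optional offset exists for power studies). The
between-participant SD (0.03) and per-row SD (0.01) are back-derived
from the reported 95% CIs of method means at n = 13 — approximations,
since the underlying SDs are not published.

Signals come from the *forward* model. Two bases exist, and the
distinction is the crux of the design:

* `signalBasis = "shared"` (default): one signal pair per
  participant × session, generated from a method-independent reference
  composition — because the acquisition is one physical measurement, and
  segmentation methods only change the correction applied afterwards.
  Between-method concentration differences then arise *purely* from the
  correction-factor ratio, the propagation mechanism under study: with
  the default compositions this reproduces method means near
  7.2 / 7.6 / 6.9 mM from a single 7.2 mM truth.
* `signalBasis = "per_row"`: each row's own fractions generate its
  signal, so quantification recovers the true concentration exactly at
  zero noise — the round-trip identity used to validate the algebra.

A consequence of the shared basis worth knowing: the shared
per-participant×session signal noise forms a random stratum that the
pooled-error model does not separate, so under a true null the Session F
is anti-conservative and the Method F conservative. This mirrors the
structure of real shared-acquisition data analyzed with a
participant-intercept-only model; it is why the type-I calibration of
the Method test is assessed under the exchangeable (`per_row`) mode,
where the test's iid assumption holds exactly, while power against the
reported between-method differences is assessed under the realistic
shared mode.

What the generator does **not** emulate: spectra, lineshapes, SNR or
fitting (signals are amplitudes by construction), spatially structured
segmentation errors, scanner drift, repositioning error between
sessions, or pathology. Passing tests therefore demonstrate that the
*pipeline* is correct and well-calibrated under its stated model — not
that any particular segmentation tool is accurate on real anatomy.

`generatePhantomMaps()` serves the geometric half of validation: planar
GM/WM interfaces (optionally smoothed) and CSF slabs on a world-centered
grid, with closed-form fractions for axis-aligned boxes and, by
symmetry, for any rotated box centered on the interface — the oracle for
oblique-voxel extraction.

## Numerical choices and degenerate inputs

* Probabilities outside [0, 1] by more than 1e-3 are an error; smaller
  excursions (interpolation spill) are clamped.
* Boxes that miss the field of view, pure-CSF voxels
  ($f_{CSF} \ge 1 - 10^{-9}$), nonpositive water signals, zero-variance
  paired differences, constant Shapiro groups, and unbalanced designs
  all fail loudly with named errors rather than returning approximate
  answers.
* Problem sizes in the validation suite: forward/inverse round trips at
  1e3 random draws (rel. 1e-10); oracle equivalence on 20 random
  balanced fixtures of 3–13 participants (1e-8); Method-test null
  calibration over 1e3 replicates and power over 200 replicates at
  n = 13; phantom geometry at supersample 5 (abs. 0.01). These sizes
  keep each property estimate's Monte-Carlo error well inside its
  acceptance band.
* Determinism: a fixed seed gives byte-identical study CSVs and report
  markdown; the CLI embeds config hashes and the seed in its outputs.

## Known limitations

* The balanced-only mixed model is a feature (exactness) and a
  constraint: dropouts require re-balancing upstream.
* Relaxation defaults are literature substitutes; concentrations shift
  systematically with these choices, though between-method *differences*
  are far less sensitive.
* Steiger's Z is asymptotic; at n = 13 its normal approximation is
  rough, which is visible in the wide Monte-Carlo bands the tests use.
* The age–concentration slope is off by default; enabling it makes true
  concentration a confounder of the age–GM association, as in real
  cohorts — intentional, but worth remembering when interpreting
  recovered correlations.
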