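# mrsq

Segmentation-aware quantification for single-voxel brain MR spectroscopy
(MRS), in R.

## The problem

Converting an MRS metabolite signal into an "absolute" molar concentration
requires a water reference and a correction for the tissue composition of
the acquisition voxel: gray matter (GM), white matter (WM) and CSF differ
in water content and in water relaxation, and CSF carries essentially no
metabolite signal. The GM/WM/CSF fractions come from segmenting an
anatomical image — and different segmentation tools (ANTs, FSL, SPM)
disagree enough that the *same* spectrum yields measurably different
concentrations depending only on which segmentation fed the correction.

`mrsq` implements the full propagation analysis for this problem:

1. **Voxel anatomy** — build the MRS voxel mask on the native grid of
   NIfTI tissue-probability maps (supersampled partial-volume weighting,
   oblique voxels supported) and extract normalized fractions
   f_GM, f_WM, f_CSF.
2. **Quantification** — the water-referenced tissue-and-relaxation
   correction

   ```
   [M] = (S_M / S_H2O) ·
         (f_GM d_GM R_GM + f_WM d_WM R_WM + f_CSF d_CSF R_CSF) /
         ((1 − f_CSF) · R_M) · [H2O]
   ```

   with compartment water densities d = (0.78, 0.65, 0.97), pure-water
   molarity 55.51 mol/L, and exponential relaxation attenuation
   R = exp(−TE/T2)·(1 − exp(−TR/T1)); plus the exact forward (generative)
   inverse used for simulation.
3. **Comparison & inference** — within-session and between-method percent
   differences, CSF-fraction sensitivity, the balanced repeated-measures
   Method × Session model with participant random intercepts (F tests on
   the within-participant error stratum, estimated marginal means with
   95% CIs, Tukey HSD contrasts), Shapiro–Wilk screens, paired session
   t-tests, Pearson age associations and Steiger's Z for dependent
   correlations.
4. **Synthetic study generator** — a test–retest cohort
   (n participants × 2 sessions × 3 methods) with method-specific mean
   compositions, shared participant anatomy, an age-linked normalized-GM
   decline, and signals generated through the forward model, so every
   stage of the pipeline can be validated against known truth. 3-D
   probability-map phantoms with analytically known fractions validate
   the voxel-mask geometry.

## Worked example

```r
library(mrsq)

config <- defaultQuantConfig()          # TE/TR 35/2000 ms, 3 T relaxation
att    <- attenuationFactors(config, "tCr")

# how much does the correction differ between two mean voxel compositions?
cfFSL <- correctionFactor(c(0.43, 0.30, 0.26), att, config)  # FSL-like
cfSPM <- correctionFactor(c(0.56, 0.27, 0.17), att, config)  # SPM-like
c(cfFSL, cfSPM)
#> [1] 0.5323133 0.4924531
percentDifference(cfFSL, cfSPM)
#> [1] 7.775681

# full synthetic study: simulate, quantify, analyze
study <- quantifyStudy(simulateStudy(seed = 42), config)
fit   <- methodSessionModel(study, "conc_mM")
fit
#> MethodSessionFit for 'conc_mM': 13 participants x 3 methods x 2 sessions
#>            term df_num df_den        F         p
#>          Method      2     60 169.6580 2.019e-25
#>         Session      1     60   0.7004 4.060e-01
#>  Method:Session      2     60   0.5901 5.575e-01
tukeyPairwise(fit)
#>         pair   estimate         se df    t_ratio   p_adjusted
#> 1 ANTs - FSL -0.3867225 0.03810649 60 -10.148467 1.994949e-11
#> 2 ANTs - SPM  0.3139612 0.03810649 60   8.239046 7.737089e-11
#> 3  FSL - SPM  0.7006836 0.03810649 60  18.387513 1.988842e-11
```

The 7.8% correction-factor difference is how far the FSL- and SPM-style
compositions pull an identical spectrum apart; in the simulated cohort the
same mechanism produces a strong Method effect (F(2,60) ≈ 170) with
session and interaction at their nulls, and FSL − SPM contrasts of
~0.7 mM on a ~7.2 mM metabolite — roughly a 9–10% spread from
segmentation choice alone.

A command-line wrapper covers the same workflow stage by stage:

```sh
Rscript inst/scripts/mrsq simulate --seed 1 --out-dir run
Rscript inst/scripts/mrsq quantify --in run/study.csv --out-dir run
Rscript inst/scripts/mrsq compare  --in run/study_quantified.csv --out-dir run
Rscript inst/scripts/mrsq report   --in run/stats.json --out-dir run
```

plus `fractions` for extracting voxel compositions from NIfTI
probability maps and a geometry config.

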