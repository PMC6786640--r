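# proteoclock

Elastic-net "proteomic clocks" for presymptomatic tumor detection from CSF
peak-intensity profiles.

## The problem

In the ENU rat glioma model, a single prenatal carcinogen exposure commits
animals to brain tumors months before anything is visible on MRI. The CSF
proteome of a healthy animal changes with age in a reproducible, *clocked*
way; tumor-destined animals follow a different chronology. `proteoclock`
learns both chronologies and scores each animal by which clock it follows —
a readout of tumor commitment available from the first sampling age.

The package is for analysts working with cross-sectional two-group omics
cohorts (samples × feature intensity matrix plus group/age metadata) who
want a tested, reproducible implementation of the clock-deviation analysis,
including its permutation-based error control and a synthetic cohort
generator for validation.

## The method

For each cohort (control → *normal clock*, exposed → *tumor clock*) an
elastic-net regression of sampling age `Y` on standardized peak intensities
`X` minimizes

    L(β) = |Y − Xβ|² + γ₁|β|₁ + γ₂|β|₂²

with `(γ₁, γ₂)` chosen by age-stratified cross-validation. Each sample is
then placed at the 2D coordinates
`(d_normal, d_tumor)` — its absolute age-prediction error in days under each
clock — and scored by

    ΔPr = d_normal − d_tumor

(the Bayesian posterior-difference surrogate; large positive = tumor-like).
The pipeline evaluates ΔPr per timepoint by rank-based AUC, estimates a
global permutation FDR for the within/cross-cohort R² difference, and tracks
the Shannon-entropy kinetics of each clock's residuals by group and age.

## Worked example

The bundled generator emulates the study design (60 control / 64 exposed
rats sampled at days 30–150, 247 anonymous m/Z peaks, 40 age-trending
features of which 35 diverge between groups):

```r
library(proteoclock)
report <- run_full_analysis(run_config(seed = 1, n_perm = 200))
print(report)
```

```
proteoclock run report

R^2 matrix:
             own_train own_test cross_group
normal_clock     0.992    0.975       0.061
tumor_clock      0.989    0.937       0.379

Per-timepoint AUC of delta_pr:
  stratum auc n_positive n_negative
1      30   1         13         11
2      60   1         16         16
3      90   1         22         23
4 120/150   1         13         10

permutation FDR: observed R^2 difference = 0.833
  null diffs: n = 200, median = 0.007, max = 0.265
  FDR = 0 (fraction of null > observed)
```

Reading the numbers: each clock dates its own cohort accurately (own-test
R² 0.98 / 0.94) but degrades sharply when cross-applied to the other group
(0.06 / 0.38) — the groups follow different chronologies. ΔPr separates
tumor-destined from control animals perfectly at every timepoint on this
synthetic cohort, including day 30 when no lesion exists. None of 200
label-permuted replicates reproduces the observed R² gap (FDR = 0), and

```r
class_priors(report$dataset)
#> class priors: Pr(normal) = 60/124 = 0.48, Pr(tumor) = 64/124 = 0.52
```

Individual stages are available as plain functions (`generate_dataset()`,
`split_cohort()`, `fit_clock()`, `predict_ages()`, `deviation_points()`,
`evaluate_2d_predictor()`, `permutation_fdr()`, `entropy_profile()`,
`compare_clocks()`, `per_feature_tests()`), and a thin command-line wrapper
with subcommands (`simulate`, `validate`, `fit`, `deviate`, `fdr`,
`entropy`, `features`, `run`) ships at `inst/cli/proteoclock.R`. Real
datasets are read from delimited text with a configurable column layout
(`read_dataset()`, `layout_config()`).

See `vignettes/proteomic-clocks.Rmd` for the model, the generator's design
assumptions, and numerical choices.

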