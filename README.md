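# tpmaquant

Quantitative analysis of transient peri-ictal perfusion MRI abnormalities
(TPMA) from dynamic susceptibility contrast (DSC) MRI.

## What it does, and for whom

Seizures transiently redistribute cerebral blood flow: cortex involved in
ongoing seizure activity — and characteristically the thalamus — is
hyperperfused, while postictal perfusion is normal or reduced. Clinically
these patterns are read visually from colour-coded perfusion maps, which
is reader-dependent at the lobe level. `tpmaquant` gives neuroimaging
researchers a reproducible, fully scripted alternative:

1. **Perfusion quantification** — converts a 4D DSC series into the six
   standard maps (rCBF, rCBV, MTT, TTP, tMIP, Tmax) via automated
   gamma-variate AIF selection and block-circulant truncated-SVD
   deconvolution.
2. **Registration** — rigidly aligns the tMIP map to the anatomical image
   (6 DOF, mutual-information cost) and pulls a cortical parcellation
   (32 parcels per hemisphere plus subcortical structures) into perfusion
   space through the inverse transform.
3. **Region statistics** — per-ROI means, intra-individual z-scores
   against total cortical grey matter,

   z_roi = (mu_roi − mu_GM) / sigma_GM,

   and left/right asymmetry indices of paired regions,

   AI = (lh − rh) / (lh + rh)  ∈ [−1, +1],

   which is 0 for symmetric regions and positive when left perfusion is
   higher.
4. **Group analysis** — Wilcoxon rank-sum comparisons of regional rCBF
   between ictal and postictal cohorts, thalamic z-score sign counts,
   categorical perfusion proportions and chi-square independence tests.
5. **Rater concordance** — Cohen's kappa between raters at subject and
   region level, per-category (positive specific) agreement, and the
   comparison of quantitative asymmetry to consensus visual
   lateralization.
6. **Synthetic cohort** — a parcellated head phantom with ground-truth
   perfusion, simulated bolus passage, adjustable ictal/postictal effects
   and noisy simulated raters, so the full pipeline is testable without
   patient data.

## Worked example

Simulate the default cohort (10 ictal subjects with bilateral thalamic
CBF × 1.3 and a left temporal focus × 1.5; 17 postictal subjects with
thalamic CBF × 0.85; 5% measurement noise; two simulated raters with 10%
error) and run the cohort analysis:

```r
library(tpmaquant)
cfg <- run_config(out_dir = "tpma_demo", seed = 3)
rep <- run_cohort(cfg)
rep$comparisons
#>         region   U           p direction n_ictal n_postictal
#> 1      frontal  66 0.352952096 postictal      10          17
#> 2       insula  62 0.258595491 postictal      10          17
#> 3    occipital  65 0.327536467 postictal      10          17
#> 4     parietal  65 0.327536467 postictal      10          17
#> 5     temporal  80 0.821245442 postictal      10          17
#> 6     thalamus 151 0.001006399     ictal      10          17
#> 7 whole_cortex  70 0.466589195 postictal      10          17
```

The thalamus separates the cohorts (U = 151, p = 0.001, higher in the
ictal group) while individual lobes do not — the injected effect is
bilateral thalamic, and the cortical focus is diluted at lobe level.
Thalamic z-score sign counts show the same picture per subject:

```r
rep$sign_counts
#>      cohort  side n_pos n_neg n_zero  n prop_pos prop_neg
#> 1     ictal  left    10     0      0 10        1        0
#> 2     ictal right    10     0      0 10        1        0
#> 3 postictal  left     0    17      0 17        0        1
#> 4 postictal right     0    17      0 17        0        1
```

Every ictal subject has positive (hyperperfusion) and every postictal
subject negative (hypoperfusion) intra-individual thalamic z-scores. A
markdown report and CSV tables are written to `tpma_demo/`.

Single-subject image processing works the same way through
`run_subject()`, which writes the six perfusion maps as NIfTI plus the
ROI/z-score/asymmetry tables, or via the individual functions
(`make_label_phantom()`, `simulate_dsc()`, `select_aif()`,
`compute_maps()`, `rigid_register()`, `resample_labels()`,
`roi_statistics()`, ...). A thin command-line front end with subcommands
(`phantom`, `quantify`, `cohort`, ...) is at `inst/cli/tpmaquant.R`.

The transform text format written by `write_transform()` is a plain 4×4
row-major world-space matrix (FSL `.mat`-style layout), readable with
`read_transform()`.

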