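Package: tpmaquant
Title: Quantitative Analysis of Transient Peri-Ictal Perfusion MRI Abnormalities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify transient peri-ictal perfusion abnormalities
    (TPMA) from dynamic susceptibility contrast (DSC) MRI. Converts a 4D DSC
    series into the six standard perfusion maps (rCBF, rCBV, MTT, TTP, tMIP,
    Tmax) via automated arterial input function selection and block-circulant
    truncated-SVD deconvolution, rigidly aligns perfusion and anatomical
    spaces with a mutual-information cost, propagates a cortical parcellation
    into perfusion space, and derives region-wise statistics:
    intra-individual z-scores against total cortical grey matter and
    left/right asymmetry indices. Cohort-level utilities cover rank-sum group
    comparisons between ictal and postictal states, thalamic z-score sign
    counts, categorical perfusion proportions, chi-square independence tests,
    Cohen's kappa inter-rater agreement, and the comparison of quantitative
    asymmetry to consensus visual ratings. A synthetic parcellated head
    phantom with ground-truth perfusion, simulated bolus passage and noisy
    simulated raters makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
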