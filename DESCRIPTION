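Package: retinocf
Title: Diffusion Visual Counterfactuals for Retinal Image Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for generating and evaluating visual
    counterfactual explanations of retinal disease classifiers. Provides a
    synthetic phantom generator for fundus-like and OCT-B-scan-like images
    with ground-truth lesion annotations, a denoising diffusion probabilistic
    model (DDPM) with epsilon-prediction training and guided reverse sampling,
    plain and adversarially robust (TRADES) classifiers with projected
    gradient attacks, diffusion visual counterfactuals (DVC) driven by
    cone-projected classifier gradients with distance regularization, a
    sparse Frank-Wolfe counterfactual baseline (SVC), pipeline-level
    evaluation (selection filtering, flip-rate sweeps, lesion-count deltas),
    and statistics for odd-one-out expert studies (Wilson intervals, odds
    ratios, logistic regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
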