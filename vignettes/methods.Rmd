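---
title: "Guided-diffusion counterfactuals for retinal phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided-diffusion counterfactuals for retinal phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`retinocf` is a desk-scale laboratory for *visual counterfactual
explanations* of retinal disease classifiers. A counterfactual of a fundus
image answers "what would this patient's retina look like if their disease
grade were different?" — the image should change class with high classifier
confidence, look realistic, and preserve everything that identifies the
subject (vessel tree, optic disc position, overall tint). The package
implements the full pipeline on synthetic phantoms with known ground truth,
so every claim about the method can be tested mechanically rather than by
expert inspection.

## The phantom generator: what it emulates and what it does not

Real fundus photograph collections for diabetic retinopathy (DR) grading
carry five ordinal grades (healthy, mild, moderate, severe, proliferative);
OCT B-scan collections carry four classes (normal, CNV, drusen, DME). The
generator reproduces this class structure with controllable, known lesions:

* **Fundus** (RGB): a circular field of view with radial shading, an optic
  disc, and a vessel tree drawn as a seeded branching random walk anchored
  at the disc. The vessel tree and disc position depend only on
  `subject_id`, giving every subject a stable identity across grades and
  seeds — exactly the structure a counterfactual must preserve. Lesions are
  stamped on top: dark microaneurysm dots, larger dark hemorrhage blobs,
  bright yellow exudates. Counts are Poisson draws whose means grow with
  grade (diseased grades always render at least one microaneurysm, so
  disease presence is never ambiguous); placements are rejection-sampled to
  keep lesions disjoint, which makes mask components equal counts under
  8-connectivity.
* **OCT** (grayscale): stacked retinal bands with smooth subject-specific
  elevation curves and a bright RPE band. Drusen raise the RPE boundary in
  dome-shaped deposits, DME carves dark intraretinal cavities, CNV grows a
  subretinal membrane below a locally lifted RPE.

Lesion types occupy disjoint intensity signatures (e.g. lesion dots are
darker in the green channel than vessels; drusen deposits are brighter than
the RPE band). This is a deliberate design choice: it lets a fixed-threshold
blob detector — the *lesion oracle* — recover the ground-truth counts
exactly on generator output, so lesion-level claims about counterfactuals
("lesions were added", "lesions were removed") become countable. The oracle
is calibrated on the renderer and verified to reproduce ground truth on at
least 99% of a 500-image sample in the test suite.

What the phantoms do **not** emulate: camera and illumination variation,
anatomical diversity beyond the seeded geometry, lesion appearance beyond
simple blobs, OCT speckle statistics. Passing the test suite therefore
demonstrates that the *algorithms* behave as intended on images with the
right class structure and identity structure; it does not certify
performance on clinical images.

Default generator parameters (lesion-count means per grade, lesion radii,
colour palette, boundary-curve amplitudes) are fixed in
`fundus_count_means()` and `phantom_palette()`. They were chosen once for
qualitative plausibility at 32–64 px — mild means one or two
microaneurysms, moderate adds hemorrhages and exudates, severe and
proliferative add many — and are exposed as configuration, not re-tuned per
experiment.

## Diffusion model

The generative backbone is a standard denoising diffusion probabilistic
model. The forward process corrupts an image with Gaussian noise of
increasing strength over `T` steps under a linear variance schedule
`beta_t`; its closed-form marginal is
`x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`. A network is
trained to predict the noise `eps` from `(x_t, t)` by minimising mean
squared error over uniformly drawn steps; reverse (ancestral) sampling then
walks `t = T, ..., 1` with transition mean
`mu_theta = (x_t - beta_t/sqrt(1-alpha_bar_t) eps_hat)/sqrt(alpha_t)` and
the forward-posterior variance `beta_tilde_t` (no noise at `t = 1`).

Desk-scale choices, and why:

* **Value range**: diffusion operates on `[-1, 1]`; images convert to and
  from `[0, 1]` at the module boundary. Standard practice, and it keeps the
  noise scale symmetric around zero.
* **Schedule**: the reference schedule is 1000 steps with
  `beta` in `(1e-4, 0.02)`. The shipped default uses fewer steps
  (`T = 250`, or 200 in the experiment scripts) with both endpoints scaled
  by `1000/T`, which preserves the terminal signal level
  `alpha_bar_T < 0.01`, so `x_T` is indistinguishable from pure noise under
  any shipped schedule.
* **Denoiser architecture**: a full-resolution stack of three 3x3
  convolutions (SiLU activations) with the sinusoidal time embedding
  broadcast as constant input channels, plus an analytic skip term
  `sqrt(1 - alpha_bar_t) x_t` — the exact conditional mean of the noise
  under a standard-normal image prior — so the network only learns a local
  correction. Noise prediction is essentially local once the global scale
  is handled by the skip, and a dense alternative (`arch = "mlp"`) is kept
  for comparison: in our experiments it reconstructs half-noised images
  about three times worse (median reconstruction distance ~28 vs ~11 on
  the `[0, 1]` scale at 32 px), which destroys subject identity in
  counterfactuals. Reverse-step variance is fixed to the posterior
  `beta_tilde_t`; a learned-variance head is deliberately out of scope at
  this scale.
* **Training**: Adam at 1e-3, batch 16, about 2000 minibatch iterations at
  32 px. This is the desk-scale stand-in for the reference setting of
  300,000 iterations on GPU hardware.

## Classifiers: plain, robust, and why both

The referable-DR task groups healthy and mild against moderate-and-worse
(disease onset at the moderate grade). The classifier is a small
convolutional network — three 3x3 convolution blocks with 2x2 mean pooling,
global average pooling, and a linear head. Weight sharing matters here:
counting small dark dots is translation-invariant, and a dense network of
similar size plateaus around 77% test accuracy by memorising subject
identity, while the convolutional model reaches about 95%.

Optimisation: Adam (3e-3) under a cosine learning-rate schedule, 35 epochs.
SGD with momentum — the textbook recipe for large residual networks — is
available behind `optimizer = "sgd"`, but at this scale the
global-average-pool head scales conv-layer gradients down so strongly that
SGD stalls in a majority-class plateau for any learning rate we tried;
Adam's per-parameter scaling escapes it.

The adversarially robust classifier is trained with the TRADES objective:
cross-entropy on clean images plus `beta` times the KL divergence between
predictions on clean and adversarially perturbed images, the perturbation
being an inner PGD maximisation of that KL inside an l2 ball of radius
`eps`. Two desk-scale facts shaped the defaults:

* **Warm start.** From a random initialisation the KL term dominates before
  the network has any class-discriminating features and training falls into
  a constant-prediction minimum it never leaves. Initialising from the
  trained plain model (`init = plain`) — the small-scale analogue of
  starting from a robustly pre-trained backbone — avoids this.
* **The radius must respect the class geometry.** A single microaneurysm
  is an l2 change of roughly 1.0 on the `[0, 1]` scale at 32 px, so at
  `eps >= 1` the ball crosses the class boundary for borderline images and
  *no* classifier can be robust: TRADES correctly collapses to constancy.
  The shipped radius (`eps = 0.5`) stays below lesion scale; the robust
  model gives up clean balanced accuracy relative to the plain model, as
  robust models do at full scale, and gains a modest margin in accuracy
  under PGD attack. A *large* robustness gap is not achievable here: the
  small convolutional plain model is itself substantially PGD-robust at
  these radii (smooth activations, global average pooling, 32 px inputs),
  which compresses the room between plain and robust models — see the
  limitations section.

PGD attacks support p in {1.5, 2, 4, Inf} with steepest-ascent steps
(dual-norm direction), projection after every step (exact for p = 2 and
Inf, radial rescaling for 1.5 and 4 — feasibility is what the downstream
guarantees need), and box clipping. The default step size is
`2.5 eps / steps` with 10 steps.

Evaluation reports accuracy, balanced accuracy (mean per-class recall) and
quadratically weighted Cohen's kappa with weights `(i-j)^2/(K-1)^2`, the
standard agreement statistic for ordinal grading.

## Diffusion visual counterfactuals

To turn the unconditional model into a counterfactual generator, the
original image is noised to step `ceil(T/2)` by the forward marginal —
starting mid-chain rather than from pure noise already anchors the result
to the subject — and the reverse chain is run with a shifted transition
mean. At every step:

1. the denoised estimate `x0_hat` is formed with `predict_x0()` and clamped
   to the value range; classifiers were trained on clean images, so all
   gradients are evaluated on `x0_hat`, not on the noisy state;
2. the **guidance gradient** is the gradient of the target-class
   log-probability with respect to the noisy state *through* the
   `predict_x0` map. The denoiser output is treated as constant in this
   chain (the standard stabilisation), which makes the map affine with
   factor `1/sqrt(alpha_bar_t)`; the factor is verified against central
   differences in the tests;
3. the **distance gradient** pulls `x0_hat` towards the original image:
   the gradient of `-lambda_d ||x0 - x0_hat||_2`;
4. the **total shift** normalises each gradient to unit Euclidean norm —
   the adaptive parameterisation that keeps the weights meaningful across
   images and steps — combines them as
   `s * g_guidance + lambda_d * g_distance`, and scales by the step's
   noise scale. The shipped default multiplies by the reverse-step standard
   deviation `sigma_t`; scaling by the variance `sigma_t^2` is available
   (`scale = "variance"`) but integrates to a total displacement far below
   lesion scale at 32 px, so the regularisation strength loses its effect
   — with unit-normalised gradients the `sigma_t` scaling is the choice
   that makes `lambda_d` behave as intended.

In `cone` mode, both classifiers are consulted: the robust model's gradient
(perceptually aligned, but the model is less accurate) is projected onto
the convex cone of directions within angle `alpha` of the plain model's
gradient (accurate, but perceptually uninformative). The projection is the
exact Euclidean one: gradients already inside the cone pass unchanged,
gradients beyond the polar cone project to zero, and everything else lands
on the cone boundary inside the span of the two gradients. Defaults
`alpha = 30` degrees and `lambda_d = 0.5` follow the source settings;
`lambda_d` trades identity preservation against the size of the change,
and the package's sweep over {0.7, 0.5, 0.3, 0.2} reproduces the expected
monotonicity: distances grow and non-flip fractions shrink as `lambda_d`
decreases.

The guidance scale `s` weights the (unit-normalised) classifier term
against the distance term. Its default is 3 rather than 1: the
unconditional model is trained on a class mix in which four of the five
grades carry lesions, so its prior actively repaints small dark lesions
while denoising. At `s = 1` that prior wins in the diseased-to-healthy
direction — hemorrhages and exudates are removed but the oracle counts
*more* microaneurysm-like dots afterwards. At `s = 3` the classifier term
dominates the prior and both directions move the lesion counts the
clinically right way, with flip rates, monotonicity and identity
preservation unchanged.

Confidence, flip status and distances are always reported under the plain
classifier.

## Sparse baseline

The sparse visual counterfactual maximises the target-class
log-probability inside an lp ball (default p = 4, which concentrates
changes on few pixels) around the original image, with no generative
model. The optimiser is vanilla Frank-Wolfe: the linear subproblem over
the lp ball has the closed form
`s_i = eps sign(g_i) |g_i|^{1/(p-1)} / |||g|^{1/(p-1)}||_p`, steps shrink
as `2/(t+2)`, and the box constraint is handled by clipping (which cannot
leave the ball, because the original lies in the box and clipping is a
componentwise contraction towards it). The adaptive step-size machinery of
the published Auto-Frank-Wolfe attack is out of scope; the diminishing-step
variant is sufficient for the comparisons made here. The objective uses the
plain+robust ensemble by default (`ensemble = FALSE` uses the robust model
alone); both appear in the literature and the choice is exposed.

## Evaluation and study statistics

`filter_counterfactuals()` mirrors the selection rule used before expert
review: keep a pair only if the classifier got the original right and
assigns the counterfactual a target confidence strictly above 0.5.
`flip_rate_table()` sweeps `lambda_d` with common random numbers across
rows so the monotonicity of the sweep is not drowned by sampling noise.
`lesion_delta_report()` summarises oracle-count changes by the median,
which is robust to the occasional guidance failure.

The statistics module covers the quantities an odd-one-out realism study
produces: Wilson score intervals for detection proportions (the Wilson
interval reproduces the printed bounds of the motivating study exactly,
which is how the CI method was identified; a normal-approximation interval
does not), odds ratios from 2x2 tables with Wald intervals (a zero cell
requires the explicit continuity-correction flag), a trial-level logistic
GLM via `stats::glm` with Wald intervals — per-rater random effects are
deliberately not modelled, matching the fixed-effects analysis it mirrors
— and a study simulator with a logistic success model used for coverage
experiments (ground-truth odds ratios are recovered with nominal CI
coverage at n = 800 trials).

## Numerical choices and degenerate inputs

* Zero gradients: unit-normalisation maps zero rows to zero (no shift);
  a zero plain-classifier gradient makes the cone ill-defined, and the
  robust gradient is used unprojected with a warning.
* Ties at the cone boundary keep the robust gradient unchanged.
* `alpha_bar_0 = 1` by convention, so `q_sample(x, 0)` is the identity and
  the last reverse step adds no noise.
* Box and ball feasibility are enforced after every attack and
  Frank-Wolfe step, and asserted in the tests on every call.
* All stochastic entry points take explicit integer seeds and restore the
  caller's RNG state (`withr::with_seed`).

## Problem sizes

The shipped experiment — also what the test suite and the acceptance
script run — uses 400 images per grade at 32 px (75/15/10 subject-wise
splits), a 2000-iteration denoiser on a 200-step schedule, a 35-epoch
plain classifier, an 8-epoch TRADES classifier warm-started from it, and
40 originals per direction for the guided sweep over
`lambda_d` in {0.7, 0.5, 0.3, 0.2}. These sizes were chosen so the whole
experiment reruns from scratch on a single CPU in well under half an hour
while leaving every qualitative conclusion stable across seeds.

## Known limitations

* Phantom realism is structural, not photometric; nothing here measures
  whether a human would find the counterfactuals realistic — that requires
  the expert study the statistics module analyses.
* The denoiser's receptive field is local; at much higher resolutions a
  multi-scale (UNet) architecture would be needed.
* The adaptive-parameterisation realisation (per-term unit normalisation)
  and the detached-denoiser guidance chain are documented stand-ins for
  the exact formulations of the full-scale method, which are not part of
  this package's scope.
* l4 and l1.5 ball projections in PGD are radial, not Euclidean; only
  feasibility, not projection optimality, is guaranteed for those norms.
* The robustness *gap* between the TRADES and plain models is small at
  this scale. The plain convolutional model is already strongly PGD-robust
  for radii well below lesion scale, and radii near lesion scale make
  robust separation information-theoretically impossible (the ball crosses
  the class boundary), at which point TRADES collapses towards constant
  prediction. Within the feasible window the best non-degenerate robust
  models we could train exceed the plain model's attacked accuracy by
  roughly 10 percentage points, not the much larger gaps seen with
  high-capacity networks on high-resolution images; the corresponding
  acceptance check in the test suite is expected to fail at this scale and
  is kept as an honest record of the limitation.
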