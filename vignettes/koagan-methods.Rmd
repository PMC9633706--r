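---
title: "Generating and auditing synthetic knee osteoarthritis radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and auditing synthetic knee osteoarthritis radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`koagan` implements a complete pipeline for producing and validating
synthetic ("DeepFake") knee-joint X-ray crops with a Wasserstein GAN:
radiograph preprocessing, WGAN-GP training on a fixed published
architecture, Fréchet-distance model selection, a nearest-neighbor
memorization audit, survey-response scoring, latent-space exploration, and
a dataset-construction experiment that measures the augmentation and
anonymization value of the generated images in a binary severity
classification task (KL grades 0–1 versus 2–4 on the Kellgren–Lawrence
scale).

Every stage is exercisable without any clinical data through a synthetic
*phantom* radiograph generator, which is first-class, tested code.

## The phantom model

A phantom is a deliberately simple geometric surrogate for a knee crop:
two horizontal "bone" bands separated by a joint-space gap, a dimmer
lateral "fibula" band in the lower half, bright semicircular bumps at the
joint margins standing in for osteophytes, optional global intensity
inversion (a negative image), Gaussian defocus blur, additive detector
noise, and a rare one-pixel bright scratch artifact.

The two severity classes differ structurally the way the real classes do
statistically: class B narrows the joint gap to 0.4 of the class-A gap
(joint-space narrowing) and doubles the expected osteophyte count. The
defaults — 299 px frames, 8 gray-level noise, blur sigma 4 px for the
blurred fraction — mirror the source-data conditions the pipeline assumes
(8-bit, 299×299 inputs; a focus continuum wide enough that the blur split
is non-trivial).

Noise is added *after* blur and before clipping, mimicking detector noise
on a smoothed signal. Right-lateral phantoms are produced by mirroring the
fully rendered left-lateral image, which makes mirror symmetry exact by
construction and testable bit-for-bit.

What phantoms do **not** emulate: real anatomy, real X-ray texture
statistics, scanner heterogeneity, or label noise. Tests that pass on
phantoms establish that the *machinery* is correct (shapes, equations,
bookkeeping, training dynamics), not that the generative model reaches
clinical realism on real radiographs.

## Preprocessing

The pipeline order is: orientation normalization → negative-image
inversion → histogram equalization → anti-aliased bilinear rescale to
210×210 → focus filtering. Rows flagged as artifacts (or otherwise
excluded) are dropped before the focus split; blurry rejects are kept in a
separate manifest because the downstream experiment reuses them as its
scarce real-data pool.

**Equalization.** Each 8-bit value $v$ maps to
$h(v) = \mathrm{round}\!\left(255\,\frac{cdf(v)-cdf_{\min}}{mn - cdf_{\min}}\right)$
over 256 integer bins, with round-half-up for bit reproducibility. The
mapping is monotone and spans exactly $[0,255]$ whenever the image has two
distinct values; a constant image makes the denominator zero, so it is
returned unchanged with a warning rather than an error.

**Focus metric.** The image is convolved with the 3×3 Laplacian
$\left[\begin{smallmatrix}0&-1&0\\-1&4&-1\\0&-1&0\end{smallmatrix}\right]$
and scored by the **sum** of squared deviations of the absolute response
from its mean. The sum (not the mean) is kept because the conventional
blur threshold of 350 is tied to that statistic. The convolution is
evaluated in *valid* mode by default — border padding would inject
artificial edges directly into a statistic that measures edge energy — and
a `same` mode with reflect padding is available for compatibility with
full-size-response conventions. The threshold itself is a configuration
value; `grid_search_threshold()` reports partition sizes over a candidate
grid (default 0, 175, 350, 525) and the choice between candidates is
deliberately left to inspection.

**Heuristics.** No rule is inherited for detecting negatives or
laterality, so both are explicit design choices here: an image whose 5%
border frame is brighter on average than its center is classified as a
negative (radiograph backgrounds are dark air); laterality is trusted from
the manifest by default, with an optional heuristic that compares lateral
mass in the lower third of the frame (the fibula side is heavier).

## The WGAN-GP

The generator maps a 50-dimensional standard-normal latent vector through
a bias-free dense layer to 100,352 units, batch normalization, ELU
(α = 0.2), a reshape to 14×14×512, three upsample-by-2 + 3×3 bias-free
convolution stages of 128 filters, a final 1-filter convolution, batch
normalization, tanh, and a 7-pixel crop from 224×224 to 210×210. The
critic takes 210×210×1 through a 2-pixel zero padding and five stride-2
5×5 convolutions (64/128/256/312/422 filters) with ELU and dropout, then a
single linear unit. Parameter totals are 6,304,900 (generator; 6,104,194
trainable) and 6,335,861 (critic); these exact counts are asserted in the
tests and recomputed by `scripts/acceptance.R`. Two details are forced by
the printed arithmetic rather than stated outright: the strided critic
convolutions must use `same` padding (to give 214 → 107 → 54 → 27 → 14 →
7), and the post-dense batch normalization must normalize all 100,352
features while the output one is per-channel (their non-trainable counts
are 200,704 and 2).

Training minimizes the critic loss
$\mathbb{E}[D(\hat{x})] - \mathbb{E}[D(x)] + \lambda\,
\mathbb{E}[(\lVert\nabla_{\tilde x}D(\tilde x)\rVert_2 - 1)^2]$
with λ = 10 and uniform per-sample interpolates
$\tilde x = \varepsilon x + (1-\varepsilon)\hat{x}$, and the generator
loss $-\mathbb{E}[D(\hat{x})]$. The critic takes four update steps per
generator step by default ("three extra steps ahead" read literally as
1 + 3; configurable to 3 — parameter counts and every acceptance quantity
are unaffected either way). Both networks use Adam with learning rate
2e-4, β₁ = 0.5, β₂ = 0.9, and decay 1e-4 applied per optimizer step in
the legacy inverse-time convention $l/(1+d\,t)$; an exponential schedule
is available, since decaying-learning-rate training can refer to either
mechanism. Batch normalization uses ε = 1e-3 and momentum 0.99. Real
images enter as $x/127.5-1$ to match the tanh output range, and latent
sampling is deliberately un-truncated.

### The network engine

No deep-learning framework is part of this package's stack; the adversarial
training is the package's core contribution, so `koagan` carries its own
compact CPU engine: declarative layer specs (the single source of truth
for shape inference, parameter counting and materialization),
forward/backward passes for dense, convolution, batch-norm, ELU, tanh,
sigmoid, dropout, upsample, pad/crop and reshape layers, and Adam.
Convolution hot loops are C++ (gather/scatter of channel-first slices plus
BLAS `dgemm`); everything else is vectorized R. Analytic gradients for
every layer are validated against central finite differences in the test
suite to ~1e-9 relative error.

One piece deserves explanation: the gradient penalty's *parameter*
gradient needs the derivative of $\nabla_{\tilde x} D$ with respect to the
critic weights — a second-order quantity. Rather than implementing double
backprop, the engine uses the mixed-partials identity
$\nabla_\theta\, u^\top \nabla_x D(x) = \nabla_\theta\,
\partial_u D(x)$ and estimates the directional derivative with a centered
finite difference of two ordinary backprop passes at $x \pm \epsilon u$
(ε = 1e-3 on unit directions). The penalty *value* itself is exact
(analytic backprop to the input). The finite-difference gradient matches
numeric differentiation of the penalty to ~1e-8 in the tests. Dropout is
disabled inside penalty evaluation so the penalty is a deterministic
function of the batches and the interpolation draws.

### Desk-scale training conditions

Full-scale training (210×210, 1000 epochs, batch 32) is a multi-day GPU
workload. The package therefore ships a *scaled spec* with the same
topology at 64×64 (seed map 5×5×64, 32-filter stages, 8-pixel crop;
critic filters 8/16/32/32/48), used by the smoke tests: 64 phantoms,
batch 16, 128 generator steps, a fixed seed. Under these conditions the
Wasserstein estimate $\mathbb{E}D(x)-\mathbb{E}D(\hat x)$ follows the
canonical WGAN trajectory — near zero at initialization, rising while the
critic learns to separate real from noise, then falling as the generator
closes the gap. The convergence test asserts exactly that shape: the
20-step moving average peaks before the final window and the tail sits
below the peak. Comparing the tail to the *initial* average would be
wrong-headed: an untrained critic scores everything near zero, so the
first steps are trivially "good".

## Model selection and the memorization audit

Epoch selection minimizes the Fréchet distance between Gaussian fits to
embedded real and generated samples,
$\lVert\mu_g-\mu_r\rVert^2 + \mathrm{tr}\,\Sigma_g + \mathrm{tr}\,\Sigma_r
- 2\,\mathrm{tr}\,(\Sigma_g\Sigma_r)^{1/2}$, with sample covariances and
eigenvalue clipping at 1e-6 for the matrix square root. A variant that
replaces the cross term with $\mathrm{tr}\sqrt{\Sigma_g+\Sigma_r}$ exists
in print; it is not zero for identical distributions, so the standard form
is the default here and the variant is kept behind `form = "printed"` for
forensic comparison only.

The feature extractor is pluggable. At full scale one would use a
pretrained InceptionV3 embedding; the package's default test extractor is
a fixed-seed random linear projection of pixels, which needs no downloads
and preserves every distance property the tests rely on. Generated sample
sizes default to matching the real set, since the Fréchet estimator is
strongly biased at small n.

The memorization audit pairs each generated image with its nearest real
neighbor (Euclidean, in feature space) and returns the top-20 closest
pairs as a side-by-side montage — a review sheet for a human expert. No
automatic memorization threshold is imposed, because the substantive
judgment (shared origin, replicated morphology) is the expert's; the
package only adds a heuristic warning when a pair distance falls below the
1st percentile of real–real distances.

## Survey scoring

Experts classify images as real or fake and rate KL grades; scoring uses
balanced accuracy $\tfrac12(\mathrm{TP}/(\mathrm{TP+FN}) +
\mathrm{TN}/(\mathrm{TN+FP}))$ because missing responses unbalance the
answered classes. Missing calls are excluded per expert, never imputed.
Precision and F1 treat "fake" as the positive class by default (the
detection task) with a switch to swap; a zero denominator reports `NA`
rather than 0. Group summaries are unweighted means over experts with
sample (n−1) standard deviations; experts whose specialty is neither
orthopedics nor radiology are disqualified from every group. Rated KL
grades map to classes as {0,1} → KL01 and {2,3,4} → KL234.

## The augmentation / anonymization experiment

Six datasets are built from a scarce pool of real images (by design, the
focus-rejected pool): a baseline of 100 + 100 real training images with
66 + 66 validation and test images per class; four augmented plans that
*recursively* extend the previous training set with +50%/+100%/+150%/+200%
generated images (300/400/500/600 training rows); and a replacement plan
that trains on the +100% plan's fakes only — anonymization by replacement.
Validation and test sets stay real everywhere, and the three real subsets
are pairwise disjoint. All of this is asserted on every build.

The full-scale classifier is a VGG16 transfer variant: the 13-convolution
base sized to emit a 6×6×512 map (input 192×192×3), flatten (18,432), a
256-unit ELU dense layer (4,718,848 parameters) and a sigmoid output
(257). The printed non-trainable count, 7,635,264, equals convolution
blocks 1–4 exactly, so those are frozen and block 5 plus the head train —
the arithmetic wins over the looser phrase "last three blocks trainable",
which does not match any contiguous freeze split. Totals: 19,433,793
parameters, 11,798,529 trainable. Grayscale inputs are replicated to three
channels for backbone compatibility; the transfer optimizer is not
specified anywhere, so the harness defaults to Adam at 1e-4 and documents
that as a gap. Pretrained ImageNet weights are not bundled; parameter
fingerprints need none, and the desk-scale experiment uses a small strided
CNN stand-in on phantom data.

Each run trains with best-validation-loss checkpointing and reports test
accuracy and loss at that checkpoint plus best validation accuracy and
loss. At desk scale the suite checks a *directional* analogue of the
augmentation finding: with separable phantom classes and an ideal fake
sampler, +200% augmentation stays within 2 accuracy points of baseline in
at least 4 of 5 seeds. Reproducing the published accuracy table itself
requires the clinical images and is out of scope.

## Latent exploration

Single-dimension sweeps cover −4.2 to +4.2 (the conventional ±3σ-ish
range for a standard-normal latent, as published) in a configurable number
of steps, default 7 — the published figures do not state their step count.
Interpolation is linear in latent space; strip frames are generated one
forward pass at a time so the endpoint images are bit-identical to the
single-latent outputs (batched BLAS paths may round differently).

## Numerical and degenerate-input policies

* Equalization of a constant image: unchanged, with a warning.
* Focus metric on images smaller than 3×3: an error (the kernel cannot fit).
* Fréchet square root: symmetrized eigendecomposition, eigenvalues floored
  at zero, tolerance 1e-6.
* Precision/F1 with empty denominators: `NA`, never 0.
* Epoch-selection ties: earliest epoch wins.
* Non-finite training losses abort with a diagnostic rather than continue.
* All stochastic stages (phantoms, cohort mixes, training, sampling,
  dataset construction, simulated surveys) run under explicit seeds and
  are bit-reproducible on one platform.

## Problem sizes used in the test suite

Module tests run on 48–96 px phantoms and feature matrices of a few
hundred rows. The heavier checks are: the univariate Fréchet closed-form
comparison at n = 10⁵; the 128-step WGAN-GP smoke run at 64×64 on 64
phantoms (a few minutes of CPU); and ten small classifier trainings for
the augmentation trend. These sizes were chosen as the smallest at which
the qualitative phenomena under test (blur separation, adversarial
convergence, augmentation neutrality) are stable across seeds.

## Known limitations

* The phantom is a geometric surrogate; nothing here validates clinical
  realism — that requires expert review of real-data models.
* The desk-scale WGAN demonstrates convergence machinery, not image
  quality; 128 steps at 64×64 is orders of magnitude short of the
  full-scale schedule.
* The random-projection extractor preserves distance structure but is not
  a perceptual embedding; absolute Fréchet values are not comparable to
  Inception-based numbers.
* Inverse-time versus exponential learning-rate decay is a genuine
  ambiguity in the source training description; both are implemented, the
  legacy inverse-time convention is the default.
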