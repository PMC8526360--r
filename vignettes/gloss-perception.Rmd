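---
title: "Unsupervised learning of gloss perception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised learning of gloss perception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Surface gloss is not a physical quantity an observer can read off an image:
the luminance pattern reaching the eye entangles specular reflectance with
illumination, surface relief and albedo. `glossim` implements a complete,
self-contained pipeline for studying the hypothesis that a *gloss-like*
perceptual dimension can emerge in a system that never receives reflectance
labels — an unsupervised generative model trained only to predict and
compress images of glossy and matte surfaces. The package renders a
controlled world, trains the model, reads gloss out of its latent code with
a linear probe, and then interrogates the representation with the tools of
visual psychophysics: representational similarity, simulated two-alternative
forced choice (2AFC), constancy-failure classification, and specular
highlight-cue manipulations.

Because the package is also its own data source, every analysis is
reproducible from a seed. Human observers are emulated by a synthetic
observer model; the package makes no claims about fitting archived human
data.

## The simulated world

`world_config()` defines a 40 x 40-unit sheet carrying irregular bumps
(sums of seeded radial Gaussian kernels), viewed from a perspective camera
12 units above the sheet with a 60 degree field of view, so each image shows
a window of roughly 14 units. Scene factors are drawn independently:

* **Relief** (max minus min elevation) uniform on \[0.1, 2.5\] units.
* **Diffuse albedo** per channel uniform on \[0.3, 0.7\].
* **Specular reflectance**: a *magnitude* (strength) and a *concentration*
  (lobe tightness). The main (bimodal) regime draws half the scenes from a
  low-gloss mode (magnitude U(0.1, 0.3), concentration U(0.2, 0.4)) and half
  from a high-gloss mode (magnitude U(0.3, 0.5), concentration
  U(0.75, 0.95)). A continuous regime samples both uniformly on
  \[0.1, 0.8\]; a rating-probe regime samples magnitude on \[0.2, 1.0\] with
  concentration tied to it.
* **Illumination**: one of six fixed, seeded light fields — 8 to 16
  directional lights with a dominant sun-like source, a distinct dominant
  azimuth and colour temperature per field, plus an ambient term — or a
  single directional "lamp" at a stated elevation for the constancy pairs.
  Light-field ids beyond the default six give novel illumination for
  generalization tests.
* **Camera jitter**: translation up to 5 units and rotation up to 15
  degrees, so the same world state yields many distinct images.

Shading is Lambertian plus a Blinn-style specular lobe. The lobe exponent is
mapped from concentration by $s = \exp(a + b\,c)$ anchored at $c = 0.2
\rightarrow s \approx 5$ and $c = 0.95 \rightarrow s \approx 200$, and the
lobe is energy-conserving (scaled by $(s + 2)/2\pi$), so concentrated
highlights are small but bright — the contrast-, sharpness- and
coverage-type cues gloss perception is known to use. Scenes are shaded at
twice the target resolution and block-averaged (`supersample = 2`) so tight
lobes are sampled adequately. The diffuse and specular components are stored
separately; the composite is their clipped sum, quantized to 8 bits when a
dataset is generated — the same 0..255 lattice the model's likelihood is
defined on. Intensities are linear throughout (no gamma).

Choices the source material leaves open, fixed here once: the bump count
(30 kernels per scene), kernel radii (5–15% of the sheet), the light-field
construction above, and the shininess anchors. The light fields are not
captured environment maps; what the analyses require is that they are
fixed, distinct and identifiable, which seeded multi-directional sets
provide.

## The unsupervised model

`train_pixelvae()` implements a PixelVAE-style model: a convolutional
encoder (three stride-2 layers, then a fully connected layer) outputs the
mean and log-variance of a diagonal-Gaussian posterior over a compact
latent code $z$ (10 dimensions); an autoregressive decoder models each
pixel's RGB value given all raster-order-previous pixels and $z$. The
pixel likelihood is a discretized mixture of logistics with linear
coupling of green to red and blue to red/green within a pixel; causal
masking enters through the convolution weights (the first decoder layer
excludes the centre pixel entirely, later layers include it). The latent
conditions the decoder as a spatially broadcast bias added at each residual
block input, and the first/last (and at full scale second/fifth) blocks are
skip-linked. The objective is the standard two-term variational bound —
teacher-forced reconstruction negative log-likelihood plus the closed-form
divergence from the standard-normal prior — optimized by Adam (learning
rate 0.001, decayed by 0.999995 per epoch, batch size 5, gradient norm
clipped at 5, no other regularization).

Two presets share every mechanism and differ only in size:

| knob | `full` | `desk` |
|---|---|---|
| image size | 128 | 32 |
| encoder widths | 64/128/256, fc 512 | 16/32/64, fc 128 |
| residual blocks | 6 x 3 layers x 64 maps | 3 x 2 layers x 16 maps |
| mixture components | 12 | 5 |
| epochs | 200 | 18 |

The desk preset trains in about ten minutes on one CPU (the package's
network core is hand-written im2col convolution on Rcpp/Armadillo with
analytic gradients, verified against numerical differentiation and a
brute-force likelihood oracle). The desk epoch count sits at the top of the
10–20 band the preset is designed for because the latent code's linear
gloss decodability — the property every downstream analysis rests on —
still improves monotonically over that range (roughly 0.79 held-out
accuracy after 10 epochs on 1,500 images, 0.87–0.93 after 12–18 epochs on
2,500 images). Routine runs and tests use 1,500–2,500-image datasets; the
full-scale preset is provided but not exercised by tests. Downstream
analyses use the posterior *mean* as the image's latent code, making every
readout deterministic; whether the original analyses used means or samples
is unstated, and the mean is fixed here as a design decision.

Comparison models: a supervised residual-network classifier (three residual
blocks of three conv layers, a 10-unit penultimate layer used as its
"latent", softmax cross-entropy, 99%+ on ground-truth gloss labels; the
desk preset shrinks the width to 8 maps but keeps the full 21-epoch
schedule, because training well past the accuracy plateau is what collapses
the penultimate features onto the gloss decision and strips them of
incidental lighting and relief information — the phenomenon the
representational comparisons are about), the
same backbone as a continuous regressor, a plain convolutional autoencoder
(mean-absolute-error objective, fully connected bottleneck), histogram
skewness with an optimal threshold, a simplified multiscale texture-feature
set (log-Gabor moments, 7 x 7 autocorrelations, cross-scale magnitude
correlations — a compact stand-in, not a reimplementation of the cited
1,350-dimension set), and pixel-space embeddings (classical MDS via
`stats::cmdscale`; compact reference implementations of t-SNE and LLE,
since no installed package provides them).

## Linear readouts

`fit_gloss_classifier()` standardizes features per dimension (train-split
statistics), fits a soft-margin linear maximum-margin classifier (cost 1,
via libsvm) on a 75/25 split, and unit-normalizes the hyperplane so that
`predict_gloss()` returns the signed distance from the decision boundary in
standardized feature units — positive means "high gloss", magnitude means
strength of evidence. This decision value is the model's *continuous* gloss
prediction everywhere downstream (2AFC simulation, cue curves,
generalization tests). Light fields are decoded one-vs-rest; relief by
ordinary least squares with held-out $R^2$ reported as computed (it may be
negative). `gloss_axis_traversal()` moves a seed image's latent 0.07 units
per step along the hyperplane normal (in the standardized space the axis
lives in, so decision values step arithmetically by exactly 0.07) and
generates an image at each point.

Feature standardization before the margin fit is a package decision (the
source is silent); the regularization constant is fixed at 1 and never
tuned.

## Representational similarity and psychophysics

`correlation_distance_matrix()` uses 1 minus Pearson's r between latent
vectors; with a 10-D code this is a noisy per-pair measure, and it is
retained because it is the field's standard metric (a Euclidean variant
exists for sensitivity checks). Same-vs-different condition contrasts
exclude self-pairs, and the paired t-test across model training instances
uses df = instances - 1 with percentile-bootstrap CIs (10,000 resamples,
seeded).

The psychophysics layer is exact where the procedures are exact:
`simulate_2afc()` enumerates all pairs with deterministic argmax choices and
0.5/0.5 tie splitting (ties are not defined by the source's deterministic
rule; the split is this package's convention); the constancy-pattern
classifier applies the published thresholds (range < 0.25 with linear
$R^2 > 0.70$ for constancy; range > 0.50 with linear $R^2 > 0.90$ for
linear increase; quadratic $R^2 > 0.90$ with negative/positive squared
coefficient for the two nonlinear classes) in the order constant,
non-monotonic, upward-nonlinear, linear — quadratic classes take precedence
because a strong quadratic also fits a line moderately well. Decile pair
selection takes the pair at rank $\lceil kn/10 \rceil$ of the ascending
|prediction difference| ranking. The seven-step relief schedule is the
geometric progression 0.10 to 3.0 (0.10, 0.18, 0.31, 0.55, 0.97, 1.70,
3.0); a printed variant with a non-monotonic sixth step is available as
`relief_schedule("as_printed")` but conflicts with the stated exponential
increase and is not the default.

Synthetic observers choose between two stimuli with probability
$\lambda/2 + (1 - \lambda)\,\mathrm{logit}^{-1}(\beta\,\Delta g)$ and rate
stimuli by cutting a noisy monotone transform of gloss at five ordered
criteria. Population defaults — 20 observers, $\beta$ log-normal with
median 2 and 0.3 log10 units spread, lapse uniform on \[0, 0.1\] — are
chosen once as representative of practiced psychophysical observers.
`fit_observer_params()` recovers $\beta$ and $\lambda$ by maximum
likelihood and exists mainly as the recovery oracle for the generator.
What passing these tests shows is that the *analysis layer* is correct and
that the observer model is self-consistent; it does not validate the
observer model against real humans.

## Highlight cues

Coverage is the fraction of pixels brighter (BT.601 greyscale, half-level
tolerance) in the composite than in the diffuse component. Sharpness is
cross-scale phase agreement of a 3-scale, 4-orientation complex log-Gabor
pyramid averaged over the highlight mask (greyscale specular > 4/255); the
cited local-phase-coherence measure lives in an external package, so the
property contract here is behavioural — blur must lower the score — rather
than numeric parity. Contrast is the summed RMS of eight octave-spaced
bandpass versions of the specular component, exactly homogeneous of degree
one. Manipulations follow the published schedules: rightward translation in
five-pixel steps on an oversized render cropped lower-right; 2 x 2
morphological erosion with step iterations; Gaussian blur with kernel size
step + 1 (1 x 1 to 11 x 11); highlight-pixel standard deviation scaled 1 to
0.1 linearly with the mean retained. At 32 px the translation-invariance of
the cues holds approximately (the window content itself shifts); the
ordering claim — translation affects predicted gloss less than any
cue-weakening manipulation — is the assertion the analyses rely on.

## Numerical choices and limitations

* Likelihood bins are \[v - 0.5, v + 0.5\] on the 0..255 scale with
  tail-absorbing edge bins; log-scales are clamped at $-7$; bin
  probabilities are floored at $10^{-12}$ inside logs.
* All randomness flows through integer seeds (31-bit derived streams); the
  RNG state is restored after every seeded operation, so library calls
  never perturb a caller's stream.
* Training is bit-reproducible for a fixed seed on a fixed BLAS.
* Desk-scale problem sizes (1,500 images, 32 px, 10 epochs, one or two
  model instances) are the package's chosen operating point for routine
  runs; they preserve every qualitative result the tests assert but shrink
  the quantitative margins — a desk-scale gloss decoding accuracy in the
  mid-0.9s corresponds to 99%+ at full scale.
* The renderer is a direct-illumination shader: no interreflections,
  shadows, tone mapping or environment-map sampling. The synthetic world is
  therefore *cleaner* than photographs; passing tests show the pipeline's
  internal claims, not generalization to real surfaces.
* The object-recognition-network comparison requires downloaded pretrained
  weights and is out of scope.

## Reproducing the study numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` re-renders
the worlds, retrains both models, and recomputes the headline quantities
(gloss decodability of both models, cue decodability and the cue–prediction
correlation, generalization $R^2$, and the re-training transfer accuracy)
from scratch; see the README for what each number means.
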