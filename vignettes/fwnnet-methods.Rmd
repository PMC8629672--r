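---
title: "Fuzzy wavelet neural networks: model, training and segmentation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy wavelet neural networks: model, training and segmentation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwnnet)
```

## The model

`fwnnet` implements an eight-layer fuzzy wavelet neural network (FWNN): a
Takagi–Sugeno–Kang (TSK) fuzzy system whose rule consequents are small
wavelet networks. For an input feature vector
$x = (x_1, \dots, x_n)$ and $M$ rules with $N$ wavelet neurons each:

1. **Antecedents.** Each rule $k$ carries one Gaussian membership per
   feature, $\mu_{kj} = \exp\!\big(-((x_j - c_{kj})/\sigma_{kj})^2\big)$
   (note: no $\tfrac12$ in the exponent — the same width convention is used
   by the histogram feature model, so fitted widths transfer directly).
2. **Firing strengths.** Product t-norm: $O_k = \prod_j \mu_{kj}$.
3. **Consequents.** Each wavelet neuron evaluates the tensor product of
   dilated/translated copies of a mother wavelet,
   $\Psi_{ik} = \prod_j \psi\!\big((x_j - b_{ijk})/a_{ijk}\big)$, and the
   rule output is $Y_k = \sum_i w_i^k \Psi_{ik} + \bar y_k$.
4. **Defuzzification.** $y = \sum_k O_k Y_k \big/ \sum_k O_k$, a convex
   combination of the rule outputs.
5. **Output layer.** For classification the continuous output is rounded
   (half away from zero) and clamped into $\{0, \dots, C-1\}$.

The trainable set is
$\Theta = \{c_{kj}, \sigma_{kj}, b_{ijk}, a_{ijk}, w_i^k, \bar y_k\}$:
$2Mn + 2NnM + NM + M$ parameters.

**Mother wavelet.** Two admissible families ship: the Mexican hat
$(1 - x^2) e^{-x^2/2}$ (default — the customary choice in the FWNN
literature) and the real Morlet $\cos(5x)\,e^{-x^2/2}$.
`check_admissibility()` verifies numerically that a candidate has zero mean
and a finite admissibility constant
$C_\psi = \int_0^\infty |\hat\psi(\omega)|/\omega\, d\omega$. The
$|a|^{-1/2}$ energy-normalizing prefactor is optional
(`normalize_wavelet`); the bare form is the default, and both are
differentiated exactly in training.

**Numerical choices.** Widths and dilations are kept off their singular
values by projection floors ($\sigma \ge 10^{-3}$, $|a| \ge 10^{-3}$ with
the sign of the pre-update dilation preserved when a step crosses zero).
The defuzzifier is undefined when no rule fires; the strict evaluation path
raises an error once $\sum_k O_k \le 10^{-12}$. Firing strengths are
computed in log space ($\log O_k = -\sum_j u_{kj}^2$), and the
`log_space = TRUE` configuration evaluates the output with
log-sum-exp-stabilized weights. That changes nothing mathematically — $y$
is invariant to a common rescaling of the $O_k$ — but keeps the weights
well defined when $n$ is large: a product of hundreds of memberships
underflows double precision long before the *relative* rule weighting
degenerates. The segmentation mode, whose input dimension is $(2m)^2 + 2$,
uses it; training always uses it internally for the same reason. Rounding
ties go half-away-from-zero, then clamp — "round" alone does not fix a tie
rule, so ours is stated rather than assumed.

## Hybrid training

Training minimizes the squared error $E = \tfrac12 (y_{\mathrm{true}} -
f(x))^2$ (dataset RMSE is reported) in two stages.

**Stage 1 — particle swarm initialization.** A global-best swarm searches a
box derived from the observed feature ranges (centers and translations
within the range, widths and dilations up to the range, weights and biases
in $[-2, 2]$). Defaults: 20 particles, 50 generations, $c_1 = c_2 = 2$,
inertia decreasing linearly 0.9 → 0.4, velocities clamped to half the box
width. Generation 1 is the evaluated initial population. The default
*inline* variant moves the swarm blockwise within each generation — first
the antecedent block $(c, \sigma)$, then the wavelet block $(b, a)$, then
the output block $(w, \bar y)$ — re-evaluating after each block, which
coordinates the search with the grouped gradient updates that follow;
`plain_pso` moves the whole concatenated vector at once. The best-ever
fitness sequence is non-increasing by construction and every run is fully
seeded.

**Stage 2 — gradient descent.** All six parameter groups have analytically
derived gradients (chain rule through the layers; the membership path is
differentiated via $\log O_k$, the wavelet path with exact leave-one-out
products so zero activations need no special-casing). Each group has its
own learning rate, default 0.01. The fit keeps the best epoch seen,
including the initialization, so a too-large step can never return a point
worse than the swarm's. Gradient correctness is pinned to a central
finite-difference oracle in the tests (50 random draws, relative tolerance
$10^{-5}$ with a unit floor for near-zero components, where the $h =
10^{-6}$ difference itself carries only $\sim 10^{-9}$ absolute precision).

**Defaults that depart from plain full-batch descent.** On the 4-class
problem full-batch descent at rate 0.01 descends the RMSE very slowly once
the swarm has placed the rules (it plateaus around RMSE 0.35), while
per-sample (online) updates reach RMSE ≈ 0.10 within a dozen epochs.
`classification_experiment()` therefore defaults to online mode with
feature z-scoring (histogram means live on a 0–255 scale; standardizing
conditions the antecedent gradients) and up to three hybrid restarts,
keeping the restart with the highest training accuracy and stopping early
at 100%. `fwn_train_config()` itself keeps the plain defaults (full batch,
0.01) so the basic scheme remains available unchanged.

**Targets.** Classification trains the regressor against the numeric
labels $0..C-1$; accuracy is measured after rounding. On the synthetic
4-class feature set at its default separation the hybrid scheme reaches
100% training accuracy — the package's testable analogue of a
perfect-training-fit claim — and the comparison baselines (decision tree,
1-NN, LDA, naive Bayes, a 10-unit MLP, an RBF SVM; each from its standard
implementation with library defaults and a fixed seed) sit near ceiling on
the same features, as expected for a set built to be separable.

## Histogram features

Each 8-bit image is summarized by its 256-bin intensity density, modelled
as a sum of four Gaussian modes $h(v) \approx \sum_{g=1}^4 A_g
\exp(-((v - m_g)/s_g)^2)$. The fit is bounded Levenberg–Marquardt least
squares (via `minpack.lm`) with a five-start strategy — quantile-spaced
means, the four strongest peaks of a smoothed copy, fixed equal spacing,
and seeded perturbations, with amplitude starts read off the histogram —
keeping the lowest-residual solution, modes sorted by mean. On
well-separated synthetic histograms (mode spacing at least three times the
largest width) the generating means are recovered to well under 2% across
seeds. The default per-image feature vector is the four sorted means;
amplitudes or the full 12-parameter description are alternatives. Which
four numbers constitute "the" features is a design choice here, documented
rather than asserted.

An independent eigen-decomposition step (`eigen_reduce()`) implements the
classical image-stack covariance analysis in the image-count-sized Gram
space; it is composable with, but not required by, the histogram features.

## Synthetic phantoms

The generator is the package's test bed, built so every pipeline runs
without external data:

* **Background** pixels are drawn i.i.d. from the four-mode mixture in
  exactly the histogram model's parameterization (mode $g$: normal with
  mean $m_g$, sd $s_g/\sqrt2$, weight $\propto A_g s_g$), so a
  generate-then-fit round trip is exact up to sampling noise. Defaults:
  means (40, 100, 160, 220), widths (12, 10, 12, 9), 256×256 images.
* **Classes** 0–3 shift every mode mean by $(\mathrm{class} - 1.5) \times
  10$ intensity units; the feature-mode dataset emits the shifted means
  plus Gaussian noise (sd 2). With 10-unit separation against 2-unit noise
  the four classes are cleanly separable — deliberately so, since the
  role of the set is to test the training machinery, not to calibrate
  real-data difficulty.
* **Tumors** are ellipses of near-constant intensity (default 215–245,
  noise sd 5) with semi-axes 6–15% of the image side, fully inside the
  image, paired with 0/255 masks.

What the phantoms do *not* emulate: anatomical structure, spatially
correlated tissue texture, bias fields, partial-volume boundaries, Rician
noise. Passing tests on phantoms therefore demonstrate that the machinery
is correct and that the method separates smooth-vs-textured regions and
shifted histograms; they say nothing about accuracy on clinical MRI.

## Patch-based segmentation

Supervised segmentation follows a sweep-and-regress design:

1. **Gabor transform.** The image is convolved with a 4-orientation
   quadrature Gabor bank (0°, 45°, 90°, 135°), magnitudes aggregated by
   maximum and min-max rescaled to $[0,1]$. The default wavelength is 3 px:
   the kernel support must stay narrower than the structures being
   segmented, so that smooth tumor interiors map low and pixel-scale
   background texture maps high. (At wavelength 8 the 29-px kernel
   swamps a typical tumor with edge halos and tumor and background become
   indistinguishable — measurably, pixel AUC ≈ 0.5.)
2. **Patch pairing.** An $m \times m$ mask patch at each sweep position is
   paired with the co-centered $2m \times 2m$ input window ($m$ even;
   reflect padding at the border). Pairing is exactly invertible on the
   mask side: reassembling the target vectors at stride $m$ reproduces the
   mask bit for bit.
3. **Regression.** One shared FWNN (regression mode, log-space weights,
   $M = N = 2$) maps the window vector plus the normalized in-patch pixel
   offset to that pixel's mask bit; a one-network-per-pixel mode is
   available. Training rows are a class-balanced subsample (default cap
   3000 — tumor patches are rare), trained by the same hybrid scheme.
4. **Prediction.** Scores from all windows covering a pixel are averaged,
   clipped to $[0,1]$, and thresholded (default 0.5) into a 0/255 mask.
   The experiment default sweeps at stride 1, so each pixel averages all
   $m^2$ covering windows; this pixel-centered smoothing is what closes
   the gap to a local-averaging oracle near tumor boundaries (pooled test
   AUC ≈ 0.98 across generator seeds at stride 1, versus ≈ 0.94 at
   stride 2 on harder draws).

Evaluation is a pixel-level ROC (threshold sweep, trapezoidal AUC —
equivalent to the Mann–Whitney statistic, cross-checked against `pROC` in
the tests), per image and pooled; single-class masks are excluded from the
per-image list with a warning.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own working sizes: the classification experiment
runs at the full synthetic scale (2000 items, 500 per class, the
generator's reference scale); segmentation runs on 20 phantom pairs at
side 128 with $m = 4$
(training 15, testing 5) — the generator's 256 default stays for data
export, the experiment size keeps the demonstration compact; histogram
round trips use full 256×256 phantoms. All randomness flows from explicit
integer seeds, and seeded runs are bit-reproducible.

## Known limitations

* The product t-norm makes raw firing strengths underflow for large $n$;
  the stabilized weighting is the supported regime there, and the strict
  path's degenerate-input error is the intended behaviour when genuinely
  no rule fires.
* With $M = 2$ rules the classifier models class structure along
  essentially one soft partition; the 4-class staircase is representable
  (and learned), but problems with more intricate class geometry will need
  more rules.
* The swarm is a global searcher with no convergence guarantee; restarts
  trade time for reliability, and the training-accuracy selection rule is
  only meaningful in classification mode (regression falls back to RMSE).
* Baseline classifiers run at library defaults by design — they are a
  comparison harness, not tuned competitors.
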