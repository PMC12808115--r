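---
title: "Probabilistic MR contrast translation: models, uncertainty and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic MR contrast translation: models, uncertainty and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Translating a brain MR volume of one contrast (say T1-weighted) into another
(say T2-weighted) is useful whenever an acquisition is missing, corrupted or
too costly to repeat. Deterministic deep-learning translators give a single
answer per input and no statement of confidence. `mrtrans` treats the
translation as *conditional generation*: given an input image $x$, a model
samples plausible target images $y^{(1)},\dots,y^{(n)}$ from a learned
conditional distribution $p(y\mid x)$. The pixel-wise ensemble mean
$\bar y = \tfrac1n\sum_i y^{(i)}$ is the point prediction, the pixel-wise
standard deviation $y' = (\tfrac1n\sum_i (y^{(i)}-\bar y)^2)^{1/2}$ is the
uncertainty map, and the scalar score $\hat\sigma$ — the mean of $y'$ over
brain voxels — flags inputs the model was never trained for
(out-of-distribution, OOD).

Four models are implemented on one shared encoder–decoder backbone so that
comparisons reflect the learning principle and not the architecture:

* **direct** — deterministic baseline, trained with the mean-squared loss
  $\frac{1}{2N}\sum_i \lVert y^{(i)} - \tilde f(x^{(i)})\rVert^2$;
* **cgan** — conditional Wasserstein GAN with gradient penalty; the
  generator $g(x, z)$ receives a 128-dimensional latent vector through
  conditional instance normalization (CIN) at every block;
* **ncsn** — conditional noise-conditional score network:
  variance-exploding forward noising $y_t = y_0 + \sqrt{\beta_t}\epsilon$,
  denoising score matching, annealed Langevin sampling
  $y_{t-1} = y_t + \gamma_t s(y_t, x, t) + \sqrt{2\gamma_t}\,\epsilon$ with
  $\gamma_t = \lambda_\gamma \beta_t/\beta_1$;
* **ddpm** — conditional denoising diffusion probabilistic model:
  variance-preserving noising
  $y_t = \sqrt{\bar\alpha_t}\,y_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$,
  ancestral sampling with a *learned* reverse variance
  $\tilde\beta(t)$ trained by a hybrid objective.

# The phantom generator

Real multi-contrast datasets need GPUs and hours of training; the package
instead ships a synthetic paired-contrast brain phantom whose difficulty is
controlled. Each subject is one integer tissue map (nested ellipses: a
gray-like shell, white-like interior, two CSF-like ventricles, 2–4
subcortical-like blobs; radii modulated smoothly along the slice axis)
rendered into each contrast through a per-class intensity profile. The same
tissue map underlies all contrasts, so the cross-contrast map is exactly
learnable when the stochastic ingredients are switched off — the "sanity
ceiling" used by the model tests. Variability enters through

* per-subject geometric jitter (default 5% of structure dimensions),
* per-subject, per-class intensity jitter (Gaussian, SD 0.02 — the scale of
  protocol/scanner variation relative to a [0,1] dynamic range),
* a smooth multiplicative bias field `exp(a * p(r))` with a low-order
  polynomial `p` and amplitude `a = 0.05`,
* additive Gaussian noise inside the brain (SD 0.02, i.e. tissue SNR ≈ 25).

Values were chosen once as a mild, realistic regime; they are spec fields,
not tuning knobs. Simplifications worth knowing about: the noise is Gaussian
rather than Rician (keeps the variance checks analytic), geometry is
2.5-dimensional (ellipse stacks, no nonrigid anatomy), and there is no
k-space physics. Consequently, passing tests demonstrate that the *methods*
behave as specified on a controlled task — not that they meet clinical-grade
performance on real MR data.

OOD corruptions mirror the failure modes the full-scale study probes:
RF-zipper stripes (periodic bright dashes), ghosting (attenuated shifted
copy), low SNR (inflated noise), a hyperintense tumor blob and small
white-matter lesions. Pathology is hyperintense only in the *target*
contrast and isointense with white matter in the input contrast, recreating
the situation where a translator cannot know the lesion is there. Severities
are anchored to the qualitative prominence of their real counterparts:
zipper stripes at half the dynamic range (severity 2), ghost at 30%
intensity (2), and low-SNR noise at five times the nominal level
(severity 5, SNR ≈ 5). Corrupted volumes are clipped back to [0,1] rather
than re-normalized — a full min-max rescale would dim the uncorrupted tissue
and largely cancel the artifact's intensity signature.

# Numerical and training choices

**Backbone.** Depth-2 U-Net, base width 8 (desk scale), GroupNorm-free:
instance normalization with learned per-channel affine (replaced by the
CIN affine when a latent path exists), SiLU activations, sinusoidal step
embedding passed through a two-layer perceptron and injected as a
per-channel bias after each block's first normalization (a bias added
*before* instance normalization would be cancelled by it). The denoising
networks additionally use a step-gated input blend
(`out + sigmoid(w(t)) * y_t`), a learnable shortcut for the small-noise
regime where the best estimate of the clean image is the noisy image itself.

**Autodiff.** All models train on a compact reverse-mode tape written for
this package (R with BLAS matrix products; 3×3 convolutions, pooling and
normalization kernels in C++). Gradients of every operation are verified
against central finite differences in the test suite.

**NCSN.** Geometric schedule between $\beta_1 = 10^{-4}$ and
$\beta_T = 1$ with $T = 100$. The usual recipe sets $\sqrt{\beta_T}$ near
the maximal pairwise distance between training images; that choice targets
*unconditional* generation, where the terminal noise must bridge arbitrary
image pairs. For strongly conditioned translation the relevant spread is
that of $p(y\mid x)$, and a terminal variance of 1 (per-pixel noise equal to
the full dynamic range) is already far beyond it; larger values only spend
network capacity on noise levels the conditional task never needs
(`noise_schedule()` exposes both choices). The Langevin step scale defaults
to $\lambda_\gamma = \beta_1 r/2$, $r = \beta_{t-1}/\beta_t$: with a
well-trained score this makes the chain's noise level after the step at
level $t$ equal the training level $t-1$. Values of
$\lambda_\gamma \gtrsim 2\beta_1$ make the update operator expansive and the
chain diverges, which is why the default is tied to $\beta_1$ rather than
being an absolute constant. Internally the score network predicts the clean
image ($s = (\hat y_0 - y_t)/\beta_t$): the minimizer at every level is the
same conditional expectation as for raw score matching, but the regression
target supervises anatomy equally at all noise levels and a Langevin step's
error stays bounded by the clean-image error instead of growing like
$1/\sqrt{\beta_t}$. Training draws continuous level indices and perturbs
with a scale factor $\kappa \sim U(0.7, 2)$ around the nominal level: a
one-step-per-level annealed sampler runs slightly "hotter" than its
schedule, and the network must stay accurate there.

**DDPM.** Linear $\beta$ schedule with the 1e-4..0.02 convention defined at
$T=1000$ and endpoints rescaled by $1000/T$ at smaller $T$, so
$\bar\alpha_T \approx e^{-10}$ and the terminal marginal matches the
$N(0, I)$ initialization at any $T$. Targets are mapped to $[-1, 1]$.
The network regresses the balanced combination
$v = \sqrt{\bar\alpha}\,\epsilon - \sqrt{1-\bar\alpha}\,y_0$
(an invertible reparameterization of noise prediction); the implied noise
estimate satisfies
$\hat\epsilon - \epsilon = \sqrt{\bar\alpha}(\hat v - v)$, so reverse-chain
updates never amplify the regression error — raw noise prediction is
noise-dominated at small $t$ and anatomy-starved at large $t$, which at this
scale makes ancestral sampling drift. The learned reverse variance
interpolates in log space between $\beta_t$ and the posterior variance
$\tilde\beta^{\text{post}}_t = \tfrac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t$,
trained by a KL term (weight 0.001) with the mean path detached. Isolated
outlier pixels in the ensemble mean are repaired by replacing the mean with
the pixel-wise median wherever the std image exceeds
`median + 5 * MAD` within the mask (threshold exposed); the rule is
idempotent because the flags depend only on the untouched std image.

**cGAN.** WGAN-GP with $\lambda = 10$, five critic steps per generator
step by default (the packaged desk study uses three, which leaves the
converged quality unchanged within margin and keeps its runtime in
minutes), Adam betas (0, 0.9). The critic avoids normalization layers (they
interfere with the pointwise gradient-norm penalty). The penalty *value* is
exact — one reverse pass yields $\partial d/\partial y$ at the interpolate —
and its parameter gradient is taken by a central finite difference along the
detached gradient direction (step $10^{-3}$), batched with the real/fake
terms; this sidesteps second-order backpropagation at the cost of two extra
critic evaluations. The generator loss is purely adversarial, with no pixel
reconstruction term. Desk-scale runs use a learning rate of $10^{-3}$;
at $2\times10^{-4}$ the critic's lead (a Wasserstein estimate stuck near
its maximum) persists for hundreds of steps before the generator catches up.

**Metrics.** SSIM uses a 7-wide uniform window, $K_1=0.01$, $K_2=0.03$,
data range 1, computed volumetrically (window fully inside; the map is
cropped by 3 voxels per side) — the implementation agrees with an
independent reference implementation to $10^{-6}$ and therefore needs all
volume dimensions ≥ 7. Boundary SSIM applies a slice-wise Sobel magnitude
with edge-replicated padding (so an additive intensity shift leaves the edge
map exactly unchanged), renormalizes both edge volumes by their shared
maximum, and reuses the volumetric SSIM. Slice-consistency SSIM compares
consecutive-slice 2D SSIM profiles. The perceptual distance follows the
layer-weighted feature-difference form with a pluggable extractor; the
default is a small fixed-seed random convolutional extractor so no
pretrained weights are needed (a pretrained feature stack can be substituted
through the same interface, and random convolutional features are a known
serviceable stand-in for ranking perceptual similarity at small scale).
Model comparison uses one-sided paired Wilcoxon signed-rank tests at 0.05
with zero differences dropped; the "best set" contains every model that no
other model beats significantly, so statistically indistinguishable models
share the title.

**OOD layer.** $\hat\sigma$ scores are min-max normalized over the pooled
validation scores before calibration (the normalization constants travel
with the calibration map). Isotonic calibration follows a five-fold protocol
over the in-distribution validation subjects, each fold joined by an equally
sized random subset of OOD validation subjects for class balance; per-fold
pool-adjacent-violators fits are averaged on a fixed 101-point grid and the
average is made monotone by a running maximum. ECE uses 10 equal-width bins;
the log loss clips probabilities at $10^{-6}$. Coverage curves use central
intervals from empirical quantiles (linear interpolation); highest-density
intervals would also be defensible but central intervals are symmetric in
the tails and match how the levels are stated.

# Study sizes

The packaged study runs at "desk scale": 32×32 slices, depth-2/width-8
networks, $T = 100$ diffusion steps, ensembles of $n = 10$, cohorts of ~10
training subjects with 4–8 slices each. These sizes make the full
train-sample-evaluate loop reproducible on a single CPU in minutes while
preserving every structural property of the full-scale design ($T = 1000$,
$n = 20$, 128×128 images), which remains available through the
configuration objects.

# What the desk-scale study does and does not show

On the exactly learnable (noise-free) task all four models recover the
cross-contrast map with masked SSIM well above 0.8, and the ensemble
machinery (mean/std/median, coverage, $\hat\sigma$) behaves as specified.
The $\hat\sigma$ OOD signal is the one quantity that does not scale down
gracefully. Within any single trained model the corrupted inputs shift
$\hat\sigma$ *consistently* (the within-group spreads are tight), but the
shift is only a fraction of a percent to a few percent of the score, and
its *direction* varies between training runs: the same protocol retrained
under a different seed can rank OOD above or below ID. The full-scale
effect rests on high-capacity networks reacting erratically off their
training manifold; depth-2, width-8 networks trained for minutes
generalize smoothly to corrupted inputs, so their ensemble spread stays
dominated by the sampler's own noise floor (Langevin injection for NCSN,
latent modulation for the cGAN) and the input-dependent component is at
the level of run-to-run variation. Desk-scale AUCs for the
$\hat\sigma$ detector are therefore reported but should be treated as
unstable; reproducing the detection result requires full-scale capacity
and training, not just the full-scale protocol.

# Known limitations

* The phantom's conditional variability (per-class jitter) is spatially
  constant per class; real uncertainty concentrates at boundaries.
* The annealed Langevin sampler takes one step per level; its chain runs
  ~20% hotter than the nominal schedule (the scale augmentation during
  training compensates).
* The gradient-penalty parameter gradient is exact only up to the
  finite-difference step ($O(\delta^2)$, $\delta = 10^{-3}$).
* Wilcoxon p-values use the normal approximation (ties are common in
  metric values after rounding).
* NIfTI volumes are written with an identity affine; no attempt is made to
  carry real-world orientation metadata.
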