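---
title: "Methods: simulating, classifying and calibrating spectrally barcoded single molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral barcode pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectramir)
```

## The measurement model

A dual-fluorophore reporter probe is a short (~30 bp) DNA construct carrying
two dyes a few nanometres apart — far below the diffraction limit, so both
emitters image to the same physical location. A pair of co-rotating
dispersing prisms in the emission path shifts each emitter's image along one
axis (here: image rows, increasing downward) in proportion to its emission
wavelength. A dual-dye probe therefore appears as a *dual-spot* point-spread
function (PSF), and the interspot distance identifies the dye pair — a
spectral barcode read out in a single exposure, with no channel splitting or
registration.

`spectramir` simulates this optical transformation and implements the full
quantification pipeline: synthetic scenes with ground truth, blob detection
and cropping, supervised crop classification, and confusion-corrected,
reference-normalized mixture composition estimates with resampling
uncertainty.

### PSF rendering

For one fluorophore, every 1 nm bin of its emission spectrum (multiplied by
the multiband filter transmission — the spectrum the camera actually sees)
contributes an isotropic 2-D Gaussian of standard deviation `sigmaPx`
(default **1.15 px**, the diffraction-limited spot width at this pixel
scale), displaced along the dispersion axis by the calibration curve
$d(\lambda)$. The summed image is normalized to unit total intensity and
multiplied by an *excitation efficiency*: the value of the excitation
spectrum at the laser line (with several lasers, the best single line — the
efficiency definition is per-line, and simultaneous excitation makes the
strongest line dominate). A dye pair is rendered by summing the two
single-dye images.

The dispersion curve is measured at a reference prism angle and scaled by
$\sin((180° - \mathrm{RPA})/2)$, where RPA is the relative prism angle;
co-rotating the prisms to 180° cancels the dispersion entirely. The default
acquisition angle is **177.5°**.

Numerical choices: a 1 nm wavelength grid, Gaussians truncated at $5\sigma$,
and separable row/column evaluation (all per-wavelength Gaussians share
$\sigma$ and column position, so the patch is an outer product of a row
profile and a column kernel — exact, not an approximation). Chromatic
axial-focus effects are not modeled; on real data they redistribute
intensity between the two spots without moving the peaks.

### Fixtures

Real vendor spectra are not shipped. `fixtureDye()` provides parametric
skew-Gaussian excitation/emission stand-ins for four commercial dye classes
(AF405/488/568/647-like), `fixtureFilter()` a five-band transmission curve
(bands at 440/521/607/694/809 nm, half-width 12.5 nm), and
`fixtureDispersion()` a monotone-cubic displacement curve with prism-like
$1/\lambda^2$ curvature spanning ~24 px across 400–850 nm after adjustment
to RPA 177.5°. All three are replaceable by CSV
(`wavelength_nm,value`). The default three-target panel pairs the 405-class
dye with each of the other three, giving three interspot distances separated
by gaps of more than 3 px — the panel-design criterion
(`panelDistinctness()`) that makes barcodes distinguishable at this
dispersion.

### Scene generation

`sampleGroundTruth()` draws molecule anchor positions by rejection sampling
with a margin (default 24 px, enough for the 24 × 10 crop box) and a minimum
pairwise separation (default 10 px). Brightness multipliers are log-normal
(default meanlog `log(1200)`, sdlog 0.3, in photon units) — chosen so the
brightest blob of a typical molecule peaks near SNR ~10 under the default
noise model; real single-molecule brightness distributions are instrument-
specific and unpublished, so these defaults are plausible rather than
calibrated. Spurious single-blob distractors (default 20% of the molecule
count) emulate false localizations. The camera model is Poisson shot noise
(unit gain by default) plus additive Gaussian noise with mean 0.3 and
configurable variance (default 25). A smooth low-order polynomial background
(default amplitude 20) is added *identically across FOVs*, so the pixel-wise
median subtraction removes it exactly; per-FOV jitter can be enabled to
stress the pruning step.

What the generator does **not** emulate: focal drift, photobleaching,
dye-specific blinking, camera gain structure, optical aberrations, or the
competitive-binding chemistry that skews real capture efficiencies. Passing
tests on synthetic scenes therefore demonstrates the correctness of the
*computational* pipeline — detection geometry, classifier mechanics and the
calibration algebra — not instrument-level performance. The calibration
step is designed precisely so that per-class efficiency differences shared
between mixture and reference cancel; the synthetic benchmark exercises that
cancellation mechanism.

## Preprocessing

1. **Background**: subtract the per-pixel median across all FOVs (robust to
   the sparse molecules, exact for the shared background).
2. **Pruning**: per FOV compute the mean of the positive median-subtracted
   pixels and the absolute mean of the negative ones — large values of
   either indicate bubbles, debris or a background that disagrees with the
   median. Both statistics are thresholded so that a target fraction of
   FOVs survives (default 80%). Rather than a hand-tuned absolute
   threshold, the rule is quantile-based: the `keepFraction` quantile of
   the maximum of the two statistics, a single shared threshold with no
   free constant. Ties are broken by FOV index; exactly
   `ceiling(keepFraction * n)` FOVs are kept.
3. **Denoising**: a pluggable slot (`none`, small-kernel `gaussian` /
   `median`, or an `external` array-in/array-out function through which a
   learned denoiser — e.g. a self-supervised network — can be attached).
   No neural denoiser is shipped: the substance of this package is the
   classification and calibration mathematics, and the pipeline is fully
   functional with `none`. The default is a light Gaussian blur
   (σ = 0.7 px), which improves detection SNR at a small, measured cost in
   localization bias (< 0.3 px).

## Detection and cropping

Blob finding is difference-of-Gaussians filtering (σ = 1.15/2.3 px),
8-neighborhood local maxima above a robust threshold — `kMad` (default 5)
MADs above the filtered image's median; interactive localization workflows
tune this threshold by visual inspection, and a statistical threshold is
the reproducible substitute — followed by 2-D Gaussian least-squares refinement
(Gauss–Newton on a 7 × 7 window) for subpixel position. Fits whose width
collapses below 0.7 px are rejected, excluding single-pixel localizations.

Localizations closer than `dMerge` (default 2 px, validated against the
panel's minimum interspot distance) are merged at their mean position,
iterated to a fixed point so merging is idempotent. Crop boxes that would
leave the FOV are discarded. Each surviving localization yields a 24 × 10
crop from both the median-subtracted and the denoised stack, anchored with
the blob at row 2 and columns 4–5 straddling the blob (0-based, rows along
the dispersion axis). Both blobs of a molecule are detected, so each
molecule produces two crops; only the top (short-wavelength) crop contains
the whole barcode, and bottom crops are absorbed by the classifier's noise
class — at least half of all crops are expected to be noise.

Ground-truth labeling (the stand-in for interactive visual tagging): a crop
is labeled with a molecule's class iff its anchor lies within 1 px of that
molecule's top-blob position; otherwise `noise`.

## Classification

Per crop: subtract the median of the edge pixels; reject the crop if any of
the four central top-blob pixels (the 2 × 2 block at rows 1–2 × cols 4–5 —
the anchor convention fixes which pixels "central" means) goes negative;
zero remaining negatives; divide by `k`, the anchor-block mean, so the
normalized anchor mean is exactly 1; add the horizontal mirror and keep the
right half (240 → 120 values, a mirror-invariant feature). `k` is kept as
the 21st feature — it carries the brightness information that normalization
removes from the shape.

Training: 90/10 train/validation split, then the training crops are
augmented with `nExtra = 2` noisy copies (pixel-wise Gaussian, SD 0.05 in
anchor-normalized units — "weak" made quantitative), tripling the training
set. Augmenting *all* labeled crops keeps the tripling factor exact and is
the default; `augmentMirOnly` restricts augmentation to the target-class
crops for workflows where the noise class is already abundant. PCA
(20 components) is fit on the augmented training set; the 20 coefficients
and `k` are standardized jointly to zero mean and unit variance (whether
`k` is standardized jointly with the coefficients — the simpler choice,
and what a generic feature pipeline does by default). An RBF-kernel SVM
with probability calibration classifies into the three target classes plus
`noise`. Hyperparameters (cost 10, kernel width 1/21 on unit-variance
features, i.e. the usual 1/d heuristic) are exposed in the configuration.

`classifyCrops()` *defines* the predicted label as the argmax of the
calibrated probability vector. Generic SVM implementations do not guarantee
agreement between their decision-value voting and their calibrated
probabilities; defining prediction through the probabilities removes that
inconsistency and makes the label and probability outputs of one model
coherent by construction. Crops rejected during preprocessing are assigned
to `noise` and flagged.

Evaluation: per-class recall $r_i = C_{ii}/\sum_j C_{ij}$ and precision
$p_j = C_{jj}/\sum_i C_{ij}$ from the confusion matrix (zero denominators
are flagged `NA`, never silently 0), and precision–recall curves by
thresholding the per-class probability between 0 and 1, summarized by
average precision (step integral; recall reaches 1 as the threshold
approaches 0).

## Calibration

Let $C_{ij}$ count crops with true label $i$ predicted as $j$, and $h$ the
predicted class counts of a data set. Two normalizations of $C$ circulate
in practice — dividing rows by row totals, or the column formula
$\hat C_{ij} = C_{ij}/\sum_k C_{kj}$ — and neither is consistent with the
correction relation $h = \hat C h'$ for a matrix oriented true-by-predicted.
This package therefore adopts the *generative* convention
$\hat C_{ij} = P(\mathrm{pred} = i \mid \mathrm{true} = j)$ (columns index
true classes and sum to 1), which is the unique choice making
$h = \hat C h'$ an exact identity on any labeled set — the package tests
enforce exactly that. The plain column formula remains available
(`convention = "column-literal"`) for comparison.

True counts are estimated as $h' = \hat C^{-1} h$ (condition number checked,
error above $10^8$); negative components, possible with a noisy $C$, are
clipped to zero with a warning rather than erroring, because the downstream
normalization requires non-negative counts. The mixture composition is the
element-wise ratio of corrected mixture counts to the corrected counts of an
equidistributed (1:1:1) reference sample, noise class dropped, normalized to
sum 1. Per-class capture efficiencies and classifier biases *shared* between
mixture and reference cancel exactly in this ratio — the central calibration
property, covered by an algebraic test.

### Uncertainty

Each of `nReps` (default 10,000) repetitions draws a *pair* of confusion
matrices from a multinomial model centred on $C$ — resampled per true-class
row with that row's total, which preserves the labeled-set class totals
(the partition into draws was unstated; per-row is the choice) — and
perturbs each count vector with Gaussian noise of SD `countCv` (default 5%)
of its mean, applied per class (per-class versus on totals was unstated;
per-class is implemented). Each vector is corrected with its own randomized
matrix, divided and normalized; singular draws are redrawn with a bounded
retry count. A 2-D Gaussian is fitted to the ensemble in isometric
simplex-plane coordinates; the reported composition is the fitted mean
mapped back to the simplex, and each class's half-width is twice the
standard deviation of the covariance projected onto that class's barycentric
gradient — "two standard deviations", a 95% interval per class.

## Problem sizes and reproducibility

The package's standard synthetic benchmark — used by the test suite and by
`scripts/acceptance.R` — trains on single-species scenes sized to give about
1,500 labeled crops per class, calibrates on a 1:1:1 mixture of about 5,000
molecules (confusion matrix from a 4,000-crop labeled subset) and tests on a
2:5:3 mixture of the same size; the uncertainty bound is additionally
evaluated on larger mixtures totalling roughly 60,000 classified crops. The
high-SNR classifier property is checked on a sparser, brighter scene
(minimum separation 20 px, narrow brightness distribution) so that every
crop contains a single molecule at peak SNR ≥ 10 — the regime the property
describes; at the default density about one crop in ten contains a
neighbour's blob and is pushed into the noise class, which is the expected
behaviour, not a defect. All stage seeds derive deterministically from one
global seed (`stageSeed()`), and a rerun with the same configuration
reproduces every CSV/JSON artifact.

## Known limitations

* Dual-dye barcodes only; 3- and 4-dye probes and bead-based references are
  out of scope.
* The simulator ignores chromatic focal shifts, so simulated intensity
  ratios between the two spots are idealized.
* The pruning rule and detection threshold are statistical rules chosen
  for reproducibility; absolute detection counts on real data would need
  instrument-specific re-tuning.
* The uncertainty model captures counting noise, confusion-sampling noise
  and a 5% count perturbation; other error sources (e.g. drift between
  acquisitions) are not modeled.
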