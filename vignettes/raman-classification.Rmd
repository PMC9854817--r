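---
title: "Serum Raman classification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum Raman classification: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramandx)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter and why their defaults were chosen, what
the synthetic data does and does not emulate, and where the design was
genuinely open.

## The diagnostic problem

Serum Raman spectra of healthy controls (HC), breast cancer patients (BC)
and ductal carcinoma in situ patients (DCIS) share nearly identical peak
positions; what differs between groups is the *relative intensity* of
bands such as the β-carotene doublet (1154, 1514 cm⁻¹) and the
protein/lipid bands (950, 1004, 1445, 1576 cm⁻¹). A classifier therefore
has to read small multivariate intensity ratios off a signal dominated by
a fluorescence background one to two orders of magnitude smoother than the
peaks. The pipeline mirrors the standard workflow: denoise, remove the
background, normalize away overall intensity, then classify.

## The synthetic cohort generator

Patient spectra for this problem are not publicly available, so the
package ships a generator whose defaults encode the cohort structure the
analysis assumes, and every downstream stage is developed and tested
against it.

* **Cohort**: 241 HC, 463 BC, 100 DCIS samples (804 total), one averaged
  spectrum per sample, on a 1698-point axis spanning 400–4000 cm⁻¹
  (spacing ≈ 2.12 cm⁻¹).
* **Peaks**: Lorentzians at the eleven canonical serum positions. The
  Lorentzian is the natural Raman line shape; the default FWHM of 16 cm⁻¹
  is comfortably above a ~4.5 cm⁻¹ instrument resolution, so peaks are
  resolvable on this axis. Base amplitudes make 1154 and 1514 cm⁻¹ the
  strongest bands.
* **Class effect**: multiplicative per-class amplitude factors — the
  carotenoid bands attenuated in BC (×0.55) and intermediately in DCIS
  (×0.75), protein bands mildly elevated (×1.30 BC, ×1.15 DCIS). The
  direction (carotenoids down with disease, proteins up) follows the
  qualitative picture for serum carotenoid depletion in cancer; the
  magnitudes are a modelling choice, since no quantitative between-group
  intensities are available. They are placeholders, exposed in
  `peak_spec()`, and the tests treat them as free parameters (the
  acceptance suite includes a no-signal control with all multipliers 1).
* **Background**: a degree-3 polynomial in the rescaled axis coordinate,
  positive everywhere and comparable in magnitude to the peak heights, so
  baseline correction is stressed realistically.
* **Noise model**: each sample draws one lognormal amplitude jitter per
  peak (`jitter_sd` = 0.05 on the log scale; multiplicative, keeping
  intensities positive), then `replicates = 5` acquisitions with i.i.d.
  additive Gaussian noise (`noise_sd` = 0.02 intensity units) are averaged
  — emulating the practice of acquiring five spectra per serum drop and
  analysing their mean. Averaging shrinks the noise standard deviation by
  ≈ 1/√5, which the tests verify.
* **Reproducibility**: each sample's random stream is derived from the
  root seed by a counter, so generation is order-independent and the
  dataset is a pure function of its configuration.

What the generator does **not** emulate: cosmic-ray spikes, detector
etaloning, wavenumber miscalibration, peak-position shifts, correlated
(pink) noise, or any SERS effects. Consequently, passing tests demonstrate
that the pipeline's machinery is correct and that the protocol can recover
known structure — they say nothing about accuracy on real patient sera,
whose between-group effect sizes are unknown to this package.

## Preprocessing

The three stages run per spectrum, in a fixed order (smooth → baseline →
scale), which a regression test pins.

**Savitzky–Golay smoothing** (window 11 points, order 3, via
`signal::sgolayfilt`). The filter is exact on polynomials up to the fit
degree, so peak shape and width are preserved while high-frequency noise
is attenuated. The window/order were not externally prescribed; 11/3 is
the common choice for ~2 cm⁻¹-spaced spectra — wide enough to average ~5
noise samples per point, narrow enough (≈21 cm⁻¹) not to clip a 16 cm⁻¹
FWHM Lorentzian.

**airPLS baseline removal** (λ = 1e5, ratio = 1e-3, maxiter = 30). The
iteration solves the weighted Whittaker system (Wₜ + λDᵀD)z = Wₜy and
re-weights: points at or above the baseline get weight 0, points below it
get wᵢ = exp(t·|dᵢ|/|d⁻|). It stops when the negative-residual mass drops
below ratio·‖y‖₁ (or vanishes — the all-zero spectrum is declared
converged immediately, since the relative criterion is vacuous there), or
at `maxiter`. λ trades smoothness against fidelity: 1e5 on a 1698-point
axis yields a baseline stiff on the ~100-point scale of fluorescence
undulations yet unable to follow 8-point-wide peaks. The system is
pentadiagonal; it is assembled sparsely (`Matrix`) and solved exactly in
O(L) memory. Two numerical properties are tested: baseline + corrected
reconstructs the input to float precision, and the iteration is exactly
equivariant under constant shifts *when iteration counts match* — the
stopping rule itself is scale-dependent (it compares against ‖y‖₁), so
the equivariance test forces equal iteration counts.

**Min–max scaling** maps each spectrum affinely onto [0, 1]. Scaling is
per-spectrum because the diagnostic signal is relative intensity; a
constant spectrum is a hard error rather than a silent zero. The ℓ₂
(vector-norm) alternative is deliberately not offered.

One open question was whether smoothing should precede replicate
averaging; the package assumes averaged input (averaging is part of
acquisition, preprocessing starts from the averaged spectrum).

## The classifiers

**1D CNN.** Architecture: conv(8 channels, kernel 3) → batch-norm → tanh →
conv(16, kernel 3) → tanh → max-pool(width 3, stride 3) → flatten →
dense(3) → softmax. Three structural choices deserve comment:

* *Valid (unpadded) convolutions with floor division in the pool* are the
  only combination under which a 1698-point input flattens to
  9024 = ⌊(1698 − 2 − 2)/3⌋ × 16 features; "same" padding would give
  9056. The acceptance suite checks the arithmetic against an actual
  forward pass.
* *Exactly one batch-norm layer*, between the convolutions. During
  training, an exponential running average (momentum 0.9, seeded from the
  first batch) tracks the channel statistics so the per-epoch validation
  curves can be computed in inference mode; after the last epoch the
  inference statistics are replaced by the exact population mean and
  variance of the pre-normalization activations over the training set
  under the final weights, the canonical inference rule for batch
  normalization.
* *tanh on both convolution outputs, no hidden dense layer*: the
  9024-node layer is the flatten output feeding the 3-node softmax.

Training minimizes categorical cross-entropy with Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8), batch 16, learning rate 0.001, samples reshuffled
each epoch from the run seed. A stratified 20% of the training set is held
out for per-epoch validation curves (the holdout fraction is a package
choice; nothing prescribes it). Epoch-level train metrics are batch
averages, validation metrics are computed in inference mode. Training can
optionally keep the weights of the epoch with the best validation accuracy
(`restore_best`, off by default): with few minority-class samples the late
trajectory sometimes oscillates between basins that treat the intermediate
DCIS class differently, and validation checkpointing — which never sees
the test set — is the standard guard. The end-to-end acceptance
experiment enables it. The
implementation is vectorized base R (im2col convolutions backed by BLAS
matrix products); gradients are verified against central finite
differences in the tests, and training is bit-reproducible given the seed
under single-threaded BLAS. A conv-layer bias before batch normalization
is mathematically redundant (the normalization absorbs it); it is kept for
structural fidelity and its gradient is verified to vanish.

**Baselines.** KNN classifies by majority vote among the k nearest
training spectra in Euclidean distance, with deterministic tie-breaking
(lowest class index) and vote fractions as probability scores; k is chosen
from {1, 3, …, 15} by cross-validation. The random forest
(`randomForest`) is tuned over trees {100, 200, 500} × depth {5, 10,
unlimited}, with depth d enforced as a cap of 2^d terminal nodes since the
underlying implementation bounds tree size by leaf count, not depth. The
SVM uses an RBF kernel with grid search over C ∈ {0.1, 1, 10, 100} and
γ ∈ {1e-4, …, 1}; multiclass problems are decomposed one-vs-rest (the
decomposition was an open choice; one-vs-rest makes the per-class scores
directly usable for ROC analysis), with Platt-calibrated per-machine
probabilities normalized across classes. All grids are configuration,
not constants.

**Model selection** is stratified 5-fold cross-validation maximizing mean
fold accuracy, ties broken by grid order. The fold assignment, all
shuffles and every stochastic fitter derive from explicit seeds, so the
entire experiment is reproducible to the byte (`run_full_experiment`
writes a report bundle whose JSON is identical across reruns of the same
configuration — an acceptance-tested property).

## Evaluation protocol

The 7:3 split is stratified: class c contributes ⌊0.7·n_c⌋ training
samples, the only rounding rule that reproduces the canonical cohort
cells 168/324/70 vs 73/139/30. Pairwise binary experiments restrict the
*same* partition to each class pair — a sample keeps its train/test
membership — and refit each family with the hyperparameters selected in
the three-class run; the positive class is the second of the pair (the
later-stage condition: BC vs HC, DCIS vs HC, DCIS vs BC), the convention
under which the published sensitivity figures are recall of the disease
class. Sensitivity/specificity with an absent truth class are flagged
`NA`/undefined rather than silently 0. Three-class ROC is one-vs-rest,
macro-averaged, with trapezoidal integration; tied scores share a
threshold, making the binary AUC identical to the Mann–Whitney pair
statistic (tested against brute-force pair counting and against pROC).
Displayed percentages round half-up to 2 decimals; raw values are kept in
the JSON report.

## Problem sizes used by the test and acceptance suites

Unit tests run on reduced axes (32–256 points) and small cohorts so the
whole suite stays fast; the properties they check are size-independent.
The end-to-end acceptance experiment runs the full 804-sample default
cohort over three seeds with the CNN trained for 40 epochs — the regime
in which its accuracy and loss curves have already converged — rather
than the nominal 100; a shorter training can only make its ≥0.95
accuracy / ≥0.99 AUC bounds harder to meet. The determinism check uses a
deliberately small configuration, since byte-identity is scale-invariant.

## Known limitations

* The between-class effect sizes are invented placeholders; real serum
  cohorts may be far less separable, and the near-perfect synthetic
  accuracies should not be read as clinical performance.
* airPLS endpoints are unweighted in the reweighting step; strongly
  curved backgrounds at the spectrum edges can bias the first/last few
  points of the baseline.
* The CNN is CPU-only and single-threaded by design; at the default 100
  epochs on 804 spectra a full training takes a few minutes.
* No despiking, calibration transfer, or batch-effect handling: the
  pipeline assumes spectra already share an exact wavenumber axis.
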