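---
title: "Post-hoc labeling of M/EEG recordings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-hoc labeling of M/EEG recordings: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posthoclab)
```

## The problem this package addresses

Developing and benchmarking neural decoding algorithms requires multichannel
M/EEG datasets with large amounts of labeled data. Real experimental
recordings provide authentic signal dynamics but come with small usable
dataset sizes, labels tied to one paradigm, and — when the label is a
behavioral surrogate — an unknown and uncontrollable amount of label noise.
Fully synthetic signal generators control everything but rest on strong
assumptions about brain dynamics that limit how far their conclusions
generalize.

Post-hoc labeling takes a third route: it derives *new* labels from a
subspace of the recording itself. The continuous sensor data are projected
onto a source space, one source is selected as the target, and the
band-power envelope of that source becomes the continuous target variable.
Because every step is a deterministic function of the raw recording and the
configuration, the labels are exactly recoverable — noise-free from the
decoder's point of view — while the signals retain real (or realistically
simulated) dynamics. Label noise can then be *injected* in controlled doses,
turning noise level, dataset size, and label variability into experimental
knobs.

## The generative model

Sensor data follow the linear forward model
$$X = A S + E,$$
with $X \in \mathbb{R}^{N_c \times N_t}$ the channels-by-samples recording,
$A \in \mathbb{R}^{N_c \times N_s}$ the lead field whose columns are spatial
patterns, $S$ the source time courses, and $E$ i.i.d. Gaussian sensor noise
with isotropic covariance $\sigma^2 I$.

`simulate_sources()` plants one narrowband oscillatory target — a sinusoidal
carrier at the center of the target band, amplitude-modulated by a smooth
positive random envelope — among background sources with a $1/f$ power
spectrum (white-noise Fourier amplitudes shaped by $f^{-1/2}$; the spectral
exponent of $-1$ in power is an assumption, chosen as the canonical
"pink-noise" shape of resting M/EEG spectra). The planted envelope is
returned as ground truth, so every downstream stage can be validated against
it.

### The envelope model

The envelope is the magnitude of lowpass-filtered Gaussian noise
(rectification *after* smoothing), cut off at $1/\tau$ for timescale $\tau$,
then offset so that its minimum exceeds $0.1\times$ its mean and normalized
to unit mean. The half-normal marginal gives a coefficient of variation of
about $0.76$ before the offset — the strong waxing and waning characteristic
of real band-power envelopes, whose epoch-wise power distributions are
heavy-tailed (approximately gamma). Rectifying *before* smoothing would
instead produce an almost constant envelope (the lowpass keeps only the mean
of $|g|$ plus a small fluctuation), which would make epoch labels
indistinguishable from per-epoch power-estimation noise; this is why the
order matters. The floor at $0.1\times$ the mean prevents degenerate
zero-power epochs. `envelope_timescale_s = Inf` forces a constant envelope
(a pure sinusoid), useful for calibration tests.

### Default study conditions

Synthetic benchmarks use, and `make_benchmark_dataset()` defaults to:
20 channels, 1 target plus 10 background sources, 120 Hz sampling, an
8–12 Hz target band, 1-s epochs, an envelope timescale of 2 s (slow enough
for epoch-to-epoch label structure, fast enough for label contrast across a
few hundred epochs), and a broadband sensor SNR of 0 dB — "moderate": noise
power equal to total source power at the sensors, so the target is clearly
present in its band yet far from dominating the broadband signal. The
synthetic lead field has spatially smoothed unit-norm random columns;
user-supplied lead fields are loaded from delimited text and deliberately
*not* renormalized.

## Inverse mapping

Two subspace projections are provided.

**Minimum-norm estimation** (anatomically constrained). With an identity
noise covariance and an $\ell_2$ penalty, the regularized inverse is
$$\hat S = A^\top (I + \lambda A A^\top)^{-1} X.$$
A technical subtlety: the minimizer of
$\lambda\,\lVert X - AS\rVert^2 + \lVert S\rVert^2$ is $\lambda$ times this
expression. The two differ only by a global positive factor, which cannot
change the *order* of envelope-derived labels, so either form yields
identical discrete labels and identically-ranked continuous labels. Both are
exposed (`form = "plain"` and `form = "ridge"`); the plain form is the
default. The linear system is solved directly rather than by explicit
inversion; the result matches the dense-inverse computation to near machine
precision.

**Regularization by generalized cross-validation.** `select_lambda_gcv()`
minimizes
$$\mathrm{GCV}(\lambda) = \frac{\lVert X - H_\lambda X\rVert_F^2 / N_t}
{\left(\mathrm{tr}(I - H_\lambda)/N_c\right)^2},
\qquad H_\lambda = A A^\top (A A^\top + \lambda I)^{-1},$$
over a log-spaced grid (default 30 points in $[10^{-6}, 10^2]$), breaking
ties toward the larger, more conservative $\lambda$. $H_\lambda$ is the
standard ridge influence matrix, whose fitted values interpolate between the
full least-squares fit ($\lambda \to 0$) and zero ($\lambda \to \infty$);
this is what makes GCV behave as intended — structure drives $\lambda$ to
the small end of the grid, pure noise to the large end. (An influence matrix
built from the plain-form fitted values $A A^\top (I + \lambda A A^\top)^{-1} X$
lacks the least-squares limit and produces an essentially flat GCV curve on
clean data; it is not used.)

**Independent component analysis** (data-driven). A fastICA with the
log-cosh contrast and deflation (at most 500 fixed-point iterations per
component, convergence tolerance $10^{-6}$) estimates an unmixing matrix
$\Phi$ with $\hat S = \Phi X$. Twenty components are extracted by default,
clipped to the channel count with a warning; rank-deficient data below the
requested component count is an error that names the achieved rank. The
decomposition is deterministic given a seed. Because ICA fixes neither sign
nor scale, each component's sign is set so its skewness is non-negative
(envelope extraction is sign-invariant; the convention exists purely for
reproducibility), and `rescale_sources()` restores an interpretable scale:
each source is $\ell_2$-normalized and multiplied by the average over
channels of its inner product with each channel's time course. The
normalization step makes the result invariant to the sources' original
scale.

**Target selection** is a policy hook — a fixed index, a seeded random draw,
or the component with the highest mean power in a band of interest. No
automatic artifactual-component classifier is bundled; component screening
is the user's responsibility via the policy interface.

## Label extraction

The pipeline in `posthoc_label()`:

1. **Artifact screening** on the broadband recording: bandpass to
   0.7–25 Hz, cut into the same non-overlapping windows used for epoching,
   and reject any window in which some channel's peak-to-peak amplitude
   *strictly* exceeds 80 µV (both band and threshold configurable).
2. **Narrowband filtering** to the target band (default 8–12 Hz) with a
   5th-order Butterworth filter applied forward and backward (zero phase).
   Filters are designed and applied as second-order sections; a single
   order-10 polynomial transfer function can be numerically unstable at
   narrow relative bandwidths, biquads are not. Zero-phase filtering is a
   choice: offline pipelines favor it because it preserves envelope timing;
   it is anticausal, so studies emulating online decoding should treat
   filtered edges with care.
3. **Projection and selection** as above.
4. **Envelope**: $z = |\mathcal{H}\{s_z\}|$, the magnitude of the analytic
   signal of the selected source. The first and last half second are less
   reliable (FFT edge effects); validation metrics in the test suite exclude
   them, but the labels themselves are not trimmed — no principled trimming
   rule exists, and epoch averaging dilutes the effect.
5. **Epoching** into non-overlapping windows from sample 0 (any original
   trial structure is deliberately ignored), dropping the trailing partial
   window and all rejected windows from data and labels alike. The epoch
   label is the window mean of $z^2$ (average power). Reading the envelope
   itself as the label is supported via `label_mode = "amplitude"`; power is
   the default because the target variable is conceptually a band-*power*
   surrogate, and the two differ only by a monotone transform of the
   envelope scale, which leaves discrete labels untouched for constant
   within-window envelopes.
6. **Discretization** (optional): binary labels split at the median (class 1
   at or below), ternary labels at the exact lower and upper tertiles,
   linear-interpolation percentiles, ties always to the lower class. The
   same tie rule applies everywhere percentiles appear, including the
   z-variance tertile assignment of sources (`variance_tertiles()`).

Every stage is a pure function of (data, configuration, seed), so labeling
the same recording twice is bit-identical, and `relabel()` regenerates the
labels from the raw recording plus the stored metadata alone. This
determinism is the framework's defining property and is asserted as such in
the test suite.

## Label-noise models

For continuous labels, intensity $\xi \in [0, 1)$ yields
$$z_n = z + \sqrt{\tfrac{1 - (1-\xi)^2}{(1-\xi)^2}}\,\sqrt{\mathrm{var}(z)}\,\eta,
\qquad \eta \sim \mathcal{N}(0, 1),$$
so the population correlation between clean and noisy labels is exactly
$1 - \xi$ and the variance inflates by $1/(1-\xi)^2$. $\eta$ is *standard*
normal — the explicit $\sqrt{\mathrm{var}(z)}$ factor implies unit variance —
and $\mathrm{var}(z)$ is the sample variance with denominator $n - 1$.

For discrete labels, $\xi \in [0, 1]$ sets the flip probability: each epoch
keeps its class with probability $1 - \xi/2$, otherwise the label is
replaced uniformly by one of the remaining classes. At $\xi = 1$ agreement
drops to one half. Flip decisions and replacement draws come from a single
seeded stream in epoch order. Only i.i.d. noise is modeled; temporally
structured label corruption is out of scope.

## Decoders

**CSP.** Class covariances $C_{1,2}$ are epoch means of
$X(e)X(e)^\top / T$ — epochs arrive bandpassed, hence effectively zero-mean,
so no per-epoch centering is applied. The filters solve the generalized
eigenproblem $(C_1 - C_2)\,w = \lambda\, C\, w$ with pooled covariance
$C = C_1 + C_2$ (using the mean instead changes eigenvalues, not
eigenvectors). Epoch covariances are not trace-normalized by default (a
configuration choice left open in the literature); the two eigenvectors at
the extreme eigenvalues are retained, their log-variance features feed a
shrinkage-regularized LDA. The generalized eigenproblem is solved by
symmetric whitening with an eigenvalue floor of $10^{-10}$ relative to the
largest eigenvalue; rank-deficient pooled covariances additionally trigger a
shrinkage repair with a warning.

**Regularized LDA.** The pooled within-class covariance is shrunk toward a
scaled identity with the analytic Ledoit–Wolf intensity; no cross-validation
is involved. Decision scores are continuous and monotone in the posterior of
the second class — AUC is computed from these scores, not from hard labels.

**SPoC.** With $C$ the mean epoch covariance and
$C_z = N^{-1}\sum_e z(e)\,X(e)X(e)^\top/T$ the label-weighted mean, the
filter is the leading generalized eigenvector of $C_z w = \lambda C w$.
Labels are standardized to zero mean and unit variance before weighting
(raw-label weighting is available via `standardize = FALSE`); without
centering the leading eigenvector tends to the dominant-power direction
rather than the comodulating one. The filter is $\ell_2$-normalized, its
orientation fixed through the associated spatial pattern $C w$ (positive
leading coefficient); predictions are per-epoch variances of the filtered
signal, and choosing the *largest* eigenvalue makes the training covariance
between predictions and labels non-negative by construction.

## Benchmarking harness

Cross-validation is chronological: contiguous temporal blocks, earliest
blocks largest when sizes cannot be equal. Shuffled folds leak information
between train and test through the temporal autocorrelation of band-power
envelopes (the envelope timescale spans epochs); contiguous blocks avoid
this.

`evaluate_cell()` takes the chronologically first $n$ epochs of a dataset —
preserving the chronological rationale; random subsampling would break the
contiguity that motivates the fold structure — corrupts the *training*
labels at intensity $\xi$, and scores each fold with AUC (binary), plain
accuracy (ternary; classes are near-balanced by construction), or Pearson
correlation (regression). By default the test labels stay clean: the noise
models corrupted *supervision*, and scoring against ground truth isolates
the decoder's robustness from irreducible evaluation noise.
`noisy_test = TRUE` scores against the corrupted labels instead.

The two evaluation modes answer different questions, and the distinction
matters at high noise. Scored against clean labels, a covariance-based
decoder does *not* fall to chance even at severe training noise: symmetric
label noise shrinks the population covariance contrast
($C_1' - C_2' = (1 - 2p_\text{flip})(C_1 - C_2)$, and the weighted
covariance scales with the label correlation) without rotating it, so the
learned filter direction survives until sampling noise swamps the shrunken
contrast. For SPoC the clean-label score is additionally biased upward on
data with a single dominant planted source: a filter anywhere near $\pm$ the
target direction predicts the true envelope regardless of how it was found,
so even information-free training labels yield positive test correlations.
A *null* reference — "the labels carry no information, the decoder must
score at chance" — therefore requires scoring against the corrupted labels
at maximal intensity, where they are independent of the data by
construction; that is how the chance-level checks in this package are
defined. Monotone degradation with $\xi$, in contrast, is asserted in the
default clean-label mode.

`run_sweep()` enumerates the factorial grid tertile × dataset size × noise ×
seed, emits one long-format record per fold, and caches finished cells in a
directory keyed by a hash of the cell configuration, making large sweeps
resumable. The bundled sweep defaults span 50–2,000 epochs and
$\xi \in \{0, 0.05, \ldots, 0.8\}$. The package's own acceptance runs use a
reduced scale — 400 epochs, five noise levels, ten seeds — sized so the
complete computation stays in the tens of seconds on a single core;
conclusions at that scale reproduce the qualitative shape (flat, then
falling) of the degradation curves, not their exact positions.

## What the simulations do and do not show

The generator provides exact ground truth and controlled conditions, which
is what the correctness tests need. It does not emulate several features of
real recordings: non-stationary source mixing (both inverse methods assume a
stationary projection), multiple simultaneously active narrowband sources in
the target band, ocular/muscle artifacts (the rejection stage is exercised
with constructed amplitude outliers, not physiological artifact shapes),
realistic volume-conduction geometry (the synthetic lead field is smooth
random, not anatomical), or line noise. Passing tests on synthetic data
therefore demonstrates algorithmic correctness and calibrated statistical
behavior — not that any particular real dataset will yield decodable
post-hoc labels. For real data, the component-selection policy and the
artifact threshold are the knobs that matter most, and sources should be
screened before one of them is promoted to target.

## Numerical choices, collected

* Butterworth filters: analog prototype, bilinear transform, second-order
  sections; zero-phase application with odd-reflection padding
  (`min(n - 1, max(24, 12 * n_sections))` samples per edge).
* Hilbert envelope: FFT analytic signal; length preserved; no trimming.
* Percentiles: linear interpolation (type 7); ties to the lower class.
* Generalized eigenproblems: symmetric whitening, eigenvalue floor
  $10^{-10}$ relative.
* GCV grid: 30 points, log-spaced in $[10^{-6}, 10^2]$; ties to larger
  $\lambda$; degenerate single-point grids return that point.
* ICA: log-cosh, deflation, 500 iterations, tolerance $10^{-6}$, seeded
  random initialization, skewness sign convention.
* Randomness: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; seeds are recorded in output metadata.
* Degenerate inputs error loudly (all-equal labels, zero-variance targets,
  rank-deficient data) or are flagged (zero-norm sources, degenerate folds
  return `NA` and are reported in `folds_used`), never silently absorbed.
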