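---
title: "Nonlinear resting-state EEG screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear resting-state EEG screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the approach

Depressive states leave signatures in the complexity of spontaneous
brain dynamics that linear band-power descriptions capture poorly.
`restingEEG` implements a fully data-driven screening pipeline for
eyes-closed resting-state EEG that (i) reduces a multichannel recording
to six nonlinear complexity features on a small set of electrodes, and
(ii) classifies subjects as depressive (DEP, label 0) or control (CTL,
label 1) with either simple baselines or small recurrent networks. The
pipeline selects its own operating point — time-window span, electrode
group and feature combination — from cross-validated baselines and
paired fold-wise t-tests rather than from anatomical priors.

Because clinical EEG with depression labels is not redistributable, the
package ships a synthetic cohort generator that plants a known class
effect in known electrodes. Every downstream stage is tested against
that ground truth, and a null configuration of the same generator
provides the negative control.

# The synthetic cohort generator

Each channel is $1/f^\beta$ coloured noise obtained by spectral shaping
of white Gaussian noise (amplitude spectrum multiplied by
$f^{-\beta/2}$, DC removed, inverse FFT, standardised), scaled to a
10 µV background SD, plus a 10 Hz alpha oscillation with random phase,
a shared coloured background common to all channels of a subject
(weight 0.3, a crude surrogate for volume conduction), and independent
white sensor noise. The defaults emulate the study conditions the
pipeline targets: 24 controls and 26 depressive subjects, a 52-channel
10-20 montage at 500 Hz, a trigger marking the eyes-closed condition
with a 2 s lead-in, and at least 17 s of signal after it (3 min by
default).

The class effect is injected only on FC2, AFz and F2: DEP subjects draw
those channels with a larger spectral exponent (`betaDep`, default 1.5
vs 1.0) and a larger alpha amplitude (6 vs 4 µV). For $1/f^\beta$ noise
the detrended-fluctuation exponent is approximately $(\beta + 1)/2$, so
a $\beta$ separation of 0.5 moves DFA by about 0.25 on the affected
channels and also lowers spectral entropy — exactly the kind of
distributed, nonlinear difference the feature set is designed to
detect. The source publications for this class of pipeline give only
distributional summaries of how the groups differ, so these effect
sizes are free parameters of the generator; 0.5 was fixed once as a
moderate, clearly recoverable effect and is not calibrated further.
What the generator does **not** emulate: artifacts (blinks exist only
as an optional injector for robustness experiments), non-stationarity
across the recording, inter-subject montage variation, and realistic
cross-channel covariance beyond the single shared component. Passing
tests therefore demonstrate internal correctness and recoverability of
a planted effect, not clinical performance on real EEG.

# Preprocessing

The chain reproduces standard resting-state practice: a 0.1–120 Hz
passband, a 50 Hz mains notch, a 90 Hz low-pass, and common average
referencing. Filters are zero-phase (forward–backward) 4th-order
Butterworth designs; the notch is an RBJ biquad with Q = 30. The
passband edge at 120 Hz is applied even though the subsequent 90 Hz
low-pass makes it nearly inert, preserving the stated order of
operations. Artifact removal is a pluggable hook with a pass-through
default — synthetic inputs are clean by construction, and artifact
subspace reconstruction is an external published algorithm, not part of
this package's contribution.

After filtering, `span` seconds are cropped from the eyes-closed
trigger onward and resampled to 200 Hz by Fourier-domain truncation
(ideal band-limited resampling; the 90 Hz low-pass guarantees no
content near the new Nyquist). The recording is then split into
consecutive non-overlapping 1 s windows of exactly 200 samples; each
channel row of each window is scaled to unit L2 norm, making windows
scale-free, and a trailing remainder shorter than one window is
dropped. Windows inherit the subject's class label. Sample indexing is
1-based throughout, following R convention.

# The six complexity features

All features are computed per channel per window and then averaged over
the selected electrodes. Entropies use base-2 logarithms and are
normalized to $[0,1]$ where a normalizer exists.

* **Permutation entropy** — Shannon entropy of the ordinal-pattern
  distribution (order 3, delay 1); ties are broken by order of
  appearance, patterns are indexed by their Lehmer code; normalized by
  $\log_2 m!$.
* **Sample entropy** — $-\ln(A/B)$ with template length $m = 2$,
  Chebyshev tolerance $r = 0.2 \cdot \mathrm{SD}$ of the window,
  self-matches excluded; pair counting is implemented in C++. $A = 0$
  or $B = 0$ yields NaN (undefined), never a silent 0; a constant
  window ($r = 0$) is a degenerate-input error.
* **Spectral entropy** — entropy of the Welch PSD (Hann window,
  segments of min(256, n) samples, 50 % overlap, mean detrend per
  segment) normalized to a distribution; divided by $\log_2$ of the bin
  count.
* **SVD entropy** — entropy of the normalized singular values of the
  order-3, delay-1 embedding matrix, divided by $\log_2 3$.
* **DFA exponent** — slope of log RMS fluctuation of the linearly
  detrended integrated profile versus log box size, boxes log-spaced
  from 4 to $n/4$ (10 sizes). At the 200-sample window length the
  largest box is 50 samples; the estimator runs without error but has
  high variance, which is the main reason features are averaged over
  electrodes and many windows.
* **Higuchi fractal dimension** — negative slope of $\log L(k)$ versus
  $\log k$ for $k = 1..10$ with the standard curve-length
  normalization.

The hyperparameters follow the defaults of the feature-extraction
library conventionally used for this feature set (order-3 embeddings,
$m = 2$, $r = 0.2\,\mathrm{SD}$, kmax 10, Welch PSD), since the
methodology this package reproduces fixed no others. Features are
computed on the L2-normalised windows; all six are invariant or nearly
invariant to the window scale, so this choice matters little, but it is
stated here because it is a genuine ambiguity. Every estimator is
checked against an independent brute-force oracle in the test suite,
and against analytic limits (white noise: DFA 0.5, Higuchi 2, spectral
entropy 1; Brownian motion: DFA 1.5; ramps: Higuchi 1, permutation
entropy 0).

# Selection procedures

All three selection stages score candidates with the same baseline: a
logistic regression on standardized features (scaler fit on the
training fold only) under stratified k-fold cross-validation (k = 10 by
default; the exploratory electrode step of the reproduced methodology
reports five folds in one place and ten in another, so k is a config
parameter). Fold-wise accuracies are compared with two-sided paired
t-tests at $\alpha = 0.05$, pairing scores by fold index. Identical
score vectors are treated as "no evidence of a difference" (p = 1); a
constant nonzero difference as deterministic (p = 0).

* **Span**: candidate spans 1, 3, …, 17 s. The chosen span is the
  smallest whose scores are not significantly lower than those of every
  larger span — the smallest-non-inferior rule, with ties broken toward
  smaller spans. On synthetic cohorts with a strong planted effect even
  1 s windows can be sufficient, so the chain may legitimately settle
  below 15 s; classifier training and evaluation in the acceptance
  analyses additionally report the 15 s operating point, the fixed
  choice of the methodology being reproduced.
* **Region**: one baseline per fully covered region of the shipped
  26-region Desikan association table, with the two exploratory
  features (Higuchi + sample entropy) averaged over the region's
  electrodes. Highest mean wins; among candidates statistically
  indistinguishable from the best, the fewest-electrode region (then
  lexicographic order) is preferred — the parsimony that selects the
  three-electrode caudal anterior-cingulate group over a five-electrode
  tie.
* **Features**: the six features are ranked by mutual information with
  the class label, estimated by a k-nearest-neighbour
  (Kraskov/Ross-type) estimator for continuous features against a
  discrete target, k = 3, with a tiny seeded jitter to break ties —
  deterministic given the seed; constant features get MI 0 and rank
  last. Cumulative prefixes COMB0..COMB5 of the ranking are evaluated
  under identical folds; the full set is retained unless a shorter
  prefix is significantly better.

Cross-validation splits at the **window** level by default, mirroring
the vector-level splitting of the reproduced methodology. Windows of
one subject can then appear in both training and test folds, so
accuracies must be read as window-classification performance, not
subject-level generalization — near-perfect scores under this scheme
partly reflect that leakage. Subject-level splitting can be emulated by
evaluating held-out cohorts with `externalValidate()`, which refits
nothing.

# Classifiers

LR (standardized `glm`) and an RBF SVM (C = 1) are the machine-learning
side; the deep side comprises an MLP (64–32 ReLU), a CNN (two
Conv1D(32, 3) blocks), a four-layer stacked LSTM (64/64/32/32) with
batch normalization before a sigmoid output with L2 kernel penalty
(1e-3), and the Conv1D(32, 3) → max-pool(2) → GRU(32, sequences) →
flatten → sigmoid model. Hidden sizes are package defaults chosen as
modest capacities for 6-dimensional inputs (the reproduced methodology
does not state them) and are overridable through `modelSpec()`.

The network engine is implemented in the package itself (dense,
batch-norm, Conv1D, max-pool, LSTM, GRU layers; binary cross-entropy;
Adam with lr 1e-3, $\beta_1$ 0.9, $\beta_2$ 0.999; Glorot
initialization). All gradients, including backpropagation through time
for both recurrent cells and the train-mode batch-norm, are verified
against numerical differentiation in the test suite, and a capacity
check confirms every architecture can drive 32 random samples to near
zero loss.

Each 6-feature vector enters the sequence models as a (timesteps = 6,
channels = 1) sequence in the canonical feature order (PermEnt,
SampEnt, SVDEnt, DFA, SpectEnt, Higuchi). How a feature vector becomes
a sequence is not fixed by the reproduced methodology; this convention
is explicit and configurable via `inputShape`, not asserted as the
original authors'. Training uses a stratified 80/20 train/validation
split, batches of 32, 100 epochs by default, and a checkpointer that
restores the weights of the epoch with the lowest validation loss
(`restoreBest = FALSE` keeps the final weights instead). Inputs to all
models are standardized with training-split statistics.

# Evaluation

Confusion-count metrics use CTL = 1 as the positive class (switchable);
zero-denominator metrics are flagged undefined rather than returned as
0. The ROC sweeps thresholds over the distinct scores and the
trapezoidal AUC is tested to equal both a brute-force concordance count
and the Mann–Whitney identity. The pooled-variance two-sample t from
group summaries uses $df = n_A + n_B - 2$; pooling (not Welch) matches
the degrees of freedom conventionally reported alongside such
contrasts. `externalValidate()` applies the frozen preprocessing +
feature chain of a selection report to unseen recordings and scores a
trained model without refitting anything.

# Numerical choices and degenerate inputs

FFT resampling assumes periodic extension; its edge effects are
negligible for the band-limited signals produced by the filter chain.
The EDF writer scales each channel to the full 16-bit range with the
physical range rounded to 4 significant digits so that the 8-character
header fields hold the exact scaling constants; round trips are exact
to one quantization step. Flat (zero-norm) window rows, constant
signals handed to sample entropy, all-zero signals handed to spectral
entropy, single-class training data and missing electrodes all raise
informative errors naming the offending channel or subject. The
paired-t helper's conventions for zero-variance differences are stated
above.

# Problem sizes used in tests and acceptance analyses

The shipped analyses run at desk scale, chosen once: the recovery
analysis uses the full 50-subject composition (24 CTL / 26 DEP) on a
36-channel sub-montage covering 16 regions of the association table,
17 s of eyes-closed signal, and 20-epoch reduced training of the two
tuned models; the null control uses 40 subjects on 8 channels; the
repeated-seed recovery property uses ten 16-subject cohorts on 12
channels. These sizes keep the full suite fast while leaving every
stage's statistical behaviour intact; none of them was adjusted after
observing test outcomes.

# Known limitations

* Synthetic validation only: no claim transfers to real EEG without
  new data (the generator omits artifacts and realistic covariance).
* Window-level CV optimism, discussed above.
* Plain paired t-tests across folds (as in the reproduced methodology)
  ignore the correlation between folds; corrected resampled tests
  would be more conservative.
* FIF input is not supported; EDF(+) is the interchange format.
* The MI estimator's jitter makes rankings deterministic per seed, but
  near-ties among highly informative features can reorder across
  seeds; combination selection is robust to this because prefixes are
  re-scored.
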