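---
title: "Decoding c-VEP spellers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding c-VEP spellers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvepr)
```

## The decoding problem

In a code-modulated visual evoked potential (c-VEP) speller, every
selectable target flickers with a circularly shifted copy of one binary
pseudorandom sequence. The visual cortex responds to the flicker in a
time-locked way, so the EEG recorded while a user fixates target $k$
contains a response whose *phase* identifies $k$. Decoding therefore
reduces to: build one template of the code-locked response, derive the
other $K-1$ templates by circular shifting, and classify incoming EEG by
correlation against all $K$ templates.

`cvepr` implements this pipeline end to end — codebook, template and
spatial-filter training, individualized filter-bank weighting, synchronous
and asynchronous classification, speller state machines, and performance
metrics — together with a seeded synthetic-EEG generator so the whole
chain can be exercised and tested without recordings.

## Stimulation protocol

The bundled base code `cvep_mseq63` is a 63-bit maximal-length sequence
(32 ones, 31 zeros; two-valued circular autocorrelation). At the default
60 Hz update rate one stimulation cycle lasts $63/60 = 1.05$ s, and at the
600 Hz EEG sampling rate each bit covers 10 samples. Target $k$ (1-based)
uses the base code rotated left by $(k-1)\cdot\mathrm{step}$ bits — step 2
for the 32-target speller and step 4 for the 4-target speller — so target
1 always carries bit-shift 0:

```{r codebook}
cb32 <- build_codebook(K = 32, shift_step = 2)
cb32
code_cycle_duration(cb32)
```

Training trials span two full cycles (2.1 s, $n = 1260$ samples), one
trial per target per block; 4 blocks for 32 targets (128 trials) and 6
blocks for 4 targets (24 trials).

## Templates and the spatial-filter ensemble

Trials are circularly shifted (within each cycle, so cycle boundaries stay
aligned) to the phase of target 1 and averaged into the grand average
$\bar{Z}$. Class templates $X_k$ are column rotations of $\bar{Z}$ by the
target's bit shift times the samples-per-bit factor. The shift *sign* is
not something a formula pins down on its own; here it is fixed by the
requirement that the template of class $k$ matches the synthetic forward
model's noise-free response to code $k$, which the test suite asserts
exactly.

Spatial filters come from canonical correlation analysis (CCA) between the
concatenated aligned trials $[Z_1 \ldots Z_N]$ and $N$ copies of
$\bar{Z}$. Instead of only the first canonical weight vector, the
ensemble keeps the first $s = 4$ left weight vectors $w_1,\dots,w_4$:
with noisy EEG, discriminative energy spreads over several variates, and
an ensemble of projections is more robust than a single one. $s$ is
exposed for ablation but defaults to 4.

The CCA solver whitens both covariance matrices via eigendecomposition
with a small ridge ($10^{-9}$ of the mean diagonal) and takes the SVD of
the whitened cross-covariance. The ridge matters in practice: short
buffers (0.25 s) and rank-deficient noise-free fixtures otherwise produce
singular covariances. Variables are centred over samples before any
moment is estimated. Canonical correlations are clipped into $[0,1]$;
filters are defined only up to sign, and every downstream score is
sign-invariant (tested by negating filters).

## Individualized filter bank

Ongoing brain rhythms — most prominently occipital alpha at 8–12 Hz — are
spectrally concentrated, while the code-locked response is broadband. The
filter bank decomposes the signal with three 8th-order Butterworth
band-passes (8–60, 12–60 and 30–60 Hz, i.e. alpha+beta+gamma, beta+gamma,
gamma), trains a separate filter/template set per band, and combines the
per-band scores
$\lambda_k = \sum_j a_j \tilde{\lambda}_k^{(j)}$ with weights
$a_j = \rho^{(j)} / \sum_l \rho^{(l)}$, where $\rho^{(j)}$ is the first
canonical correlation of the training matrices after filtering with band
$j$. A band polluted by non-stimulus activity trains to a lower
$\rho^{(j)}$ and is automatically down-weighted for that individual.

Two choices here were genuinely open:

* **Zero-phase versus causal filtering.** Sub-band filtering is
  forward–backward (`signal::filtfilt`) by default for both training and
  testing, because templates and buffers must be filtered identically and
  zero-phase filtering preserves the code-phase alignment that the whole
  method rests on. A causal single-pass mode is available
  (`apply_subband(..., causal = TRUE)`) for strictly online replication.
* **The order parameter.** "8th order band-pass" is read as the order of
  the final band-pass transfer function, realized from a Butterworth
  prototype of order 4.

In the online path the accumulated buffer is re-filtered as a whole each
time it is scored; the decaying influence of record edges makes this
slightly different from filtering an infinite stream, which is one reason
the sub-band shift-equivariance test carries a tolerance.

## Scoring and the asynchronous decision rule

The buffer $Y$ ($m \times n_y$) is compared against the first $n_y$
columns of each template. Both are projected through the $s$ filters and
stacked into $s \times n_y$ arrays; the score is the first canonical
correlation between the two stacks. The alternative reading — flatten
both stacks and take an absolute Pearson correlation — is implemented as
`score_method = "pearson"` and pinned by tests, but the canonical form is
the default since it matches how $\rho$ is defined for multivariate
inputs everywhere else in the method.

EEG arrives in 0.05 s blocks ($n_a = 30$ samples). Classification starts
once the buffer holds 0.25 s ($n_y \ge 150$). The candidate is
$C = \arg\max_k \lambda_k$ (ties: lowest index, for determinism), emitted
only when the margin between best and second-best score *strictly*
exceeds the threshold $\beta$ (0.15 for 4 targets, 0.1 for 32; $\beta = 0$
reproduces the synchronous variant). While no decision is reached the
window grows; at the full trial length ($n = 1260$) the oldest
$n/2 = 630$ columns are shuffled out — $n_a$ must divide $n/2$, which the
state constructor enforces. After a decision the buffer is cleared and a
1 s gaze-shift pause follows; the logged selection time is the window
length plus that second. A configurable dwell cap (default 10 s) turns a
never-confident segment into an explicit timeout rather than blocking —
that is the non-control state.

## The synthetic generator

The generator emulates exactly the statistical structure the decoder
assumes, with every draw seeded:

* **Evoked response**: an impulse at each '1'-bit onset, circularly
  convolved within the cycle with a damped oscillation (~100 ms, 25 Hz,
  20 ms decay), mixed through a fixed unit-norm occipitally weighted
  topography. Because convolution is circular per cycle, noise-free
  responses of different targets are *exact* circular shifts of each
  other — the property the template logic needs, and the oracle used to
  pin shift directions.
* **Noise**: per-channel $1/f$-amplitude (pink) processes band-limited to
  2–100 Hz (the recording band-pass of the emulated amplifier), mixed
  spatially so channels are correlated.
* **Alpha contaminant**: an amplitude-modulated 10 Hz sinusoid on
  occipitally weighted channels; `alpha_amp` sets its RMS relative to the
  pink noise.
* **SNR**: the ratio of evoked RMS to noise RMS on the channel where the
  evoked topography is strongest, scaled empirically per trial.
  `snr = Inf` gives noise-free data.

What it does **not** emulate: realistic head-volume conduction,
eye/muscle artifacts, latency jitter and non-stationarity of the evoked
response, electrode drift, or inter-subject variability. Tests passing on
this generator therefore validate the *decoding machinery* (alignment,
shifting, scoring, thresholds, metrics) under controlled conditions; they
do not predict human online performance, which depends on recordings the
package deliberately does not model.

## Study conditions and desk-scale problem sizes

The protocol constants (600 Hz, 60 Hz update, 63-bit code, 2-cycle trials,
block counts 4 and 6) are kept exactly. For Monte-Carlo property checks
the montage is reduced to 8 channels — mirroring the reduced-montage
analysis of occipital subsets — and most sweeps use the 4-target book,
which keeps the full test suite and the acceptance script in the
one-to-two-minute range while leaving every pipeline stage exercised:

* snr/window monotonicity: 20 seeds × snr ∈ {0.1, 0.2, 0.4, 0.8} × windows
  {0.25, 0.5, 0.75, 1} s, 4 training blocks, 8 held-out trials per cell.
  The snr grid deliberately spans chance floor to ceiling; the window
  trend is evaluated at the two intermediate snr levels, since at the
  floor (pure noise) accuracy is flat by construction and at the ceiling
  it saturates.
* filter-bank contrast: 20 seeds, snr 0.3 with alpha contamination at
  twice the pink-noise RMS, 4-fold stratified cross-validation at 0.25
  and 0.5 s windows.
* K-contrast: 20 seeds at matched snr 0.35, one training block per class
  for K = 32 versus two blocks for K = 4, 0.5 s windows.

## Spellers, dictionary and metrics

The 4-target speller selects one of 27 characters (A–Z, underscore) in
three steps (groups of nine, groups of three, single characters); its
fourth target deletes the previous character at the root and goes back
one step below it. The 32-target speller selects among 28 characters,
three suggestion slots and undo in a single step. Suggestions come from a
word bigram model (counts of word pairs, unigram fallback for unseen
contexts, alphabetical tie-break); selecting one completes the current
prefix and appends an underscore, and undo removes the *entire* output of
the last selection — the simplest self-consistent reading of stepwise
correction with multi-character outputs. A bundled toy corpus of ~180
everyday English sentences stands in for a large web corpus; any
plain-text corpus (one sentence per line) can be supplied.

Copy-spelling simulation uses a greedy intent policy (undo until the typed
text is a prefix of the goal, then the next useful selection) against
either a per-selection error model — correct with probability $p$, errors
uniform over the other $K-1$ targets — or the full decoder in the loop.
With perfect selections the 43-character pangram needs exactly 43
selections (32-target) or 129 (4-target).

Metrics: accuracy is correct selections over all selections; the Wolpaw
ITR is
$B_m = [\log_2 K + p\log_2 p + (1-p)\log_2\frac{1-p}{K-1}]\,/\,(t/60)$
with $0\log 0 = 0$ and $K$ the number of targets per step (4, not 27, for
the multi-step speller). Below-chance accuracies are reported as 0
bit/min: the bracket is formally a Kullback–Leibler divergence and turns
positive again far below chance, where an "information rate" would be
meaningless. OCM divides the characters of the final, fully corrected
text by the total spelling time in minutes. The offline harness runs
4-fold stratified cross-validation of synchronous classification over a
window sweep, with optional channel subsets and the
standard-versus-filter-bank toggle; per-fold ITRs use the window plus the
1 s gaze shift as selection time and are averaged across folds.

## Numerical and degenerate-input conventions

* CCA: ridge $10^{-9}\cdot\overline{\mathrm{diag}}$ on both covariances;
  correlations clipped to $[0,1]$; zero-variance inputs raise an error
  rather than returning NaN scores.
* Argmax ties resolve to the lowest class index; the margin criterion is
  strict (`>`).
* All-zero buffers, empty corpora, missing classes in training data,
  mixed-rate EDF selections and window/trial-length mismatches raise
  typed errors early.
* Containers: the plain-text trial/stream format stores doubles as C99
  hex floats, so round trips are bit-identical; the decimal variant is
  exact to full double precision. Trained models persist via `saveRDS`.

## Known limitations

The forward model is a single-source linear mixture — adequate for
validating the pipeline, far from a biophysical simulation. Online
filtering is zero-phase on the buffer, not causal, so latencies differ
slightly from a real-time implementation. Human-level group results
(online accuracies around 94–96%, ITRs of 45–97 bit/min) depend on real
recordings of many participants and are outside what the synthetic
analogue can or should reproduce.
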