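---
title: "Signal-space demultiplexing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-space demultiplexing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(squiggleplex)
```

## The problem

Multiplexed Oxford Nanopore sequencing ligates a short barcode onto both
ends of every library molecule; after sequencing, reads must be sorted
back into per-sample bins. Base-space demultiplexers first basecall the
read and then search for the barcode in the called sequence, which makes
them hostage to basecalling errors. squiggleplex instead classifies the
*raw current signal* ("squiggle"): a convolutional network looks directly
at the electrical trace near each read end and emits a probability for
each barcode, plus an explicit no-barcode probability.

The package provides the whole loop needed to develop and evaluate such
a classifier without any sequencing hardware: a squiggle simulator with
exact ground truth, semi-global DTW for locating barcode signal,
training-set construction, the network itself, the read-calling rules,
and the standard demultiplexing metrics.

## The simulator

Real R9-style pores read roughly six bases at a time; the MinION samples
the current at 4 kHz while DNA translocates at about 450 bases/s, i.e.
~8.9 samples per base on average. The simulator mirrors this:

* **Pore model** (`build_pore_model()`): every one of the $4^k$ k-mers
  (default $k = 6$) receives an expected current level drawn from a
  standard normal. All amplitudes in the simulator are therefore
  expressed in units of the inter-k-mer level spread (sd 1), which makes
  noise magnitudes directly interpretable.
* **Dwell**: each base stays in the pore for a shifted-geometric number
  of samples (minimum 1, mean $4000/450$). Only the average rate is
  physically documented; the geometric choice is the maximum-entropy
  discrete waiting time and produces realistic dwell dispersion. A 40 bp
  barcode construct (24 bp core + 8 bp flanks) then yields ~356 samples
  on average, inside the typical 250-600 sample range for such
  constructs, and 1024 — the smallest power of two above the 600-sample
  typical maximum — is the window every classifier stage uses.
* **Measurement noise**: i.i.d. Gaussian per sample, default sd 0.25
  (of the level spread). Amplitude drift is deliberately not simulated:
  the network's training-only Gaussian-noise layer plays that role.
* **Reads** (`simulate_library()`): open-pore pad (uniform 50-2000
  samples at a high current level, so the multi-window search is
  genuinely exercised), adapter, barcode construct, insert, barcode
  construct, adapter, trailing pad. A configurable fraction of reads
  carries no barcode (default 5%), and a small fraction (default 0.3%)
  are cross-barcode chimeras joining two inserts with different
  barcodes at either end. Each read draws a quality factor that sets
  its base-space substitution rate (2-20%), so mean q-scores vary
  across reads; optionally (`noise_mult_range`) the same factor also
  scales the read's signal noise, making "low-q" reads genuinely
  harder in both signal and base space — the q-score-stratified
  evaluation tests enable this coupling explicitly, while the default
  keeps every read at the model's noise sd.
* **Inserts**: one synthetic 500 bp reference per barcode. Real
  amplicon references are tens of times longer; the shorter inserts
  keep simulated libraries desk-sized without affecting the read ends
  where all classification happens.

What the simulator does *not* emulate: real pore chemistry (measured
k-mer level tables, homopolymer dwell pathologies), amplitude drift and
stall artefacts, or basecaller-specific error structure. Passing tests
on simulated data therefore demonstrate that the machinery — window
harvesting, training, merging, calling, scoring — is correct and
self-consistent, not that a model trained here transfers to a real flow
cell; real deployments should train on real reads.

## Locating barcodes: semi-global DTW

Training labels require knowing *where* the barcode signal sits inside
a read. `semiglobal_dtw()` aligns the noise-free expected signal of a
construct (template) against the read: the template must be consumed
end-to-end while the read's prefix and suffix are free. Design choices,
made where the method itself is silent:

* local distance $|a-b|$ rather than squared error — robust to the
  occasional spike;
* symmetric three-step pattern (diagonal / advance-template /
  advance-read), no slope weighting;
* full dynamic-programming table — templates are only ~350 samples, so
  banding is unnecessary;
* templates stay in pore-model units. Model levels are already
  standardised across k-mers, and re-normalising one 40 bp template by
  its own 35-level sample standard deviation rescales its amplitude by
  up to ±25%, enough to make a construct whose levels happen to span a
  narrow range unfindable in its own read. The read, whose thousands of
  samples estimate scale reliably, *is* z-normalised (after trimming
  the leading open-pore run).
* a match is "clear" (`locate_barcode()`) when the cost per template
  sample is below 0.30 z-units *and* the matched read interval spans
  0.6-2 times the template length. The duration gate is essential:
  warping lets any template align into featureless or pure-noise
  signal at a moderate cost (white noise floors near 0.18-0.23), but
  only by compressing drastically — measured noise matches span
  0.09-0.23 of the template length, while genuine construct passages
  at ~9 samples/base span 0.64-1.12. Duration, not cost margin,
  is what separates noise from a real barcode (cost margins of
  negatives overlap those of true matches). Both numbers were
  calibrated once on simulated positive and negative batteries.

Template matching is a *clear-instance harvester*, not a classifier:
on low-noise (sd 0.1) simulated reads it identifies and localises all
12 barcodes essentially perfectly, but at the simulator's default
noise its 12-way identification degrades to ~75-85% regardless of
variant (slope weighting, local normalisation, noise deadbands, event
segmentation and affine rescoring were all evaluated) — which is
precisely why the classifier is a trained network rather than a
template matcher, and why training harvests should restrict to clear
matches (ambiguous reads return no call).

The implementation is checked against exhaustive enumeration of all
monotone alignments on small instances, so the DP is exact, not
approximate.

## Training sets

`extract_training_windows()` cuts 1024-sample windows that fully
contain the located barcode interval, with the barcode position
jittered uniformly inside the window — the network must not be able to
memorise position. Read-end windows are reversed so one orientation
convention serves both ends (separate start and end models are still
trained, as the two ends differ in context and reliability).

A substantial share of each assembled set is no-barcode signal. Most
of it is harvested from the reads themselves
(`harvest_training_windows()`): windows from non-barcode parts of
barcoded reads — half drawn from the *partial-overlap band* where
25-90% of the barcode pokes into the window — plus windows sampled
along barcode-less reads. These are critical. The deployment windows
slide at a fixed stride, so most windows a read produces contain
adapter, insert, open-pore boundary or a barcode fragment; a network
never shown such windows hallucinates confident wrong-barcode calls on
them, and a single confident wrong window is enough to destroy the
merged probability gap (or to bin a barcode-less read). Only full
containment counts as a barcode — the window scheme guarantees that
some window fully contains any barcode within the span. The set is
then topped up with synthetic no-barcode windows
(`make_no_barcode_samples()`): barcode-free read signal from random
sequences, adapter-only signal, flat signal, white Gaussian noise and
smooth 1-D gradient (Perlin) noise; the random-sequence windows are
what teach the network to reject *unseen* inserts (a negative-control
library) instead of memorising the training reads. The explicit
no-barcode class lets the classifier actively reject signal rather
than merely fail to match. In the default pipeline the no-barcode
class ends up near 45% of the set — above the nominal quarter — because
the partial-overlap and barcode-less windows proved indispensable;
barcode-window confidence was unaffected by the extra no-barcode mass.

**Augmentation** (`augment_signal()`) distorts the time axis:
duplicate the values at a random quarter of positions, delete the
values at a disjoint quarter. Length is exactly preserved (the two sets
are disjoint by construction) and no new amplitude values are invented.
The default augmentation factor 2 (one distorted copy per original,
regenerated every epoch, training partition only) matches the regime
under which this style of augmentation was found most effective.

**Refinement** (`refine_by_cross_split()`): split the set into four
folds, classify each fold with a model trained on the other three, and
discard samples whose prediction disagrees with their label. On a
separable synthetic set this removes almost nothing; with deliberately
mislabelled samples injected it removes the majority of them, which is
the property that matters for cleaning harvested real-world labels.

## The network

`build_model()` implements a compact 1-D CNN, written in this package
(R orchestration over compiled convolution/pooling kernels):

    input 1024x1
    -> Gaussian noise (sd 0.02, training only)
    -> [conv(48, k=9) x2 -> max-pool(2) -> batch-norm -> dropout(0.1)] x 6
       (one inception-style module after group 3)
    -> global average pooling
    -> dense softmax over 13 classes

The filter count is constant (48) except where the inception-style
module concatenates its three parallel paths (1-wide convolution, a
bottlenecked stacked convolution, and a pooled path behind a 1-wide
bottleneck) to 72 filters. Signal length halves at every group:
1024 → 512 → … → 16. The exact per-layer widths of the original
architecture are not recoverable from text, so every dimension here is
driven by `network_config()` and alternatives are testable. The
reference model has ~315k parameters; models were deliberately kept
under half a million parameters to limit overfitting.

Training (`train_model()`) minimises categorical cross-entropy with
Adam over a random 95:5 training:validation split. The initial learning
rate is 2e-3, halved whenever validation loss plateaus for 2 epochs —
with only tens of desk-scale epochs available, the faster initial rate
reaches the same plateau that 1e-3 reaches in roughly twice the time.
Noise, dropout and augmentation apply to the training passes only, so
validation metrics routinely *exceed* training metrics; that is
expected, not a bug. Training is bitwise reproducible under a fixed
seed on a fixed BLAS.

`desk_network_config()` is the scale used by the package's tests and
demonstrations: 24 filters, one convolution per group, pools
(4, 4, 2, 2), inception after group 2, dropout 0.05 — about 20k
parameters. It trains to ~0.97 window accuracy on simulated 12-barcode
libraries in minutes on one CPU. Convolution arithmetic runs in single
precision (the standard for network training; roughly twice the
single-core gemm throughput), with a double-precision switch
(`options(squiggleplex.double_conv = TRUE)`) used by the
finite-difference gradient checks, where float rounding would swamp
the numeric derivatives. The full-scale regime (reference
architecture, 1000 epochs x 100 000 samples) remains reachable through
the same configuration objects but is a GPU-class undertaking.

Numerical notes: batch-norm uses population statistics with running
(momentum 0.9) inference estimates; gradients are verified against
central finite differences in the test suite. One subtlety: with
zero-initialised biases a pre-activation can sit *exactly* on the ReLU
kink, where a central difference and the (valid) subgradient disagree;
the gradient test nudges biases off zero to avoid flagging this
non-issue.

## Read classification

A barcode usually sits in the first 1024 samples, but long open-pore
stretches can push it deeper, so `demultiplex()` examines 11 windows of
1024 samples at stride 512 (6144 samples) from each end, the trailing
span reversed to match the training orientation. Per-window
probabilities are merged by keeping each *barcode* class's maximum
across windows and the *no-barcode* class's minimum, then
renormalising. The asymmetry follows from what the windows mean: they
are alternative candidate locations for one barcode, so the
best-scoring window carries the barcode evidence, whereas no-barcode
is supported only if no window shows a barcode — taking the no-barcode
maximum instead would let the many genuinely barcode-free windows of
every read veto every call. Windows are z-normalised individually — a
window still containing open-pore remnant would otherwise distort the
scale.

Open-pore trimming, needed before windowing, uses a data-derived
cutoff when none is given: the midpoint between the signal's 10th
percentile and its maximum. Open-pore current is a high, narrow mode
well separated from the DNA signal, so the midpoint lands between the
two; centre-plus-scaled-spread rules (median + k·MAD) fail here
because a long pad inflates both the centre and the spread estimates.

`call_barcode()` assigns the arg-max barcode only when its probability
beats the runner-up by strictly more than 0.5 and the arg-max is not
the no-barcode class. Ties give a gap of zero and are never called —
deterministic without randomness. `combine_ends()`: by default a read
is binned if either end produced a call; two conflicting calls mark a
cross-barcode chimera, binned as none. Stringent mode requires both
ends to agree (higher precision, lower recall); start-only mode serves
preparations that barcode one end. Reads shorter than a single window
are assigned none — padding would fabricate signal.

## Evaluation

`assign_ground_truth()` implements the alignment-based truthing rules:
a read's label is its longest-alignment reference provided that
alignment covers at least `min(100, 10%)` of the read; an alignment to
a *different* reference covering at least `max(50, 5%)` marks a
cross-reference chimera (within-reference chimeras are undetectable by
construction). `score_demux()` reports the confusion matrix, binned
fraction (over all reads), precision (correct/binned, among known-truth
reads), recall (correct/all known-truth reads), the 2.5th-97.5th
percentile range of binned reads' mean q-scores (computed in
error-probability space), and the fractions of unknown and chimeric
reads that were nevertheless binned. With nothing binned, precision is
reported as undefined (`NA`) rather than 0 or 1. Q statistics cover
binned reads only; none-bin reads are excluded. `consensus_bins()`
keeps a read's bin only when every supplied demultiplexing run agrees
on it — the intersection trades recall for precision.

## Problem sizes used by the tests

The package's own verification runs at deliberately desk-sized scales,
chosen once as the smallest sizes at which each property is
comfortably measurable: the end-to-end benchmark simulates 2000 reads
across 12 barcodes (seed 42, default noise), harvests two jittered
barcode windows plus one to four no-barcode windows per read end, and
trains desk-scale start/end models for 14 epochs of 5000 samples (each
presented once unmodified and once temporally distorted); the
refinement experiment uses a 4-class separable set of 240
windows of length 128 with 5% labels flipped; DTW exactness uses 120
random instances with templates up to 6 and reads up to 10 samples;
simulator calibration uses 1000 construct squiggles.

## Known limitations

* The simulator's pore model is synthetic; levels are exchangeable
  across k-mers, unlike real chemistry where similar k-mers have
  similar levels. Real confusability between barcodes is therefore not
  represented.
* fast5/HDF5 containers are not read; the package's raw-signal
  container is a documented plain-text format, and all built-in data
  paths go through the simulator.
* Classification throughput is CPU-bound R/BLAS; it is adequate for
  simulated libraries, not for a live PromethION stream.
* The probability-gap threshold (0.5) and DTW cost threshold (0.4) are
  fixed defaults; both are exposed as parameters rather than
  auto-calibrated.
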