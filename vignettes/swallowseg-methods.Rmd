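---
title: "Detecting and segmenting swallow sounds: models and methods"
author: "swallowseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting swallow sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowseg)
```

## The problem

Cervical auscultation records swallow and breath sounds from a microphone
on the neck during a feeding observation. Identifying the onset and offset
of every swallow in such a recording is the precondition for any objective
analysis of feeding in preterm neonates, and doing it by hand is slow
expert work. `swallowseg` implements an automatic detector: given a mono
WAV recording of a feeding observation it returns the set of predicted
swallow intervals at 0.16 s temporal resolution, and given a labeled corpus
it trains that detector and reports diagnostic test accuracy (sensitivity,
specificity, PPV, NPV, F1), overall and stratified by bottle versus breast
feeding.

## The model

The pipeline is a transfer-learning design. Audio is resampled to 16 kHz
(Kaiser-window FIR polyphase resampling), peak-normalized to $[-1, 1]$, and
split into frames of 0.96 s with 50% overlap (hop 0.48 s). Each frame is
converted to a log-Mel spectrogram patch — 25 ms Hann windows at a 10 ms
hop, 64 triangular mel bands spanning 125–7500 Hz, then
$\log(E + 0.001)$ — giving a $96 \times 64$ patch, the native input
geometry of the pretrained audio-event backbone whose penultimate-layer
outputs serve as 1024-dimensional frame embeddings. The frame's
zero-crossing rate (fraction of consecutive-sample sign changes, an
amplitude-invariant spectral cue) is appended, giving a 1025-dimensional
feature vector per frame.

A fully-connected detection head replaces the backbone's classifier: four
hidden ReLU layers of 1024, 1024, 1024 and 512 units and a six-unit sigmoid
output. Each output unit corresponds to one 0.16 s *subframe* of the 0.96 s
frame, so the head predicts six confidences per frame and the temporal
resolution of segmentation improves by a factor of six over frame-level
prediction. Ground truth is built the same way: subframe $k$ of a frame is
labeled 1 when a swallow interval overlaps
$[t_0 + 0.16k,\; t_0 + 0.16(k+1))$.

Training follows the protocol: participants (recordings) are randomly
divided 60/20/20 into train/validation/test sets at participant
granularity, so no neonate contributes frames to two subsets. Before each
epoch the training frames are re-balanced by undersampling the majority
class (a frame is a "swallow frame" if any of its six subframe targets is
1) and shuffled. Optimization is mini-batch Adam (batch 32) on the
mean-squared error between the sigmoid outputs and the binary targets, with
L2 regularization on the first three hidden layers, at most 70 epochs, and
early stopping after five epochs without validation-loss improvement, with
best-validation weights restored.

At inference each 0.16 s bin of the timeline is covered by the subframes of
two overlapping frames (the hop is exactly three subframes); their
confidences are fused by arithmetic mean (an OR/maximum rule is available
as an option), bins with fused confidence strictly above 0.5 become
predicted swallow bins, and maximal runs of positive bins become predicted
intervals $[\text{run start}, \text{run end})$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| frame length / overlap | 0.96 s / 50% | analysis frame geometry; fixed by the backbone's input patch |
| subframe width | 0.16 s | unit of temporal prediction; 6 per frame |
| mel bands, range | 64, 125–7500 Hz | backbone front-end configuration |
| decision threshold | 0.5 (strict `>`) | confidence above which a bin is a predicted swallow |
| batch size / max epochs / patience | 32 / 70 / 5 | training protocol |
| L2 strength | $10^{-4}$ | on the first three hidden layers |
| learning rate | $3 \times 10^{-4}$ | Adam step size (see below) |

The learning rate and L2 coefficient are not fixed by the protocol above
and are this package's own defaults. With the optimizer's more
conventional $10^{-3}$ the MSE loss on this head (3,677,702 parameters,
verified by `head_param_count()`) oscillates and can diverge after a few
epochs under per-epoch re-balancing; $3 \times 10^{-4}$ trains stably
across corpus sizes, so it is the shipped default and remains configurable.

Two further numerical choices are the package's own. First, features are
standardized per dimension (mean/SD fitted on the training frames, stored
in the trained head, re-applied at prediction): embedding activations and
the ZCR live on very different scales, and without standardization the
sigmoid output saturates at initialization and MSE gradients vanish.
Second, the ground-truth overlap rule is *any* nonzero overlap between a
swallow and a subframe (the most inclusive reading, preserving the
interval round-trip bound below); a majority-overlap rule
(`min_overlap_frac = 0.5`) is available.

## Embedding backends

The production backend — the pretrained audio-event network — needs an
external deep-learning runtime and downloaded weights; it is an optional
dependency, and calling it without them raises an explicit
"backend unavailable" error. The shipped, always-available backend is a
*projection* backend: a fixed random linear projection (seed-determined,
default seed 20250912) of the flattened $96 \times 64$ patch to 1024
dimensions followed by a ReLU. It is deterministic, bitwise reproducible,
roughly distance-preserving, and cheap — sufficient for the detection head
to learn on synthetic audio and for every test to run offline. Both
backends satisfy one contract (dimension 1024, determinism, finiteness)
and are interchangeable behind `embedding_backend()`.

## The synthetic corpus

No public corpus of neonatal feeding audio exists, so the package ships a
generator that emulates the acoustic scene: low-pass-filtered background
noise amplitude-modulated at the breathing rate (default 1 Hz), short
quasi-periodic sucking clicks (default 1.5/s), and band-limited
(300–3000 Hz) noise bursts with a fast-attack/slow-decay envelope standing
in for the "fluid flushing" swallow sound. Swallow onsets follow a thinned
Poisson process (default candidate rate 0.4/s) with a 0.2 s minimum gap;
durations are uniform on 0.2–0.8 s; each burst is scaled so the
within-interval power exceeds the local background power by the configured
SNR (default 10 dB, verifiable with `measure_snr()`). Defaults follow the
study conditions the pipeline targets: two-minute recordings sampled at
44.1 kHz, so the resampling front end is exercised exactly as in
production. Breast-type corpus entries are made harder — SNR lowered by
4 dB and unlabeled low-level confounder bursts added as stand-ins for
quiet non-nutritive/saliva swallows — giving stratified evaluation a
realistic bottle > breast ordering to detect.

What the generator does *not* model: real swallow spectro-temporal
structure (formant-like resonances, click components), microphone contact
artifacts, crying, ambient ward noise, or physiological variability
between neonates. Passing tests on this corpus therefore demonstrates that
the pipeline's machinery — features, labels, training, decoding,
evaluation — is correct and that the detector can learn genuinely present
band-limited events at realistic SNR; it does not validate clinical
performance on real cervical auscultation audio.

## Numerical choices and degenerate inputs

* Log-Mel dialect: $(0.96 - 0.025)/0.010 + 1 = 94.5$ windows do not tile a
  frame exactly, so each frame is zero-padded at its end to
  $(96-1) \cdot 160 + 400 = 15600$ samples and exactly 96 windows are
  taken. Silence maps to a constant patch of $\log(0.001)$.
* Resampler: polyphase FIR with $2 \cdot 10 \cdot \max(L, M) + 1$ taps and
  a Kaiser window ($\beta = 5$); output length is the rounded length
  ratio, and a one-sample edge discrepancy against other resamplers is
  tolerated by design.
* ZCR: a zero sample inherits the previous nonzero sign (leading zeros the
  first nonzero sign), so flat plateaus do not double-count; an all-zero
  frame has ZCR 0. The rate is amplitude-invariant, so it is indifferent
  whether it is computed before or after peak normalization.
* Degenerate frames: a constant (zero-RMS) frame carries no acoustic
  content, so its subframe confidences are forced to zero at inference —
  silence can never yield a detection, regardless of how the head
  extrapolates to such out-of-distribution inputs.
* Intervals are half-open $[\text{onset}, \text{offset})$, in seconds from
  recording start; overlapping annotation intervals are merged on
  construction. Audio shorter than one frame yields an empty frame set
  (not an error), silence normalizes to itself, and zero-denominator
  metrics report `NA` rather than erroring.
* Interval round-trip: intervals aligned to the 0.16 s grid survive
  label → fuse → decode exactly; arbitrary intervals are recovered with
  every boundary within one subframe (0.16 s), the design resolution.
  Events separated by less than one bin may merge into a single run.
* Fusion of the two frames covering a bin is this package's decision (the
  protocol leaves it open): arithmetic mean before thresholding, which is
  symmetric and coincides with the single-frame case when both frames
  agree; strict `>` at 0.5 means an exactly-0.5 confidence is *not* a
  detection.
* Determinism: every stochastic step (corpus generation, participant
  split, weight initialization, per-epoch balancing) is driven by explicit
  seeds; repeated runs are bitwise identical. The training loop itself is
  C++ with all random draws made on the R side.

## Problem sizes

The package's study-scale simulation — also what `scripts/acceptance.R`
reruns — uses 60 recordings of 120 s (SNR 10 dB, swallow rate 0.4/s, half
bottle / half breast), about 15,000 frames, trained with the full protocol
on a 36/12/12-recording split. Unit tests use corpora of ten 30 s
recordings and small randomized fixtures so the whole suite stays fast;
the fitted toy detectors behave qualitatively like the study-scale one
(stable descent, high-SNR events found) but their headline numbers are not
meaningful and are not asserted.

## Known limitations

* The projection backend is not a trained acoustic representation; with
  the real pretrained backbone the same head and protocol apply unchanged,
  but results on clinical audio are not predicted by the synthetic
  benchmark.
* Evaluation is at the subframe (0.16 s bin) level, the model's native
  output; event-level counting (one hit per swallow) is deliberately not
  the headline metric and boundary bins of an event are the dominant error
  source.
* The annotation reader accepts the canonical CSV dialect and Audacity
  label tracks; other formats must be converted.
* Recordings are processed whole; there is no notion of feeding-active
  sub-segments.
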