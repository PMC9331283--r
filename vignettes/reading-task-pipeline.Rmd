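---
title: "Multimodal reading-task features: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal reading-task features: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`readtaskdx` implements a multimodal feature pipeline for screening
schizophrenia from a standardized text-reading task: acoustic markers of
speech emotional flatness, landmark-based head-movement markers of
re-reading and unconscious motion, image representations of mouth-movement
fluency with a transfer-learned feature extractor, and a repeated
cross-validated evaluation harness. This vignette explains the underlying
models, the parameters that matter, what the synthetic cohort generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The acoustic model of emotional flatness

Flat affect shows up in speech as monotonous loudness and reduced pitch
variation. Two features capture this.

**PIVD (phonatory intensity variation diversity).** The signal is cut into
25 ms frames every 10 ms (standard speech framing; configurable through
`frame_params()`). Each frame is summarised by its mean intensity; with the
default power convention the per-sample intensity is the squared amplitude
(absolute amplitude is selectable, and PIVD values depend on this choice).
PIVD is the standard deviation of the first-order difference of that
per-frame sequence, using the number of frames minus one — the length of
the difference sequence — as the divisor. A perfectly level or linearly
ramping intensity track gives PIVD = 0; lively frame-to-frame variation
gives large values. PIVD is invariant to adding a constant intensity and
scales linearly with intensity gain, so absolute recording level matters —
deliberately: reduced vocal intensity is itself part of the phenotype.

**AFVC (auditory frequency variation coefficient).** Per frame, 12
mel-filterbank log energies (triangular filters spanning 0 Hz to Nyquist,
Hamming window, no pre-emphasis) are cosine-transformed into 12 cepstral
coefficients; all 12 DCT coefficients are kept, including the energy-like
c0 — with 12 filters the transform is square, and dropping c0 would discard
the overall level that the flat-affect phenotype also shifts. A
second-order delta with the five-frame kernel (−2, −1, 0, 1, 2)/3 adds
local dynamics; the denominator 3 is used exactly as stated by the feature
definition rather than the conventional sum-of-squares normalisation, and
boundary frames are edge-replicated. AFVC is the coefficient of variation —
population SD over absolute mean — of the 24 column means (12 MFCC + 12
delta). The mean can legitimately approach zero for pathological inputs, so
the implementation raises an explicit degenerate-input error below
`eps = 1e-9` instead of silently clamping.

**Baselines.** The comparator features are order-free summaries: mean/SD of
an autocorrelation F0 track (60–400 Hz search range, voicing threshold 0.3
on the normalized autocorrelation peak, 40 ms frames, parabolic peak
interpolation, input decimated to ~11 kHz — ample for F0 below 400 Hz), and
mean/min/max/SD of the frame intensity means.

## Head-movement features from the 68-point landmarks

The mean frame-to-frame displacement of the 17 jaw-contour points gives a
two-channel trajectory: horizontal (the repeated-reading dimension) and
vertical (the unconscious-movement dimension), in standard image axes
(x right, y down).

**RHR** binarizes the horizontal channel (right = 1, left = 0) with a
symmetric dead-band of 0.2 px/frame — steps inside the dead-band carry the
previous state, so sensor-level jitter does not thrash the direction — and
counts one rotation per 1→0 transition after absorbing runs shorter than
3 frames. A rotation is thus the leftward return that ends a rightward
reading sweep; straight-through reading of *n* lines gives RHR ≈ 1, and
re-reading pushes it above 1. Which event to count (sweeps, returns, or all
direction changes) is not uniquely determined by the phenomenon; returns
were chosen because each line, read or re-read, ends in exactly one.

**UHD** is the summed absolute vertical displacement per text line. The
necessary vertical travel per line is similar across subjects, so the
excess reflects unconscious head movement.

**MEA**, the trajectory-blind comparator, thresholds absolute gray-level
frame differences (default 10/255) inside a head region of interest
(bounding box of the contour points dilated by 20%) and averages over frame
pairs, normalized by ROI area. It measures amount of motion only, which is
why trajectory-structured group differences separate better under RHR/UHD
than under MEA — an ordering the test suite asserts on synthetic cohorts.

## Mouth-movement fluency representations

The mouth aspect ratio (MAR) is the distance between landmarks 52 and 58
divided by the distance between 49 and 55, per frame; frames with failed
detection are linearly interpolated (edges replicate). Two images encode a
MAR sequence for the feature-extraction network:

- **Time-domain map.** The i-th value becomes the R-channel pixel
  `round(200·value)` clipped to [0, 255] (G = B = 0), written row-major
  into a square grid of side `ceiling(sqrt(L))`, zero-padded, then resized
  by nearest neighbour to the backbone input side (default 224). The exact
  pixel layout of this encoding is an interpretation — the defining
  property preserved is that every element of the sequence is represented
  and any change of at least 1/200 in any element changes the image.
- **3-D spectrogram.** The sequence is segmented into 3 s windows every
  1 s (`floor((L − 3·fps)/fps) + 1` segments); each segment is
  Hamming-windowed and transformed with a single FFT of the segment length
  (no sub-windowing). The time × frequency × magnitude surface is rendered
  as a fixed-viewpoint waterfall projection, back-to-front, magnitudes
  normalized by the recording's global maximum and coloured with the
  viridis colormap; the DC bin is dropped before rendering so the constant
  mouth-opening level does not dominate the colour scale. Rendering is
  fully deterministic: identical inputs give bit-identical PNGs.

## The RRF transfer-feature extractor

A frozen convolutional encoder feeds a binary fully-connected head; only
the head is ever trained (mini-batch SGD, batch 10, 140 epochs, learning
rate 1e-4, softmax cross-entropy, seeded shuffling, no scheduling). The RRF
vector concatenates the two pre-softmax logits of the time-domain-map head
with the two of the spectrogram head — pre-softmax rather than
probabilities because the logit scale carries information that the softmax
saturates away (configurable). The backbone is pluggable: the default is a
compact seeded random convolutional encoder (nearest-neighbour downsample
to 32 px, 8 random 5×5×3 filters, ReLU, global average pooling, plus
per-channel means), which keeps the repository self-contained and
CPU-friendly while preserving every architectural contract — frozen
convolution, trainable binary head, 4-element output. A deep pretrained
residual network can be dropped in through `backbone_spec(encode = ...)`
without touching the rest of the pipeline.

Inside cross-validation the heads are retrained on each training fold only,
so no test segment ever influences the features extracted for it. A global
training mode (`global_rrf_features()`) exists for inspection and is
documented as leak-prone.

## The evaluation protocol

Stratified 10-fold cross-validation repeated 5 times; metrics (accuracy,
specificity over controls, sensitivity over patients, rank AUC with tied
scores mid-ranked) are computed per fold, averaged within repeat, then
across repeats. Folds split **by subject** by default: with 4 segments per
subject, by-segment folding lets a classifier recognise the subject rather
than the condition, so the by-segment switch exists but is documented as
optimistic. Feature standardization uses training-fold statistics only.
The SVM uses a radial kernel with cost 1; the random forest 500 trees; AUC
scores come from the SVM decision value and the forest class probability.

## What the synthetic cohort emulates — and what it does not

The recordings behind the published results are private clinical data, so
the package ships a seeded generator whose defaults mirror the study
design: 20 subjects per group, 4 segments each (160 segments), 30 fps
video, 44,100 Hz audio. Segments default to 10 s with 8 text lines — short
standardized reading segments sized so the full cohort generates and
evaluates in about two minutes on one CPU.

Audio is a harmonic carrier (10 decaying harmonics of a slowly modulated
140 Hz fundamental) with syllable-rate (3.5 Hz) sinusoid-plus-noise
amplitude modulation, weak aspiration noise, and a fixed linear gain — no
per-recording level normalization, so intensity features see the
configured vocal level directly. Landmarks move rigidly along constructed
reading sweeps (rightward drift, leftward return per line, Poisson extra
re-reads capped by the fixed duration, a deterministic downward step per
line, i.i.d. vertical jitter), and the mouth points oscillate at a 4 Hz
syllable rate with inserted pauses.

Group blocks encode the clinical directions: patients get lower
amplitude-modulation depth and loudness, less pitch modulation, more extra
rotations (mean 1.5 per line), larger vertical jitter (2 px) and more
pauses. Subjects within a group draw their parameters from the block mean
with fixed between-subject spreads, which keeps every single feature
informative but imperfect; the fused feature set then lands in the high-80s
to high-90s accuracy range with a genuine fusion gain, rather than
saturating. The patient and control loudness bands (0.12 and 0.30) sit at
the minimum and on the rising branch of the AFVC-versus-level curve at
44.1 kHz, which is what carries the control-greater-than-patient AFVC
direction in this synthetic material; the effect sizes are generator
defaults, not estimates of the clinical effect.

What passing tests on this cohort show is that the pipeline measures what
it claims to measure on signals with known ground truth — parameter
recovery, directional fidelity, fusion gain, leak-freedom. What they cannot
show is clinical performance: the audio is not speech, the faces are
templates, and no medication, symptom-severity or demographic structure is
modelled.

## Numerical choices and degenerate inputs

- Mel filterbank energies are floored at 1e-10 before the log; digital
  silence therefore yields identical (not infinite) coefficient rows.
- `afvc()` errors (rather than clamps) when the parameter-sequence mean is
  within 1e-9 of zero; `pivd()` requires at least 3 frames; `mfcc()` at
  least 5.
- `binarize_rr()` resolves an all-dead-band trajectory to a single carried
  state; leading dead-band frames take the first decisive direction.
- Run-length filtering in `count_rotations()` absorbs short runs into the
  preceding run (the leading run into the following one) until a fixed
  point, then counts 1→0 transitions.
- `mar_sequence()` raises a frame-indexed error on coincident mouth
  corners (zero length).
- The WAV reader accepts PCM 16-bit and float-32 mono/stereo; stereo is
  downmixed with a warning. 16-bit round trips are exact to one
  quantization step.
- All stochastic stages (generator, fold assignment, head training,
  classifiers) are seeded; identical configurations reproduce reports
  bit-for-bit.

## Problem sizes used by the shipped checks

The test suite exercises the full default cohort (40 subjects × 4
segments) once, end to end. Repeated-cohort properties (directional
medians over 20 seeded cohorts, MEA-versus-trajectory ordering) use
reduced cohorts — 6 subjects per group, one 8 s segment, 6 text lines —
at the default audio rate; these sizes are the package's choice of a
problem large enough to be stable (RHR is quantized in units of 1/n_lines,
and very few lines produce exact median ties) and small enough to iterate
on. Formula-level checks run against independently coded brute-force
oracles on hundreds of random small inputs.

## Known limitations

- AFVC on arbitrary real-world material can sit near the degenerate
  zero-mean regime; the error is explicit but means the feature is not
  total.
- The rotation-event definition (returns after run filtering) is one of
  several defensible readings of "number of head rotations"; counts from
  other definitions differ by a roughly constant factor on sweep-like
  trajectories.
- The default backbone is a random encoder: adequate for separating the
  synthetic fluency images and for exercising every contract, but not a
  pretrained visual feature hierarchy; swap in one via `backbone_spec()`
  for real imagery.
- The pipeline assumes landmarks are given (CSV/JSON or a pluggable
  detector); face alignment itself is out of scope.
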