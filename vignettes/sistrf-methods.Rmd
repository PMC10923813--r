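---
title: "Encoding models of dialogue speech and speech-induced suppression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of dialogue speech and speech-induced suppression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sistrf)
```

## The scientific problem

During a conversation a listener's auditory system receives two continuous
speech streams: the interlocutor's voice and their own. The brain treats
them very differently — responses to self-produced speech are strongly
attenuated (speech-induced suppression, SIS), classically attributed to an
efference copy of the motor command that cancels the predicted sensory
input. `sistrf` implements the analysis stack needed to quantify this in
continuous, unscripted dialogue EEG:

1. **Stimulus features** at the EEG frame rate (128 Hz): 16-band mel
   spectrogram and Hilbert envelope, computed on strictly non-overlapping
   125-sample windows of 16 kHz audio, so no feature frame sees future
   audio.
2. **Encoding models**: per channel, band and dialogue condition, a ridge
   regression predicts each EEG sample from the previous 600 ms of
   stimulus features. The weights, reshaped to feature × lag, are the
   multivariate temporal response function (mTRF) and are read like an
   evoked response to the continuous stimulus. Performance is the Pearson
   correlation between predicted and recorded EEG on held-out folds.
3. **Dialogue conditions**: inter-pausal units (IPUs — maximal one-speaker
   segments bounded by pauses longer than 100 ms) define, per frame,
   whether only the other speaks (E), only oneself (S), both (B, analyzed
   from both perspectives as E|B and S|B), or neither (Silence). Training
   samples for a condition require the condition to hold uninterruptedly
   over the full 600 ms lag window.
4. **Statistics**: a row-permutation test for per-channel model
   significance, exact Wilcoxon signed-rank maps between conditions,
   paired Cohen's d and JZS Bayes factors, Bonferroni and
   Benjamini–Hochberg control, a TFCE one-sample test over the mTRF plane,
   and a lagged phase-locking (PLV) analysis that replicates the encoding
   result through phases instead of amplitudes.

Suppression appears as: condition E models perform well and pass the
permutation test; condition S models hover at chance and fail it, even
though one's own voice is acoustically the loudest stimulus present.

## The synthetic dialogue generator

Real dialogue corpora cannot ship with a package, and no recorded corpus
has ground truth for the response kernel. The generator
(`dialogue_spec()`, `sample_dialogue()`, `synthesize_eeg()`) produces
sessions in which every downstream claim can be scored against known
truth:

* **Turn-taking**: two speakers alternate; turn lengths and pauses are
  exponential (memoryless — the simplest defensible model), defaults 1.5 s
  turns and 0.5 s pauses, close to conversational IPU statistics. With
  probability `overlap_prob` (default 0.2) a turn onset overlaps the other
  speaker's ongoing turn, so the B condition occurs.
* **Features**: 16 band streams, zero outside speech. Inside speech each
  band is an amplitude-modulated noise profile: per-band modulators
  (low-passed at ~16 Hz) mixed tridiagonally across adjacent bands plus a
  slow global ~4 Hz syllabic-rate component. This gives the
  distance-decaying band correlation of real mel spectra (adjacent bands
  ~0.7, distant bands ~0.1). A uniform global factor was rejected: it
  yields near-singular designs in which per-band kernels are not
  identifiable at realistic SNR, which would make kernel-recovery tests
  meaningless. Feature streams, not waveforms, are the primary product;
  audio is only needed to exercise the feature extractors, which are
  tested on constructed tones instead.
* **EEG**: per channel, the causal convolution of the features with a
  smooth multi-peak kernel (`make_kernel()`, peaks at 50/125/250 ms,
  emulating auditory evoked morphology), with separate gains for the
  other's stream (`gain_other`) and one's own (`gain_self`; 0 encodes full
  suppression), plus 1/f background noise (spectral shaping, exponent 1).
* **SNR definition**: `calibrate_noise_sd()` sets the noise SD so that
  `var(signal)/var(noise)` equals the requested SNR *over the analyzed
  condition's samples*. Session-wide variance is dominated by
  speech/silence block alternation and would overstate the usable SNR
  several-fold; the condition-restricted definition is the one that
  governs encoding performance.
* **Microphone crosstalk** is an observation effect, not a brain effect:
  `apply_crosstalk()` adds an attenuated copy of the other's features to
  one's own microphone stream, which is what lets a "self" model pick up
  a weak response to the *other's* leaked voice when both speak — the
  same artifact discussed for directional microphones in real recordings.

What the generator does **not** emulate: phonetics or intelligible speech,
ocular/muscle artifacts, electrode drift, inter-subject anatomical
variability. Passing tests therefore validate the *estimation machinery*
(identifiability, calibration, error control), not robustness to real-EEG
artifact structure.

## Numerical and design choices

* **Lag window**: 600 ms at 128 Hz with the first 3 ms discarded (the
  acoustic travel time over ~1 m) gives integer lags 1..77; the envelope
  design has 77 columns and the 16-band spectrogram 77 × 16 = 1232. Lag 0
  is excluded, so designs are strictly causal.
* **Ridge and alpha**: plain fixed-alpha ridge on centered data via
  Cholesky-factored normal equations (deterministic; matches a direct
  solver to < 1e-8). Alpha is selected per channel on each training split
  by inner 3-fold cross-validation over a log grid 1e-2..1e6 (13 points),
  with a **one-SE parsimony rule**: the largest alpha whose mean held-out
  correlation is within one standard error of the best. On informative
  data the SE is tiny and the rule reduces to the argmax (noiseless data
  select the grid minimum); on uninformative data it prefers strong
  regularization instead of chasing noise. Inner folds are contiguous
  blocks of the training rows; outer folds are contiguous, unshuffled
  fifths, and weights/correlations are averaged over folds before any
  across-participant averaging.
* **Permutation test**: whole training rows of the design are shuffled
  (each row keeps its internal 600 ms lag structure), the model is refit
  with the original alpha, and the original held-out set is predicted;
  p = (N_exceed + 1)/(N_perm + 1) with strict exceedance, so p can never
  be 0 and is bounded by 1/(N_perm + 1). The default is 3000 permutations;
  desk-scale runs use 200. A channel is significant when p stays below
  `alpha_fw / n_channels` in every fold. The Bonferroni divisor defaults
  to the actual channel count (128 in the full montage gives the standard
  3.9e-4 threshold; at 128 the threshold is unreachable with only 200
  permutations, which is a resolution fact, not a bug).
* **Band filters**: window-method (hamming) FIR at the canonical edges
  (Delta 1–4, Theta 4–8, Alpha 8–13, LowBeta 13–19, Broad 0.1–40 Hz),
  transition bandwidth `min(max(0.25·low, 2), low)` Hz, edge-value
  padding. Zero-phase applies the linear-phase filter with group-delay
  compensation; the causal option converts it to minimum phase
  (homomorphic/cepstral), guaranteeing no output before input at the cost
  of a positive delay that propagates into mTRF latencies — the classic
  ~50 ms causal-filter shift. Decimation applies an anti-alias low-pass
  before integer sub-sampling (plain sub-sampling would alias the synthetic
  tests); filtering happens at the native rate, then decimation, then
  z-scoring.
* **Envelope**: modulus of the analytic signal (FFT Hilbert), averaged
  over 125-sample windows, min–max normalized to [0, 1] (guarded for
  silence). The windowing is causal; the Hilbert kernel itself has weak
  non-causal 1/t tails, as in the standard tool chain. Spectrogram bands
  are min–max normalized per band to match the envelope contract.
* **Wilcoxon**: exact signed-rank p from the null distribution when
  untied (any n up to 1023), exhaustive 2^n sign-flip enumeration when
  tied and n ≤ 16, tie-corrected normal approximation beyond. Zeros are
  dropped; all-zero differences are degenerate (the lateralization test
  reports p = 1 with a warning). Twelve same-sign pairs give the exact
  two-sided p = 2/4096 ≈ 0.00049.
* **Bayes factors**: JZS paired-t with Cauchy prior scale √2/2, by
  numerical integration; evidence labels: log10 BF10 > 0 positive, > 0.5
  substantial, > 2 decisive. Paired Cohen's d uses the sample SD of the
  differences.
* **TFCE**: extent exponent 0.5, height exponent 2, threshold start 0 and
  step 0.2, 4-connected clusters on the feature × lag grid, positive and
  negative parts enhanced separately; significance from the sign-flip
  permutation distribution of the maximum absolute enhanced value
  (family-wise control), with exhaustive enumeration when the permutation
  count reaches 2^subjects.
* **PLV**: phases from the analytic signal of the band-passed series
  (envelope 4–8 Hz, zero-phase so latencies are not filter-shifted; EEG
  supplied in its analysis band). The lag grid is every integer sample
  covering −200..400 ms (±200/400 ms are not on the 128 Hz sample grid,
  so the grid spans −203.1..406.3 ms). Positive lag means the EEG follows
  the envelope: the scan shifts the envelope back by τ, so a causally
  delayed EEG copy peaks at its true positive delay (125 ms for a
  16-sample delay). Condition samples are concatenated as one trial;
  samples within one low-edge period (default) of a segment boundary are
  dropped against edge artifacts.
* **Lateralization**: the two hemispheres' frontal selections (12
  channels each) are rank-matched — channels sorted by mean correlation
  within each hemisphere and paired by rank — and compared by the exact
  signed-rank test.

## Problem sizes used by the test suite and acceptance script

These are the package's own desk-scale study conditions: kernel recovery
runs on a 150 s session with 4 channels at condition-SNR 10 and a 7-point
alpha grid (mean mTRF–kernel cosine similarity is the score); suppression
recovery on a 150 s, 8-channel session with 200 permutations and the
all-folds Bonferroni rule; null calibration on 200 replicate 60 s sessions
with envelope designs and 1/f-noise EEG (Kolmogorov–Smirnov distance to
uniform); TFCE calibration on stacks of 12 subjects with a d = 2 cluster
injected into bands 6–10 × lags 10–20 and 256 sign-flip permutations.
Longer sessions sharpen every recovery metric (the 150 s cosine ~0.97
rises to ~0.98 at 300 s); these sizes were chosen as the smallest that
leave comfortable margins.

## Known limitations

* The generator's linearity matches the model family; it cannot probe
  robustness to nonlinear cochlear/cortical transforms.
* With strongly collinear designs (features nearly identical across
  bands), the per-band decomposition of the mTRF is not identifiable even
  when predictions are perfect; recovery claims assume the generator's
  realistic, distance-decaying band correlation.
* Real-data ingestion covers WAV audio, interval CSV/TextGrid annotations
  and plain-matrix EEG; proprietary EEG container formats are out of
  scope, as are ICA artifact removal (a pass-through hook marks the
  stage), pitch/shimmer features, and noise-ceiling correction (undefined
  for unscripted continuous recordings).
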