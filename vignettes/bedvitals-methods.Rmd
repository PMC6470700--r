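---
title: "Methods: beat detection in the bed-mounted ballistocardiogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat detection in the bed-mounted ballistocardiogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedvitals)
```

## The measurement and its signal model

A load cell coupled to the mattress along the longitudinal (head–foot)
axis of a bed measures, superimposed on a static preload of a few to a
few tens of newton, the recoil forces of the body: the cardiac
ballistocardiogram (BCG), the respiration forces, broadband sensor noise
and mains interference. At the 84.8 Hz sampling rate of the acquisition
front-end, 50 Hz interference is under-sampled and aliases to 34.8 Hz,
inside the Nyquist band of 42.4 Hz. A single-lead ECG sampled at three
times the force rate (254.4 Hz) serves as the timing reference for
evaluation only; it plays no part in the BCG detection itself.

The BCG of a healthy subject presents a quasi-periodic wave complex per
heartbeat whose systolic portion — the upward H, J, L tips alternating
with the downward I, K troughs — forms a characteristic "W". The
morphology varies between people, between lying positions and slowly over
time, which motivates an unsupervised, training-free detector that only
assumes short-term consistency of the waveform.

## Band separation

The cardiac component is extracted by a cascade of two linear-phase FIR
filters: an 80-tap low-pass at 15 Hz and a 540-tap high-pass at 0.5 Hz.
The band and the lengths are fixed design inputs; the design *method* is
open, and this package uses Kaiser-windowed ideal responses with the
window parameter chosen from the target deviation (passband ripple
5e-5, stopband 1e-4 as linear fractions of unity gain — the tests verify
both levels on probe sinusoids). Two details matter:

* With an even tap count a symmetric high-pass necessarily has a zero at
  the Nyquist frequency. That region is removed by the cascaded low-pass
  anyway, so the constraint is harmless here. The high-pass taps have
  their mean subtracted, which nulls the DC gain exactly while keeping
  the impulse response symmetric.
* Both impulse responses are exactly symmetric, so the cascade is exactly
  linear-phase with a group delay of (80−1)/2 + (540−1)/2 = 309 samples
  (about 3.6 s). `cardiac_component()` shifts the output left by exactly
  this delay, re-aligning the filtered signal with the raw time base.
  Before convolution the signal is extended by replicating its edge
  samples; without this, the preload step (thousands of mN against a
  cardiac signal of tens of mN) would contaminate several seconds at each
  end of the recording.

The respiratory component uses a single 3rd-order Butterworth band-pass,
0.05–0.5 Hz. Normal adult respiration spans about 8–30 breaths/min
(0.13–0.5 Hz); the lower edge is deliberately generous. By default the
filter runs forward–backward so its phase cancels exactly; a forward-only
mode reproduces single-pass behaviour (the Butterworth phase in this
narrow band is mild but non-zero) for fidelity to real-time processing.

## The clustering detector

Processing is segmented: windows of 10.66 s stepped every 10 s, the
0.66 s overlap equal to the feature-vector span, so that a candidate wave
too close to a segment's end to host a complete feature window reappears
intact at the head of the next segment. Within a segment:

1. Local maxima of the filtered signal (sign changes of the first
   difference from positive to non-positive; plateaus resolve to their
   first sample) are the candidate upward waves.
2. Each maximum anchors a feature vector: every second sample of the
   0.66 s that follow, 28 features at 84.8 Hz. The span corresponds to
   one cardiac cycle at 90 bpm; decimation by two is lossless in practice
   because the signal is already low-passed at 15 Hz, half the decimated
   Nyquist.
3. Pairwise dissimilarity is the angle between feature vectors,
   `acos(x'y / |x||y|)` — a pure shape measure, insensitive to the
   breathing-driven amplitude modulation of the waves — **gated** to the
   maximal value π when any of three conditions indicates the pair cannot
   be successive waves of the same type: magnitude ratio outside
   [1/3, 3]; anchors closer than 0.33 s (which caps usable heart rates
   just below 182 bpm); chronological order difference below `i_min`.
4. Complete-link agglomeration merges clusters by their *most dissimilar*
   cross pair. This is what makes the gating effective: a single gated
   pair keeps two clusters apart below the cut, whereas single-link would
   chain around it. Merge heights are monotone non-decreasing, which the
   implementation asserts on every run; equal-height merge candidates
   merge in lexicographic order of their earliest member times so output
   is deterministic.
5. The dendrogram is cut at θ = 1.2 rad: a cluster survives iff all its
   internal merges lie strictly below θ. The largest surviving cluster is
   taken to represent the heartbeat waves; ties fall back to the lowest
   mean pairwise dissimilarity, then to the earliest first member.
6. The whole procedure runs twice, with `i_min = 3` and `i_min = 2`. The
   normal morphology offers at least three upward waves per cycle, and
   `i_min = 3` prevents two different wave types of the same cycle from
   clustering. At high rates superimposition can leave only two upward
   waves per cycle, where `i_min = 3` is wrong; the `i_min = 2` result is
   adopted only when the population standard deviation of its
   within-segment beat-to-beat rates is strictly smaller, otherwise the
   `i_min = 3` result stands.

Beat times are the anchoring maxima of the chosen cluster — whichever
wave type the cluster happens to represent. No attempt is made to
canonicalise to the J wave: consecutive segments may legitimately track
different types, which is precisely why intervals spanning a segment
boundary are flagged and never rated. Within a segment the gating
guarantees consecutive beats at least 0.33 s apart; across a boundary the
wave-type switch can place two detections closer, and only exact
duplicates from the overlap (within 0.05 s) are removed when segments are
concatenated.

## Reference ECG and evaluation

The ECG is used unfiltered. Clean recordings need only an absolute
amplitude threshold on local maxima. Under baseline drift the absolute
level is meaningless and each peak's immediate rise above its preceding
local minimum is compared with 0.6 times the recording-wide median rise.
Under strong mains interference most local maxima are interference
crests, and a peak is retained when its rise exceeds 1.2 times the moving
average of the rises of the 8 surrounding peaks: interference crests then
sit *below* their own neighbourhood average-times-coefficient while QRS
rises stand clearly above it. A coefficient below one — comparing each
rise against a *fraction* of the neighbourhood average — cannot separate
the two populations once interference crests dominate the average, which
is why the default is 1.2. All modes end with a refractory pass
(strongest peak wins within 0.33 s, matching the BCG timing gate). These
thresholds are package defaults validated on synthetic data only; all are
exposed in `qrs_params()`. A spectral heuristic (`mode = "auto"`) picks
the mode from the energy below 1 Hz and near the mains line, mirroring
the per-recording choice an operator makes by eye.

Evaluation walks the reference cycles (consecutive R–R intervals).
Correct means: exactly one BCG detection in the cycle, integer
beat-to-beat rates agreeing within 5 bpm, and the detection's offset from
the cycle start within 0.15 s of the segment's modal offset. The last
condition operationalises "same wave type as the segment majority", which
a human assessor judges visually; 0.15 s is roughly the spacing of
adjacent wave types and well below the minimum cardiac cycle. Failures
split into false positives (more than one detection in the cycle), false
negatives (none) and misplaced (a lone detection failing the rate or
offset test); their sum is the not-correct count, and the detection
percentage is `100·(detectable − not correct)/detectable`, rounded half
away from zero to one decimal. Detectable excludes the cycles straddling
segment boundaries (29 in a 5-minute recording) and — when the caller
passes `t_max` — cycles ending within one feature window of the end of
the recording, where the detector cannot emit a beat by construction.
The rate attributed to a lone detection is its forward interval, falling
back to the preceding interval when the forward one is boundary-flagged.

Aggregation over measurements is the unweighted mean of the detection
percentages (equal recording lengths, equal weights). The package bundles
the per-measurement results of a published seven-volunteer, four-position
evaluation of this detector as `reference_detection_table()`; the
aggregation reproduces its per-position, per-volunteer and overall
summary rates from the printed counts.

## The synthetic generator

Real bed recordings of this kind are not publicly deposited, so the
package ships a generator that emulates the signal structure with known
ground truth: DC preload (N, stored as mN), sinusoidal respiration, one
Gaussian-lobed wave complex per heartbeat, optional white noise and
optional 50 Hz interference; the ECG channel is a spike train
phase-locked to the true beat onsets with optional drift and
interference. Scenario defaults are fixed study-like conditions:
5 minutes, 60 bpm, 15 breaths/min, 15 N preload (the field measurements
used 4–5 N and 12–21.5 N), J-wave amplitude 30 mN and respiration
amplitude 60 mN — cardiac and respiratory components of comparable
magnitude, as the longitudinal mounting delivers. The normal template
carries the G–N wave series with the W-shaped H–L core; its latencies
compress proportionally once the cycle drops below 0.75 s, mimicking
superimposition. A two-wave variant (J and a similar, slightly smaller L
at 0.15 and 0.62 of the cycle) exercises the dual `i_min` logic: with
three-wave spacing gone, `i_min = 3` gates all same-type pairs and
degenerates, while `i_min = 2` recovers every cycle — and disabling the
index gate entirely on the same signal produces the duplicate detections
the gate exists to suppress. Premature-beat timing (every *n*-th interval
rescaled, default 20% shortening when enabled) and uniform interval
jitter cover arrhythmic patterns. A single integer seed fixes the entire
realisation; generation restores the caller's RNG state.

What the generator deliberately does **not** model: movement artifacts
beyond optional noise, subject-to-subject morphology variability,
mattress mechanics, or a validated haemodynamic preload–amplitude law
(the observed coupling is available only as an optional proportional
scaling). Passing tests on these signals therefore demonstrates the
correctness of the algorithmic chain under its stated assumptions, not
field performance on real patients — the bundled reference table is the
record of the latter.

## Numerical and design choices

* **Derivative and maxima.** First-order forward difference; maxima at
  `+ → ≤0` sign changes, plateaus to the first sample. Feature windows
  decimate at phase 0 (offsets 0, 2, 4, ...), 28 samples.
* **Numerical floor.** Feature vectors with magnitude below 1e-6 mN are
  discarded as floating-point residue of physically flat signals; the
  angular measure is undefined at zero magnitude.
* **Gate tolerances.** The time gate compares with a 1 ns slack and the
  magnitude-ratio gate with a 1e-12 relative slack so that borderline
  equality (e.g. beats exactly 0.33 s apart at 181.8 bpm) behaves as the
  inequality intends under floating point.
* **Tie-breaks.** Merge ties by earliest member time; selection ties by
  mean dissimilarity, then earliest member. Both are asserted
  deterministic in the tests, and the clustering path is checked
  merge-for-merge against a brute-force agglomerator that recomputes the
  complete-link distance from scratch at every step.
* **σ comparison.** The dual-run comparison uses the population standard
  deviation of within-segment beat-to-beat rates; runs with fewer than
  three beats get σ = ∞ (one interval cannot attest consistency), and
  ties keep `i_min = 3`.
* **Segmentation.** A trailing window is opened only when it extends past
  the previous segment's end by at least half a sample, so a recording of
  exactly one window length yields exactly one segment and a 5-minute
  recording yields 30.
* **Problem sizes in the tests.** The oracle-equivalence property runs
  220 random instances of up to 10 vectors; end-to-end checks use 60 s
  recordings over 50–170 bpm and 120 s recordings for rate-readback
  checks — sizes at which the whole suite completes in well under a
  minute while every code path (dual run, boundary handling, all three
  QRS modes) is exercised.

## Known limitations

* The detector reports whichever wave type clusters best; applications
  needing a fixed fiducial (e.g. pulse-transit-time work) would need
  J-wave canonicalisation on top.
* Sustained rates above ~180 bpm violate the 0.33 s timing gate by
  design.
* The misplaced-detection criterion depends on a modal offset per
  segment; in a segment where fewer than half the detections are of the
  majority type the criterion can mislabel individual cycles.
* The QRS noise-mode thresholds are validated against synthetic drift and
  interference only; real electrode artefacts are more varied.
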