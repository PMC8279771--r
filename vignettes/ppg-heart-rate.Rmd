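---
title: "Estimating heart rate from fingertip-video brightness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heart rate from fingertip-video brightness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgtrace)
```

## The measurement problem

When a fingertip is pressed against a smartphone camera with the torch or
ambient light behind it, the mean red-channel intensity of each video frame
tracks the blood volume in the skin: a photoplethysmogram (PPG) obtained
with no equipment beyond the participant's own phone. This makes cardiac
measures available to fully remote experiments, at the price of
considerable noise — uncontrolled devices, variable frame rates, finger
motion — and of a beat detector that sometimes skips a pulse or counts one
pulse twice.

`ppgtrace` implements a complete pipeline from such recordings (or from
precomputed per-frame brightness CSVs) to per-participant heart-rate
change ratios:

1. whole-frame red-channel mean per frame (`extract_brightness`);
2. resampling of the trace to a canonical 30 frames/s (`resample_to_fps`);
3. band-pass filtering over 0.67–3.83 Hz — about 40–230 beats/min — with
   a second-order Butterworth filter (`bandpass`);
4. discrete double differentiation to sharpen the systolic wave
   (`second_difference`);
5. peak detection on the curvature trace (`detect_peaks`);
6. pulse-to-pulse intervals (PPIs) and a harmonic-tolerant estimate of the
   average interval and heart rate (`estimate_m_prime`).

## The robust average-interval estimator

Detected intervals come in three flavours: accurate ones, doubled ones
(a missed beat merged two cycles) and halved ones (a spurious detection
split one cycle). A plain mean is badly biased by either failure, so the
average interval M′ (frames) is defined as the minimiser of

$$ f(M') \;=\; \sum_k \min_{a \in \{2,\,1,\,0.5\}} \big(a\,\mathrm{PPI}_k - M'\big)^2 $$

evaluated exhaustively on the grid 15 to 40 frames in steps of 0.01 (45 to
120 beats/min at 30 frames/s). Each interval is matched under its best
harmonic correction: a halved interval is doubled (a = 2), a doubled one
halved (a = 0.5). The average heart rate is the reciprocal interval,
h = 60·fps / M′. Exhaustive grid evaluation is deliberate — the grid is
small, and exactness lets the estimator be checked bitwise against a
brute-force oracle in the test suite.

### Aliases and the selection rule

The loss has a structural subtlety beyond exact ties. For constant
intervals p, both p and 2p (or p/2) can zero the loss when inside the
grid; that is the exact-tie case. But with any jitter the branches are
*asymmetric*: matching every interval at a = 0.5 against M′ = p/2 rescales
every residual by one half, so the half-interval branch carries one
quarter of the loss of the true branch. For any true rate at or below 60
beats/min (p/2 ≥ 15 frames, inside the grid) the *global* minimiser is
therefore the half interval, and the naive arg-min doubles the heart rate
of a perfectly healthy recording.

Because raw losses are not comparable across alias branches, the
estimator selects among candidates — the global minimiser plus local
minima of the loss curve lying at a harmonic multiple of it (within 10%,
and within an `alias_guard` (default 20×) sanity bound of the minimum) —
by assignment structure:

1. the candidate assigning the most intervals to a = 1 (unscaled
   intervals are direct observations; rescaled ones are corrections);
2. among those, the smallest loss;
3. then the candidate closest to the median interval;
4. then the smallest M′.

With a zero global minimum this reduces exactly to tie-breaking among the
zero-loss aliases (constant 18-frame intervals select 18, not 36). The
estimate reports `tie_detected` when near-minimal losses occur more than
one frame apart, `alias_corrected` when the selection overrode a strictly
better global minimiser, and `boundary_hit` when the optimum clamps to a
grid endpoint (a rate outside 45–120 bpm at 30 fps); all three surface in
quality control.

## Preprocessing choices

**Zero-phase filtering.** The band-pass runs forward and backward by
default so that peak times are not delayed (a causal mode exists via
`filter_spec(zero_phase = FALSE)`). The effective amplitude gain is then
the squared magnitude response — exactly 1/2 at each cutoff — which the
test suite verifies against the analytic prewarped Butterworth response
to within 1%. Before filtering, the series is padded by odd reflection;
without it the implicit zero extension treats the ~100-unit DC brightness
level as a step and rings far into a 30-s recording.

**Double differentiation.** `second_difference` is the plain discrete
operator y[i] = x[i+1] − 2x[i] + x[i−1]; the output shrinks by two frames
and carries a frame offset so peak indices map back to original frames.
Differentiating twice amplifies a component of frequency ratio j by j²,
which is what makes the sharp systolic wave dominate — and what makes the
pipeline sensitive to high-frequency noise, the motivation for the band
pass above.

**Peak detection.** Strict local maxima of the curvature trace are kept
when their topographic prominence reaches a threshold, and a minimum peak
separation of `floor(fps · 60/230)` frames (one interval at the top of
the pass band) is enforced, higher peaks winning. The default threshold
is 2× the raw median absolute deviation of the trace. The factor was set
by a separation argument rather than convention: on an oscillatory trace
the prominence of a genuine beat is ≈2.5× the raw MAD (peak plus the
descent into the flanking valley), while ghost wiggles riding the flat
segment left by a dropped beat — filter leakage bracketed by deep
valleys — reach ≈1.5×; a threshold of 1× MAD sits inside the ghost band
and lets skipped beats resurface. Both parameters are configurable, and a
`flip` flag detects minima instead for signals of opposite polarity.

## Study-level analysis

`estimate_period_hr` runs the whole chain on one analysis window. By
default the full recording is filtered before the window is trimmed
(`filter_first = TRUE`): the stimulus windows [5, 90) and [90, 175) s of a
180-s recording cut 5 s at the outer edges precisely to discard filter
transients, which only works if filtering precedes the cut. The baseline
is the first 30 s of the trial recording.

`participant_change_ratios` estimates the baseline rate h_b, the two
period rates h_p1 and h_p2 (per stimulus, then averaged across the
stimuli; a pooled-interval mode concatenates PPIs across stimuli
instead — the two agree within about a beat per minute on clean data) and
forms the response variables ln(h_p1/h_b) and ln(h_p2/h_b).

**Quality control.** A participant is excluded when any period estimate
has fewer than 20 intervals, a loss per interval above (2 frames)², more
than half its intervals harmonically rescaled at the optimum, or a
grid-boundary hit; estimation failures and non-finite ratios also
exclude. Near-tie flags are recorded but do not exclude by default (the
selection rule resolves them deterministically); `qc_config` exposes all
thresholds. Exclusions are monotone: tightening any threshold can only
grow the excluded set.

## What the synthetic generator emulates

Every stage is testable without recordings via `synth_ppg` /
`generate_cohort`, which simulate the full study design: a 30-s trial
recording at a participant's baseline rate and four 180-s stimulus
recordings whose second half embodies a group effect on ln(h_p2/h_b).

**Waveform.** Each beat contributes a raised-cosine absorption dip,
w(φ) = −Σⱼ hⱼ(1 − cos 2πjφ): at systole the extra blood absorbs light and
brightness dips. The shape is continuously differentiable with zero slope
at cycle boundaries, so per-beat amplitude changes join without kinks,
and its curvature maximum lies at the dip centre — one detection per
beat. The default second harmonic is 0.05: components above 1/16 create a
second curvature maximum every cycle after the j² amplification, i.e.
systematic double counting that no averaging scheme can undo, which is
not the single-peaked morphology of real filtered fingertip traces.

**Heart-rate variability.** Beat gaps are 60/hr with independent Gaussian
jitter on the instantaneous rate (SD 3 bpm, a typical resting value);
no autocorrelated variability is modelled.

**Noise.** The trace is a whole-frame mean over ~10⁶ pixels, so the
shot/quantisation floor is ~0.002 brightness units against a unit pulse;
the default white noise SD of 0.02 is ten times that floor to allow for
codec and exposure noise. Slow drift (2 units at 0.25 Hz, respiration-like
and below the pass band) and sporadic motion transients complete the
model. Transients are 0.15-s Gaussian bumps of height 3 — a finger shift
spans several frames, and a single-frame delta would have a physically
implausible flat spectrum. Their default rate, 0.25 per minute, was
calibrated so that the default cohort, under the default QC thresholds,
loses roughly 40% of participants — the one published yardstick of
smartphone-PPG data quality at desk scale being an exclusion rate of
40.00% in a comparable remote study.

**Artifacts.** The two detection failures are injected with ground-truth
logs. Missed pulses attenuate a beat's amplitude to 2%, sampled with at
least two live beats between misses (closer misses merge three or more
cycles, which the scale set {2, 1, 0.5} cannot represent — the modelled
failure is a single skipped beat). Spurious detections are additive
narrow dips of amplitude 1.0 (about half the main dip depth, an
exaggerated dicrotic wave) planted midway between two genuine detection
points, so both resulting intervals are half-length; the amplitude
compensates the main waveform's boundary curvature, which cancels about
1.2 units of the bump's own.

**What passing tests do not show.** The generator has no rolling shutter,
auto-exposure, compression blocking, finger repositioning, or
autocorrelated heart-rate dynamics; recovery on these simulations
demonstrates the pipeline's logic (filtering, detection, harmonic
absorption, baseline normalisation), not field performance on arbitrary
phones. The ~40–50% simulated exclusion rate is a reminder that a large
fraction of real remote recordings is expected to be unusable.

## Numerical conventions and problem sizes

Time is measured in half-open windows [start, end) with frame timestamps
(i − 1)/fps; grid values are snapped to 10 decimal places so exact
constants (22.5) compare cleanly; exact ties use an absolute tolerance of
10⁻⁹ on the loss; near-constant inputs are rejected before peak detection
(after band-passing, only filtering roundoff would remain and would
hallucinate peaks). Simulation-based tests use 90-s single recordings, 10
replicates per artifact condition and one 30-per-group cohort (each
participant: one 30-s trial plus four 180-s stimuli at 30 fps); the whole
suite runs in about a minute and the acceptance script in well under one
minute on a single core.

## Known limitations

- Rates outside 45–120 bpm clamp to the grid boundary and are flagged
  rather than estimated; widen `grid_spec` for other populations.
- The alias selection rule favours the unscaled-assignment branch; data
  whose majority of detections are genuinely half-cycles (systematic
  double counting) will still be read at the detected rate.
- Video ingestion operates on in-memory frame arrays or brightness CSVs;
  container decoding (MP4/MOV) is left to external tooling that exports
  either form.
- `locate_sync_marks` is a simple envelope thresholder for clean
  electronic tones; it is not a general audio onset detector.
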