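---
title: "Methods: individualized sound enrichment for hearing-loss tinnitus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized sound enrichment for hearing-loss tinnitus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundenrich)
```

## The model and its assumptions

Chronic tinnitus frequently accompanies sensorineural hearing loss.
The working model behind this toolkit is central gain enhancement:
cochlear damage removes excitatory drive in the loss frequency range,
inhibition around those frequencies weakens, and compensatory gain in the
central auditory pathway raises spontaneous activity that is perceived as
tinnitus. Two observable criteria tie an individual's tinnitus to this
mechanism rather than to somatosensory, metabolic or other etiologies:

1. **Threshold at the pitch.** Under the discordant (outer- vs
   inner-hair-cell) damage account, the mismatch between afferent and
   efferent fiber damage is maximal where the loss is roughly 45--55 dB HL,
   so a tinnitus pitch matched inside such a region is evidence for a
   cochlear origin. The screen therefore requires the interpolated
   threshold at the matched pitch to lie in the closed window
   `[45, 55]` dB HL.
2. **Residual inhibition (RI).** If a minute of narrowband noise at
   MML + 10 dB transiently suppresses the tinnitus, spontaneous
   hyperactivity is plausibly the proximate cause, and re-afferenting the
   deprived region can be expected to help. Only RI-positive patients
   pass.

The therapy sound then supplies energy exactly where input is missing
(the loss band), with extra weight at the tinnitus pitch where the
hyperactivity is presumed maximal. The placebo keeps the identical
carrier, level and schedule but confines the spectrum to frequencies
where hearing is normal, which under the model should be inert.

These are modeling commitments, not certainties: the package computes
stimuli and screens, it does not validate the physiological claims.

## Screening rules

`check_eligibility()` evaluates, in this order for cohort tallies:
organic cause (external flag), pitch-threshold window, RI outcome,
profound loss (any threshold strictly above 90 dB HL), chronicity
(strictly more than 6 months), tonality, and presence of any hearing
loss. A record failing several criteria is excluded once, under the first
triggered reason, so cohort arithmetic (admitted = included + sum of
exclusions) always closes. The boundary conventions are deliberate:
45 and 55 are both eligible, a 90 dB HL threshold is retained while 91 is
excluded, and a 6-month duration is not yet chronic.

Group allocation (`randomize()`) is a seeded shuffle with a ratio split.
No block structure is imposed; unequal arms are produced by the ratio
alone.

## Stimulus synthesis

All stimuli start from seeded Gaussian white noise at 44100 Hz
(`gaussian_noise()`), scaled to a digital RMS of 0.1 full scale. Filtering
is zero-phase multiplication in the frequency domain: an envelope is a
piecewise gain curve, linear in (log2 frequency, dB) between knots, with
raised-cosine transitions from the passband edge down to a stopband floor.
This was chosen over IIR/FIR band-pass designs because the band edges are
exact, there is no ripple to confound spectral verification, and the
transition width is a single interpretable parameter in octaves.

* **v1 (loss compensation).** Passband = the loss region
  `[f_start, f_end]` (thresholds above the 15 dB HL normal cutoff). The
  in-band gain is `(threshold(f) - 15)` dB, normalized so the passband
  maximum is 0 dB: deeper loss receives relatively more energy. A flat
  alternative is available via `synthesis_config(v1_shape = "flat")` for
  users who prefer equal-energy enrichment.
* **Smoothing rule.** The transition width is
  `w = clamp(c / delta, w_min, w_max)` octaves with `c = 10` dB·octave,
  `w_min = 0.05`, `w_max = 1`, where `delta` is the absolute threshold
  step between the loss onset and the nearest measured frequency with a
  normal threshold. Only the inverse proportionality is dictated by the
  protocol ("large difference, low smoothing"); the constant and clamps
  are this package's quantification, chosen so that a typical abrupt
  40 dB onset yields a quarter-octave edge and a shallow onset never
  smears more than one octave. A `delta` of zero returns `w_max`.
* **v2 (pitch emphasis).** Flat unit passband exactly
  `[0.9, 1.1] * pitch`, fixed narrow 0.02-octave edges. Mixed over v1 at
  +6 dB (`emphasis_gain_db`): because both carriers share the same
  pre-filter RMS and v1's plateau is normalized to 0 dB, a deterministic
  linear factor of `10^(6/20)` realizes the intended PSD offset without a
  measurement step. The protocol specifies no mix ratio; +6 dB makes the
  pitch maximum unambiguous against PSD estimation noise (about 0.3 dB at
  60 s) while keeping the loss band audible.
* **v3 (study sound)** = v1 + scaled v2, RMS-normalized, peak-limited to
  0.999 full scale if needed. v1 and v2 use independent carriers seeded
  `seed` and `seed + 1`, so their PSDs add.
* **Placebo.** Flat passband from the lowest measured frequency up to the
  loss onset `f_start`, transition fixed at `w_min` (low smoothing) so no
  energy leaks into the loss region.

A single convention resolves the onset: `f_start` is the first measured
frequency whose threshold exceeds the normal cutoff. It is simultaneously
the lower edge of the study band and the upper edge of the placebo band,
which keeps the two spectra complementary.

Absolute presentation level is out of scope by design: patients set level
on their playback device per protocol phase, so the digital RMS is only a
normalization constant. Output is mono 16-bit PCM WAV; the 60 s default
duration is intended for gapless looping.

## Spectral verification

`spectrum_report()` uses a Welch averaged periodogram: Hann window,
8192-sample segments, 50% overlap (5.4 Hz bins at 44.1 kHz, about 640
averages per minute of audio). The peak is taken on a 9-bin moving
average to suppress single-bin fluctuations; band edges are read at
-3 dB relative to the passband median; out-of-band rejection is the
passband median minus the maximum PSD beyond a one-octave guard band
(the guard covers the widest permissible transition, and bins below
10 Hz are ignored as DC leakage). Note the rejection is referenced to
the passband *median*: for a strongly tilted v1 passband the median sits
well below the 0 dB plateau, which makes the >= 40 dB rejection check
conservative in the flat-placebo case and tight in steep study cases.

## The synthetic-data generator

`gen_audiogram()`, `gen_profile()` and `gen_cohort()` emulate the
screened population: audiograms normal below a 1 kHz onset, rising at
15 dB/octave from 20 dB HL at the onset with ±3 dB seeded jitter, capped
at 90 dB HL (a profound variant plants one threshold above 90); pitches
placed at a measured frequency whose threshold is in the qualifying
window; TLL a 5--15 dB sensation-level offset above the pitch threshold
and MML 5--10 dB below TLL, echoing the reported pretreatment levels;
durations drawn from 14--52 months. Jitter is bounded so a record's
screening category can never flip stochastically, and each non-eligible
category violates exactly its defining criterion. The default cohort
counts (96 eligible; 6 organic, 11 pitch-out, 10 RI-negative, 4 profound
among 127) mirror the protocol's published participant flow.

What the generator does *not* emulate: measurement noise correlated
across frequencies, non-sloping (notched, flat, rising) loss
configurations, bilateral asymmetry (one audiogram per record), RI
psychophysics (the outcome is an input flag), or longitudinal outcome
trajectories. Passing tests therefore demonstrate correctness of the
screening arithmetic and stimulus construction under the intended
audiometric shape, not robustness to every clinical audiogram.

## Numerical choices and degenerate inputs

Threshold interpolation is linear in log2-frequency (octave convention),
exact at knots, error outside the measured span. Envelope evaluation
clamps frequency to a positive floor before log2 and holds the stopband
floor beyond the outermost knots, so DC and Nyquist bins are attenuated.
An all-zero signal cannot be normalized; an empty signal cannot be
written; a fully normal audiogram has no loss region (study synthesis
errors, as does placebo synthesis, which additionally requires normal
hearing below the onset). A tinnitus pitch outside the loss region
warns — the stimulus is still produced, since pitch matching and
audiometry can disagree near the edge — and the condition is recorded in
the signal's metadata. Test-suite and example problem sizes (4--20 s
stimuli for property checks, 60 s for carrier-statistics checks) were
chosen to keep PSD estimation error near 0.3 dB while the whole suite
runs in seconds.

## Dosing

`build_plan()` emits the three-phase schedule (6, 3, 2 h/day over months
0--1, 1--3, 3--6). Level anchors quantify the verbal rules with one 5 dB
step — the audiometer's minimum — relative to the profile: phase 1 one
step above TLL (the comfort ceiling stays a device-side instruction),
phase 2 MML + 5, phase 3 TLL − 5. `adherence_summary()` buckets a daily
minutes log into phases at 30 days/month and reports mean daily time and
the fraction of logged days meeting the phase target; it is a bookkeeping
remedy for the protocol's acknowledged lack of usage monitoring.

## Known limitations

dB HL is an audiometric, per-frequency-calibrated scale; converting the
synthesized spectra to actual sound pressure on a given headphone would
require transducer calibration data that is explicitly out of scope.
The 45--55 dB HL window, the smoothing constants and the +6 dB emphasis
are protocol constants, not fitted quantities; nothing in the package
estimates them from data. Clinical outcome modeling (questionnaire
scores, repeated-measures analyses) is likewise out of scope: the
package builds and verifies the intervention, it does not evaluate it.
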