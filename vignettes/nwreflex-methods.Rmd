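---
title: "Methods: laser-evoked withdrawal-reflex analysis and its synthetic cohorts"
author: "nwreflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laser-evoked withdrawal-reflex analysis and its synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwreflex)
```

## The measurement problem

After spinal cord injury (SCI), spinal circuits below the lesion can become
hyperexcitable. One window onto that state is the nociceptive withdrawal
reflex: a brief radiant-heat (laser) pulse applied to the skin of the leg
activates thinly myelinated A-delta fibers (conduction velocity roughly
5--30 m/s) and unmyelinated C-fibers (roughly 0.5--2 m/s), and a
hyperexcitable cord answers with bursts of muscle activity recordable by
surface EMG over the tibialis anterior (TA) and soleus (SO). Because the two
afferent classes conduct at such different speeds, their reflex components
separate cleanly in time: an early window (TW1, 90--600 ms after the pulse)
carries the A-delta component and a late window (TW2, 1000--3000 ms) the
C-fiber component. The analysis this package implements takes stimulus-locked
two-channel EMG epochs (1000 Hz, -500 to +3000 ms around the pulse), detects
and characterizes reflex bursts, aggregates them into per-participant
response rates, latencies and magnitudes, estimates afferent conduction
velocity from inter-site latency shifts, and relates the reflex readouts to
clinical scores of spasticity and neuropathic pain.

Raw recordings of this kind are not publicly distributable, so the package
carries a fully specified synthetic-cohort generator with the same
statistical structure. Every stage of the pipeline is tested against data
from that generator, whose ground truth is known exactly.

## Conditioning chain

Epochs are band-pass filtered at 1--450 Hz, segmented, and full-wave
rectified, in that order; detection runs on the rectified trace and phase
counting on the filtered, unrectified trace. Choices the chain had to make:

* **Filter realization.** The band-pass is a cascade of a Butterworth
  high-pass at the low edge and a Butterworth low-pass at the high edge
  (order 4 each), applied forward-backward so that it is zero-phase: onset
  latencies -- the scientific quantity -- carry no filter delay. A direct
  transfer-function band-pass of combined order 8 with a low edge at 0.002
  of Nyquist is numerically fragile; the cascade keeps each polynomial at
  order 4. The upper edge (450 Hz) sits at 0.9 of Nyquist for the canonical
  1000 Hz rate, which the epoch container validates.
* **Startup transients.** Each zero-phase pass starts from the filter's
  steady-state step response scaled by the first (reflection-padded) sample.
  Without this, the 1 Hz high-pass's transient outlives any reasonable
  padding and leaks several percent of a constant offset into the epoch;
  with it, a constant input is attenuated below 1e-7.
* **No resampling.** Data at other sampling rates are rejected with an
  error rather than silently resampled.

## Reflex detection

A reflex is polyphasic EMG activity exceeding two standard deviations above
background noise. The detector makes that operational as follows, with every
constant exposed in `detection_config()`:

* **Background** is the mean and SD of the rectified pre-stimulus window
  `[-500, 0)` ms. The threshold is `mu + 2 * sigma`; including the mean makes
  the threshold invariant to the positive offset that rectification
  introduces.
* **Burst extraction.** A burst opens at the first of at least 6 ms of
  consecutive supra-threshold samples; sub-threshold dips shorter than 50 ms
  are bridged; the burst closes after 50 ms below threshold; bursts closer
  than 50 ms are merged; detection is restricted to `[0, 3000)` ms. The
  persistence requirement keeps the false-positive rate on noise-only
  trials at effectively zero (the per-sample crossing probability is about
  0.05, so six consecutive crossings in noise occur with probability ~1e-8
  per position) while staying short enough that a burst one noise SD above
  threshold is still caught; the constant was calibrated against the
  measured sensitivity/specificity operating characteristics and is exposed
  in `detection_config()`.
* **Polyphasia.** Phases are counted on the unrectified trace as sign-runs
  whose peak reaches half the threshold; an event needs at least 3 phases.
  This suppresses monophasic artifacts (electrode pops, baseline steps).
* **Characterization.** Onset is the burst's opening sample; the magnitude
  is the area under the background-corrected rectified curve (AUC, uV s),
  `sum(max(rect - mu_bg, 0)) * dt`. Absolute AUC depends on amplifier
  scaling, so between-group ratios and orderings, not absolute values, are
  the meaningful readouts.
* **Windows.** Events are labelled TW1 `[90, 600)`, TW2 `[1000, 3000]`,
  `intermediate` `[600, 1000)` or `none`; nothing is silently discarded.
  The boundaries contain the observed latency distributions (early
  components cluster near 190--280 ms depending on site, late components
  near 1200--1500 ms) with room for between-participant spread.
* **Trial-level rules.** A trial with background SD above 30 uV on either
  channel is invalid (movement artifact) and carries no events. A window is
  co-activated when TA and SO both fire there within 100 ms. A response
  trial counts once per window regardless of which muscle fired; the
  trial's window latency is the earliest onset and its AUC the sum within
  the window.

## Conduction-velocity estimation

Stimulating two sites along the same nerve path -- the sole of the foot (FS,
distal) and below the fibula head (FH, about 40 cm proximal) -- shifts the
reflex latency by the travel time between the sites. The estimator takes the
median per-trial latency at each site within a window, forms
`delta = median(FS) - median(FH)`, and reports
`CV = distance / delta`. Medians are used because trials occasionally carry
multiple bursts and the latency distribution is right-skewed. An estimate is
*undefined* -- flagged, not an error and never clipped -- when either site
has fewer than 3 response trials or the shift is not positive. The canonical
worked example (42 cm, 561 ms shift) gives 0.75 m/s, squarely in the
C-fiber range; early-window shifts of only 25--80 ms at 5--17 m/s are at the
edge of what 1 ms sampling and ~10 ms trial jitter can resolve, which is why
early-window estimates scatter more.

## The synthetic cohort generator

The generator's defaults *are* the study conditions; they are not tuned per
test. Each group (SCI, NDC) has a parameter set (`group_sim_params()`):

* **Response structure.** Late-window responder fractions 74% (SCI) and 28%
  (NDC); per-site per-trial response probabilities with cohort means 9.6%,
  14.4%, 14.3% (SCI TW1 at FS/FD/FH), 19.9%, 20.7%, 16.2% (SCI TW2) and
  2.5%, 4.3%, 3.1% (NDC TW2); NDC never responds in the early window.
  Participants are zero-inflated: a non-responder draw contributes zero
  trials, a responder draws a per-site propensity from a Beta distribution
  (concentration 2) whose mean preserves the cohort rate. This reproduces
  both the responder percentages and the wide interquartile ranges of the
  observed per-participant rates (zero to ~35%).
* **Latencies and conduction velocity.** Each participant draws a latent
  C-fiber conduction velocity (SCI 1.34 +/- 0.46 m/s, NDC 1.08 +/- 0.38 m/s)
  and an A-delta velocity uniform on 5.2--16.7 m/s, plus a base latency at
  the proximal site FH (TW1 278 +/- 111 ms; TW2 1257 +/- 158 ms SCI,
  1030 +/- 249 ms NDC, truncated to the windows). Latencies at FD and FS are
  the FH base plus `distance / CV`, so inter-site shifts are
  velocity-consistent *by construction* -- a requirement for testing the CV
  estimator against ground truth. The printed per-site latency tables cannot
  be honored simultaneously with velocity consistency (their site ordering
  is inverted in the early window, an artifact of differing responder
  subsets per site), so the generator anchors proximally and lets distal
  means emerge. Between-participant spread uses the table SDs; within-trial
  jitter is 10 ms (the physiological order of trial-to-trial onset
  variability), plus 5% multiplicative jitter on the per-trial shift.
* **Burst morphology.** A burst is a train of half-sine phases of
  alternating sign, phase duration 10--16 ms (motor-unit-potential scale),
  with per-pair equal amplitudes drawn in 0.6--1.0 of the peak and one pair
  at the peak. The polarity of the second half of the pairs is flipped and
  the amplitude multiset mirrored so that the burst's net area *and* first
  moment cancel: without that, the 1 Hz high-pass smears a slow rebound of
  tens of uV around large bursts and corrupts onsets by ~100 ms. The
  waveform stereotype (phase count, durations, amplitude pattern) is drawn
  once per participant and window -- reflex waveforms are stereotyped within
  an individual -- which also makes zero-jitter configurations exactly
  reproducible trial to trial.
* **Magnitude contrast.** SCI bursts default to 40 times the NDC amplitude
  with 2.5 times the duration (1600 vs 40 uV, both against 5 uV background),
  reproducing the roughly two-orders-of-magnitude AUC contrast; per-trial
  amplitudes carry lognormal variation (sdlog 0.6). The NDC amplitude is
  set so that a planted NDC response is reliably detectable by the 2-SD
  detector -- observed response rates are by definition rates of *detected*
  responses.
* **Muscles.** SCI trials co-activate TA and SO with probability 0.5
  (SO onset within +/-30 ms); NDC trials are single-muscle, TA with
  probability 0.78.
* **Background noise** is Gaussian, band-limited to 20--450 Hz by spectral
  masking (exact band edges, fast, deterministic under seed), SD 5 uV.
* **Pain ratings.** Analgesic participants (all sensorimotor-complete
  injuries, topped up to a 45% SCI marginal) rate every stimulus zero;
  others draw ratings around group means (SCI 3.5, NDC 14.9 on the 0--100
  scale, the across-site averages of the observed per-site means, since the
  parameter is scalar per group).
* **Clinical table.** Neuropathic-pain grading (CPG) is positive with
  probability 8/15; clinically relevant spasticity follows
  `logit P = log(6) + log(1/18) * CPG`, reproducing the observed 2/8 vs 6/7
  inverse association in expectation; joint-level MAS/SCAT scores are
  generated consistently with the any-joint > 1 relevance rule; SCIPI and
  NRS are drawn conditionally on CPG (including occasional discordant
  screens, as observed).

Reproducibility: a single master seed fans out into per-participant and
per-trial substreams, so enlarging the cohort or adding trials never
reshuffles existing participants. Identical configuration and seed give
byte-identical artifact files.

**What the generator does not emulate:** habituation across the 60-stimulus
series, biophysical motor-unit recruitment, reflex receptive fields,
skin-temperature effects, missing stimulation sites (the default cohort
stimulates all three sites in everyone), or volitional contamination of
late responses. Tests passing on this generator therefore demonstrate that
the pipeline recovers the structure it is specified to recover, not that it
is robust to every pathology of real surface EMG.

## Statistical battery

All tests are nonparametric, as the readouts are rates, ranks and small
counts. The primitives are implemented so a brute-force oracle can verify
them exactly:

* **Wilcoxon rank-sum** with midrank ties; exact p by exhaustive
  enumeration of rank assignments for combined n <= 12, otherwise the
  normal approximation with tie and continuity correction. Effect size
  `r = |Z| / sqrt(N)` (< 0.3 small, < 0.5 medium, > 0.5 large).
* **Fisher's exact test** on 2x2 tables: two-sided p sums hypergeometric
  probabilities no larger than the observed table's; effect size is the phi
  coefficient `|ad - bc| / sqrt` of the margin product.
* **Kendall tau-b** by pair counting with tie corrections; p from the
  tie-corrected normal approximation for S.
* **Eta coefficient** `sqrt(SS_between / SS_total)` for binary-vs-metric
  association; where a p-value is reported it comes from the equivalent
  one-way ANOVA F test (eta squared is that model's R squared).

Tails follow the a-priori policy: hyperresponsiveness comparisons
(responders, response rates, SCI greater than NDC) and spasticity-reflex
correlations are one-tailed; everything else is two-tailed. Alpha is 0.05
and no multiplicity correction is applied; the report carries the number of
tests run. Missing data are removed pairwise per test and each row reports
its n. Group comparisons use the late window (the only window with responses
in both groups); the clinical association analyses use the all-window
response rate.

Two conventions worth making explicit: summary SDs are sample SDs by
default (a population-SD convention differs in the second decimal for this
cohort size, and published tables are not always consistent between the
two); and clinically relevant spasticity from a means-only table uses
`MAS mean > 1 or SCAT mean > 1`, falling back from the any-joint rule; with
joint scores present the joint rule is applied. On the packaged reference
table the means-only rule reconstructs the printed 2/8 vs 6/7 contingency
exactly. Recomputing the MAS eta on that table gives 0.62 against a
published 0.59 -- the package reports what the table yields.

## Calibration and problem sizes

The type-I calibration simulates each test under its null and checks
rejection at alpha = 0.05 within +/-0.02 over 1000 replicates. The
calibration designs are chosen so the nominal level is *attainable*:
continuous data with n = 30 per group for the rank tests and eta, and 2x60
Bernoulli(0.5) tables for Fisher. Exact conditional tests are structurally
conservative on small discrete tables -- at n = 15 the attainable size of
Fisher's test is only ~0.01--0.03, a property of the test, not of an
implementation -- so calibrating it at cohort n would test discreteness, not
correctness.

Test-suite problem sizes: detector operating characteristics use 1000
noise-only trials and 400 planted bursts spanning 4--12 background SDs;
conduction-velocity recovery uses 20 seeded SCI cohorts of 15 participants
at two sites with 60 trials each (zero-jitter exactness is checked
separately at a fixed 0.5 m inter-site distance, where 1 ms latency
quantization stays below the three-significant-digit target); the group
contrast uses 20 replicates of the full 15 + 12 cohort at three sites and
60 stimuli. With the compiled filter core a full cohort runs in roughly
half a minute.

## Known limitations

* Burst offsets (and hence AUC) are inflated by up to ~150 ms of bridged
  noise crossings after the true burst end; onsets, rates and latencies --
  the comparison quantities -- are unaffected.
* Sensitivity near the 4-SD amplitude floor is graded, not a step: a burst
  whose level is within half a noise SD of the threshold cannot reliably
  satisfy 10 ms of persistence. Rare extreme-amplitude bursts (lognormal
  upper tail) can still leak enough sub-band energy to shift an onset
  early; medians and 2-SEM mean checks absorb both effects.
* Early-window conduction velocities are resolution-limited (see above);
  the package reports them but flags that the late window is the reliable
  one at this geometry.
* The BrainVision adapter is out of scope in this build; the TSV epoch
  format is the interchange surface.
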