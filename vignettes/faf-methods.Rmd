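---
title: "Measuring vocal pitch compensation and auditory ERPs under frequency-altered feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal pitch compensation and auditory ERPs under frequency-altered feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fafpipe)
```

## The paradigm and what the package computes

In a frequency-altered feedback (FAF) experiment a speaker sustains a vowel
while hearing their own voice through earphones; at an unpredictable moment
the feedback is pitch-shifted downward by a fixed amount (here -50 or -200
cents, 100 cents = 1 semitone) for 200 ms. Most speakers produce a rapid
*compensatory* response — a transient rise of voice fundamental frequency
(F0) opposing the shift — and the perturbation evokes a cortical N1-P2
complex in the EEG. Three families of measures are computed per subject:

1. **Vocal**: the magnitude (cents) and latency (ms) of the compensatory
   response per perturbation magnitude, plus the across-trial SD of the
   baseline F0, an index of the natural variability of the voice.
2. **ERP**: N1 and P2 peak amplitude and latency at ten fronto-central
   electrodes per perturbation magnitude, after artifact rejection and
   mastoid re-referencing.
3. **Statistics**: split-plot repeated-measures ANOVAs relating these
   measures to a between-subject genotype factor (three levels: AA/AG/GG at
   a biallelic locus), Bonferroni post hocs, per-genotype Pearson
   correlations between compensation magnitude and baseline variability,
   and a Hardy-Weinberg equilibrium check of the genotype counts.

Because the raw recordings of such studies are not deposited, the package
ships a synthetic-cohort generator with known ground truth; every stage of
the measurement chain is validated against that truth.

## Vocal pipeline

F0 contours (from `estimate_f0()` or delimited files) are converted to cents
with `cents = 1200 * log2(F0 / 195.997)` (G3 reference). Epochs span
`[-200, 700)` ms around each perturbation onset — half-open, with time 0 at
the first frame at or after the onset, so at the 100 Hz frame rate every
epoch holds exactly 90 frames, 20 of them baseline. Epochs are normalized by
subtracting their baseline mean.

*Direction classification.* A trial is compensatory when the mean of its
normalized contour over a response window has the sign opposite to the
perturbation. The window defaults to `[100, 500)` ms: it starts after the
earliest plausible vocal reaction and ends before the post-offset decay
dominates. Trials with more than 20% missing frames or any excursion beyond
600 cents are discarded as contaminated (automated stand-ins for the
by-eye waterfall screening used with real recordings; both bounds are
arguments).

*Measures.* Compensatory trials are averaged pointwise; the magnitude is the
maximum of the averaged contour in `[0, 700)` ms and the latency its time
(ties resolve to the earliest sample; a maximum on the window edge is
flagged). Since no response-onset detector is imposed, the search window is
the full epoch. Baseline variability is the n-1 SD across the averaged
trials of per-trial baseline means; an alternative reading (SD of the
averaged contour's baseline samples) is available via
`baseline_variability(use =)`. The across-trial version is used because it
captures production-to-production variability of the voice, which is the
construct the correlation analyses need.

## EEG pipeline

Epochs span `[-200, 500)` ms at 1000 Hz. The 1-20 Hz band-pass is a
4th-order Butterworth magnitude response applied spectrally to
reflect-padded traces: zero phase by construction, with the standard
Butterworth rolloff (50 Hz is attenuated to under 3% in amplitude), and it
vectorises over thousands of epoch-channel traces at once. Order and band
edges are arguments.

*Artifact rule.* The rejection criterion is ±55 uV relative to an 80-ms
moving average (centred, reflect-padded; a trailing variant is available).
Two complementary readings are combined by default: a **deviation** test
(any sample departing more than 55 uV from the local moving average), which
catches fast events — muscle bursts, steps — and a **smoothed-excursion**
test (the 80-ms-smoothed trace spanning more than 55 uV peak-to-peak within
the epoch), which catches slow, smooth deflections such as eye blinks. A
150 uV blink deviates only ~4 uV from its own 80-ms moving average, so a
deviation-only rule is structurally blind to it; the combined rule flags
both artifact classes while leaving a 40 uV drift untouched. Each sub-rule
is selectable via `detect_artifact(rule =)`.

*Channel and subject rules.* A channel is bad when flagged in strictly more
than 20% of epochs; a subject is excluded when strictly more than 10
channels are bad; epochs flagged on any retained channel are dropped.
Retained epochs are re-referenced to the mastoid average (M1/M2), averaged,
and baseline-corrected. N1 is the minimum sample in 80-160 ms and P2 the
maximum in 180-280 ms (inclusive windows, earliest-sample tie-break, no
local-maximum requirement) at FC1-4, FCz, C1-4, Cz.

## Statistics

`mixed_rm_anova()` implements the univariate split-plot ANOVA through the
multivariate contrast formulation: orthonormal within-subject contrasts,
Type III (sum-to-zero) between-subject hypotheses — the conventions of
mainstream GLM software, appropriate for the unbalanced 49/63/21 genotype
groups. For every within effect the Greenhouse-Geisser epsilon is estimated
from the effect-specific error SSCP and a corrected p-value is reported
alongside the uncorrected one, rather than gating the correction on a
sphericity verdict; Mauchly's test is computed and reported for inspection.
Two-level factors have epsilon = 1 identically. Effect sizes are partial
eta-squared. The implementation is cross-checked in the test suite against
a hand-written textbook sums-of-squares oracle on balanced designs and
against `car::Anova()` on unbalanced two-within designs, to 1e-8.

Post hoc comparisons are Bonferroni-adjusted pairwise t tests on group
means with a pooled error term (the ANOVA error stratum when supplied).
The per-genotype correlations between compensation magnitude and baseline
variability pool subject-by-condition points — two points per subject, one
per perturbation magnitude — because the degrees of freedom reported with
such correlations in this literature are only consistent with that pooling.
The Hardy-Weinberg test estimates the allele frequency from the counts and
uses 1 df (one estimated parameter, biallelic locus).

## The synthetic cohort

`cohort_spec()` encodes the emulated design: 133 subjects (49 AA, 63 AG,
21 GG), 100 trials per magnitude, 200-ms downward shifts at -50/-200 cents
delivered 1500-2000 ms into 3-s vocalizations; F0 contours at 100 Hz and
64-channel EEG at 1000 Hz.

Subject-level parameters (`effect_params()` defaults, chosen once):

* Compensatory gain: mean 25 cents (-50) and 27 cents (-200) — the two
  conditions barely differ, as group-level FAF magnitudes typically do not —
  with 10 cents between-subject SD, truncated at +2 cents (compensation
  opposes the shift, and individual differences in this paradigm are large).
  The GG group's mean at -200 cents is reduced by 0.8 SD. A subject's gains
  correlate 0.7 across conditions: compensation behaves like a stable trait.
* Baseline F0 jitter: stationary AR(1) on the cent scale, coefficient 0.55
  at 100 Hz (decorrelation in a few frames, consistent with contours
  dominated by frame-level tracking noise), subject scale ~ N(8, 3) cents
  truncated at 2. The latent correlation between a subject's jitter scale
  and gain is 0.53 / 0.26 / 0.10 for AA / AG / GG.
* Vocal response shape: a smooth gamma-like bump, zero until 150 ms after
  the perturbation, peaking at exactly the gain at the subject's peak
  latency (~N(350, 40) ms, truncated to 250-550), decaying smoothly after.
  15% of trials are generated as "following" (bump sign with the shift,
  scaled 0.6); with the default noise this yields ~81-85% of trials
  retained as compensatory, matching the retention typical of real FAF
  sessions.
* ERP: N1 and P2 are raised-cosine components centred at 120 and 230 ms
  whose supports coincide with the 80-160 / 180-280 ms measurement windows,
  scaled by a fronto-central topography (exactly 1 at FCz, frontal row >
  central row, 0 at the mastoids), in 1/f background noise of 8 uV RMS per
  channel. N1 means are -5 / -7 uV (-50 / -200), genotype-independent; P2
  means are 6 / 8 uV with a 0.8 SD GG boost at -200. Blink artifacts
  (150 uV half-sine, 300 ms) hit the seven far-frontal channels in 15% of
  epochs — enough to exercise the QC rules without tripping the 10-channel
  exclusion for default cohorts.

A design note on calibration: classifying trials by the sign of the
baseline-normalized mean preferentially keeps trials whose baseline noise
is low, which inflates measured magnitudes in proportion to each subject's
realized baseline spread and therefore induces a positive
variability-magnitude correlation in *every* genotype, over and above the
latent one. The default gains are large enough relative to the trial noise
that the classifier operates near saturation, keeping this induced
component modest; it cannot be removed entirely, so measured correlations
sit above their latent targets (GG in particular), while the genotype
*ordering* — the scientifically meaningful contrast — is preserved. This is
a property any direction-classified FAF analysis shares, and the main
respect in which passing tests here should not be over-read as a statement
about real data.

What the generator does **not** emulate: acoustic feedback-loop latency and
masking, non-stationary drift and microprosody in F0, spatially correlated
EEG noise, volume-conduction-accurate topographies, ocular channels, or
genotyping error.

## Numerical and reproducibility choices

All randomness flows from a single integer seed; per-subject substreams are
derived arithmetically (kept below 2^31), so the streaming driver
`run_faf_study()` — which holds one subject in memory at a time — is
bit-reproducible and identical to the materialized `simulate_cohort()` path
(tested). Noise-free configurations recover generator truth exactly:
vocal magnitudes to machine precision, latencies to one frame, ERP
amplitudes exactly at the unit-weight electrode. Ties in every peak search
resolve to the earliest sample. Degenerate inputs (empty baselines, zero
variance, missing cells, missing electrodes or mastoids) raise errors
naming the offending entity rather than propagating NA.

Problem sizes used by the validation suite: the type-I calibration uses
2000 null cohorts of 12 subjects per genotype with 20 trials per condition;
the power and correlation checks use 200 full-sized cohorts (133 subjects,
100 trials per condition); both finish in minutes on a single CPU, and the
acceptance script reports the same quantities recomputed from scratch.

## Known limitations

* The measured variability-compensation correlations include the induced
  selection component discussed above.
* ERP component amplitudes are measured as extreme samples, so they carry a
  small positive noise bias that shrinks with the number of retained
  epochs; noise-free recovery is exact.
* The band-pass filter's spectral realisation assumes reflect-padding
  represents the signal beyond the epoch; for epochs much shorter than one
  high-pass period this is approximate (as is any short-epoch filter).
* EDF input is not supported; EEG interchange uses the float32 + JSON
  fixture format (`write_eeg_epochs()`), and WAV input is limited to mono
  PCM16.
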