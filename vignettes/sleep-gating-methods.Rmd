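---
title: "Methods: simulating and measuring sound-evoked disruption of sleep oscillations"
author: "sleepgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring sound-evoked disruption of sleep oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

A sleeping animal must balance rest against danger detection: acoustic
input is filtered ("gated") according to its behavioural relevance. One
experimental window onto this process is to present sounds of different
meaning — a neutral tone heard before conditioning (pre-control), a sound
previously paired with an aversive outcome (conditioned), and a novel
neutral sound introduced alongside conditioning (post-control) — to
sleeping mice while recording parietal EEG and neck EMG, and to quantify
how each sound perturbs the state-dependent oscillations: delta power
(0–4 Hz) during NREM sleep and theta power (6–10 Hz) during REM sleep.

`sleepgate` implements this entire measurement chain as reusable,
testable code: stimulus synthesis and scheduling, a ground-truthed
synthetic EEG/EMG generator with sound-evoked power suppression, spectral
sleep scoring, sound-locked normalized band-power extraction with
two-stage aggregation, and the block-wise mixed-model and behavioural
statistics. Because no public recording accession exists for this
paradigm, the synthetic generator is the canonical input source: it is
first-class, tested code, and every downstream module is validated
against its known ground truth. Real recordings can enter the same
pipeline through the EDF reader plus hypnogram/trigger CSVs.

## Stimuli

Three sound families are synthesized at 200 kHz:

* **Pure tones** (`makePureTone()`), the pre-control sound of the
  frequency-modulated experiment; a fixed frequency between the two sweep
  ranges (typically 10–24 kHz).
* **Logarithmic chirps** (`makeChirp()`), the conditioned and
  post-control sounds: `f(t) = f0 * 2^(±rate·t)` with a default span of
  two octaves at 50 octaves/s (40 ms). The post-control sound is the
  downward mirror image. The sweep is specified "at least two octaves";
  the span is configurable and defaults to exactly two.
* **Tone clouds** (`makeSoundCloud()`), used in the generalization
  experiment: six pure-tone segments drawn from a frequency window that is
  partitioned into three contiguous equal-width (linear-Hz) subranges, two
  tones per subrange. The published ordering rule ("within each half, no
  tone is in the same frequency range as the one previously") is
  ambiguous; we enforce the strictest consistent reading — each half of
  the six-tone sequence contains one tone per subrange, and no two
  consecutive tones share a subrange, including across the half boundary.
  Four of the six orderings of the second half are always admissible, so
  bounded rejection sampling terminates. The five published cloud windows
  are available via `cloudWindows()`.

Every presentation follows a fixed intensity ramp
(`buildIntensityRamp()`, `rampSchedule()`): three zero-amplitude pulses
(speaker-artefact control) in a leading one-second block, then eight
one-second blocks of three pulses each — 24 sound pulses over eight
seconds — stepping from 24.6 to 73.5 dB SPL. Published sources give the
endpoints and "eight steps" but not the spacing or within-block timing,
so we use equal *decibel* spacing (the field convention for intensity
series) and left-aligned 0.25-s pulses on a 1/3-s grid (~83-ms gaps).
Each pulse and tone segment carries 5-ms raised-cosine ramps to avoid
spectral splatter. Levels map to linear gain through
`dbToAmplitude()`, calibrated so the loudest level reaches digital full
scale.

The zero-amplitude block sits immediately before the first sound pulse,
so the analysis timeline (8 s pre / 8 s during / 8 s post) is anchored at
the first non-zero pulse; the zero block falls inside the pre-sound
baseline, which is exactly where a silent speaker control belongs.

## The synthetic EEG/EMG generator

`simulateSession()` renders a vigilance-state bout plan (a `Hypnogram`)
into a two-channel recording in microvolts. Within each bout the EEG is

> state-band oscillation × slow log-normal amplitude envelope
> &nbsp;&nbsp;+ broadband 1/f background,

and the EMG is white noise at a state-dependent tone. The oscillation has
a *regular* component (an amplitude-modulated sinusoid) and an
*irregular* component (band-limited Gaussian noise):

| state | regular | irregular band | osc RMS | envelope CV | background | EMG |
|------|----------|----------------|---------|-------------|------------|-----|
| NREM | 1.0 Hz (70% of power) | 2–4 Hz | 50 µV | 0.40 | 10 µV | 5 µV |
| REM  | 7.5 Hz ± 3% wander (97%) | 6–9 Hz | 22 µV | 0.15 | 4 µV | 4 µV |
| WAKE | — | 4–12 Hz | 10 µV | 0.2 | 15 µV | 30 µV |

These defaults emulate the canonical signatures: NREM as high-amplitude
irregular delta activity (a slow-oscillation component plus delta noise),
REM as low-amplitude regular theta, wakefulness as desynchronized EEG
with high muscle tone. Three numerical choices deserve explanation
because they were driven by estimator analysis rather than physiology
alone:

1. **Spectral separation of the regular and irregular components.** A
   coherent sinusoid and band-limited noise sharing frequency bins
   produce a large cross-term in the 1-s periodogram, inflating the
   per-second band-power coefficient of variation well beyond the
   chi-square value. Placing the NREM regular component at 1 Hz and the
   noise at 2–4 Hz keeps the per-second delta-power CV near 0.4, which in
   turn keeps the baseline-normalization (Jensen) bias of the pipeline
   at ~2% — small against the ±0.05 recovery tolerance the package holds
   itself to.
2. **Phase handling.** The regular component starts at a random phase per
   bout. With about one cycle per 1-s analysis window, the demeaned
   Hann-window band power of a 1-Hz component is phase-sensitive; a
   common starting phase would bias every epoch's baseline the same way.
   Slow oscillations below 2 Hz are kept phase-stable within a bout
   (no frequency wander) for the same reason; theta-range components get
   3% relative frequency wander.
3. **Envelope timescale.** The log-normal amplitude envelope uses a
   per-bout constant plus a very slow (≤ 0.005 Hz) wander. Amplitude
   drift on faster timescales would decorrelate the 8-s baseline from
   the post-sound window and masquerade as a sound effect; drift this
   slow cancels in the per-epoch normalization while still letting
   amplitude vary across bouts and sessions (the "irregularity" the
   scoring features rely on).

**Sound-evoked suppression** (`applySoundResponse()`,
`SuppressionProfile`): from the first ramp pulse whose intensity reaches
the profile threshold, the state-band oscillation amplitude relaxes
exponentially (time constant 0.4 s) toward √g, so oscillation *power*
reaches the profile gain g; after sound offset the gain returns linearly
to 1 over the recovery duration (default 6 s, inside the reported 4–8-s
range). Suppression acts on the oscillation component only — broadband
background and EMG are untouched, matching the observation that the
perturbation is a change in ongoing oscillations, not an awakening. A
brief EMG twitch can accompany suppression onset without any state
change.

Learner default gains are calibrated to the reported effect sizes:
conditioned NREM 0.35 and REM 0.60, engaging at 30 dB SPL; post-control
NREM 0.45 with a later (38 dB) onset and no REM effect; pre-control 0.90
with a 65-dB threshold so only the loudest ramp steps produce a small
late drop. Non-learners use gains of 0.95 everywhere ("no clear
effect"). `nullProfiles()` sets every gain to exactly 1 for calibration
work.

## Scoring

`computeFeatures()` computes, in non-overlapping 4-s windows at the
1000-Hz analysis rate: the **theta/delta power ratio** (6–10 Hz over
0–4 Hz), the **peak-to-peak SD** (population SD of absolute
local-extremum amplitudes; plateaus of equal samples count once, at their
centre), and **EMG power**. Band power is the Hann-tapered periodogram of
the demeaned window — one FFT per window, no overlap — integrated over a
half-open band `[lo, hi)`, so disjoint bands add exactly and a partition
of `[0, fs/2)` recovers the time-domain variance (Parseval). The 4–6-Hz
gap belongs to neither band. The SD convention is population (divide by
N); the sources are silent on this and a fixed convention keeps results
reproducible.

`classifyEpochs()` applies the rule: WAKE when EMG power exceeds its cut,
otherwise REM when the ratio exceeds 1, otherwise NREM; missing features
give UNKNOWN, and an optional 3-window majority smoothing removes
isolated flips. The original study scored sleep manually and used the 2-D
feature space to validate that scoring; the explicit classifier here
replaces the human in the loop, and the separability requirement (the
NREM and REM clusters overlap by < 5% in each 1-D projection at the
published validation-set scale of 246 + 228 8-s snippets) is enforced in
the test suite.

## The power pipeline

`extractEpochPower()` computes 24 consecutive 1-s band powers aligned to
sound onset — 8 pre (block 1), 8 during (block 2), 8 post (block 3) — in
the state-appropriate band (delta for NREM onsets, theta for REM), then
divides by the mean of the 8 pre-onset values, so the block-1 normalized
mean is exactly 1 for every epoch. Epochs with zero or near-zero
baselines are flagged and excluded rather than clamped. Windows are
onset-locked, not clock-aligned. `processPresentation()` runs scoring
first and rejects presentations whose onset does not fall in scored
sleep.

`aggregateEpochs()` averages in two stages — over all recordings of each
animal, then unweighted over animals — so animals with unequal session
counts carry equal weight. `downsampleRecording()` brings
acquisition-rate data (30/32 kHz) to the 1000-Hz analysis rate with a
zero-phase 512-tap FIR low-pass at 0.4 × the target rate before
decimation.

## Statistics

`fitBlockLMM()` fits, per block, a REML linear mixed model on the long
table (one row per epoch-second): fixed effects as requested (defaults:
sound type, time as a continuous 1–8-s covariate, and their interaction),
random intercepts for animal and for session nested in animal (each
session is one sound presentation). F tests use Satterthwaite denominator
degrees of freedom — the common default where no method is named —
and coefficients are reported as estimated effect sizes. A likelihood-
ratio test against the fixed-effects-only linear model (ML refits)
reports the contribution of the random effects with degrees of freedom
equal to the number of variance parameters actually removed (2 for the
default structure), rather than any hard-coded value. Singular fits are
flagged, not hidden. Significance conventions follow 0.05/0.01/0.001 with
no correction across blocks.

Behavioural analyses: `classifyLearner()` applies the exact rule —
learner iff day-2 avoidance strictly exceeds 80% *and* at least 15
conditioning trials accumulated — and is monotone in both inputs.
`avoidanceBySound()` computes per-animal, per-sound avoidance
percentages, with early/late phases defined as the first/last two days of
a sound's exposure. `fitSigmoid()` fits a 4-parameter logistic
(floor, ceiling, midpoint, slope) by Levenberg–Marquardt least squares; a
small ladder of starting values guards against singular gradients on
step-like data, and non-convergence is reported with residuals.
`anovaTukey()` is a one-way ANOVA across sounds followed by Tukey–Kramer
pairwise comparisons (the studentized-range procedure with the unequal-n
generalization, as implemented by `TukeyHSD`).

## Calibration experiments and problem sizes

The test suite validates the chain end to end, at sizes chosen to match
the published design while staying cheap enough to run routinely:

* **Gain recovery.** 50 scored epochs per condition (5 synthetic animals
  × 10 presentations) recover the conditioned-sound gains — mean
  normalized during-sound plateau within ±0.05 of 0.35 (NREM delta) and
  0.60 (REM theta). The plateau is defined as during-sound seconds 4–8,
  after the 30-dB threshold crossing (second 2 of the ramp) and the
  0.4-s onset time constant. A property test repeats this for gains
  0.2, 0.6 and 1.0.
* **Null control.** 200 replicates of a 6-animal × 21-presentation NREM
  design with all gains at 1: grand-mean normalized power in blocks 2–3
  stays within 0.05 of 1, and the block-2 sound×time interaction is
  significant at the nominal 5% rate (within [2.5%, 7.5%]). Presentation
  order is randomized within session, as in the original protocol —
  with blocked (non-randomized) order, slow envelope drift aliases into
  spurious sound×time interactions, a useful cautionary replica of a
  real design hazard. These replicates run at a reduced 200-Hz sampling
  rate, which leaves the 0–10-Hz analysis bands and their per-window
  statistics unchanged while keeping 200 mixed-model replicates
  affordable.
* **Separability.** 246 NREM and 228 REM 8-s snippets (the published
  validation-set scale) yield feature clusters whose best
  single-threshold misclassification is below 5% on each feature, and
  ≥ 95% window-level classifier agreement with ground truth.

`scripts/acceptance.R` recomputes the headline numbers from scratch for
any seed: the chirp sweep rate recovered from the analytic signal, the
maximum tone frequency across 10,000 pre-control clouds, and the NREM/REM
conditioned-sound plateaus as percentages of baseline.

## What the generator does and does not emulate

It reproduces the spectral state signatures, their amplitude statistics
at the scoring-feature level, state-dependent muscle tone, the fixed
intensity-ramp presentation scheme, and multiplicative, sound- and
state-specific oscillation-power suppression with realistic onset and
recovery dynamics. It does **not** emulate: spindles, slow-wave/REM
micro-structure or state transitions' gradual character; electrode or
movement artefacts; circadian or homeostatic drift across a session;
volume conduction or channel cross-talk; or any biophysical mechanism of
the suppression itself. Passing tests therefore demonstrate that the
*measurement chain* is correct and calibrated — not that real mouse EEG
satisfies the generator's assumptions. On real data the classifier
thresholds (EMG cut in particular) are per-animal calibration constants,
and the residual ~2% upward bias of ratio-normalized power (a small-
sample property of dividing by an 8-s baseline estimate) applies to real
recordings exactly as it does to synthetic ones.

## Degenerate inputs and numerical conventions

Tones at or above Nyquist, chirps leaving [20 Hz, Nyquist], pulses longer
than the 0.25-s slot, epochs extending past the recording, WAKE/UNKNOWN
onsets, unknown sound types and empty bout plans are all rejected with
explicit errors. Zero baselines flag the epoch rather than producing
infinities. Band edges are half-open; plateau extrema count once; the
population-SD convention is fixed; file round-trips are bounded by 16-bit
quantization (EDF physical ranges are rounded up to the header's
3-decimal precision so writer and reader scaling agree exactly). All
randomness flows from explicit seeds; `childSeed()` derives per-branch
seeds deterministically, and `withSeed()` never perturbs the caller's
RNG stream.

## Known limitations

* The EDF writer/reader covers the continuous 16-bit subset used here
  (uniform record layout, one annotations channel); it is not a general
  EDF+ implementation.
* The intercepts-only mixed model is mildly anticonservative on block-1
  data because per-epoch normalization induces negative within-epoch
  residual correlation there; block-1 "no effect" claims are therefore
  best read from the normalization identity itself.
* The suppression model is phenomenological (gain, threshold, latency,
  recovery); it cannot distinguish mechanistic hypotheses about arousal
  circuitry, and day-course effects enter only through per-day profile
  choices, not an endogenous habituation process.
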