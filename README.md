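# sleepgate

Sound-evoked disruption of sleep oscillations: simulation, scoring and
statistics.

## The scientific problem

Sleeping animals keep filtering sound by its behavioural relevance
("sensory gating"). A direct way to measure this is to present sounds of
different meaning to sleeping mice — a neutral **pre-control** tone heard
before any training, a **conditioned** sound previously paired with an
aversive outcome, and a novel neutral **post-control** sound — while
recording parietal EEG and neck EMG, and to quantify how each sound
perturbs the state-dependent oscillations: delta power (0–4 Hz) in NREM
sleep, theta power (6–10 Hz) in REM sleep.

`sleepgate` implements that measurement chain end to end for researchers
in sleep electrophysiology and auditory neuroscience:

* **Stimuli** — pure tones, logarithmic FM chirps
  (`f(t) = f0·2^(±rt)`, default two octaves at r = 50 oct/s), pseudo-random
  tone clouds (six tones, two per subrange, no consecutive repeats), and
  the fixed presentation ramp: 3 zero-amplitude pulses, then 24 pulses in
  8 blocks stepping 24.6 → 73.5 dB SPL in equal dB steps.
* **Synthetic electrophysiology** — ground-truthed EEG/EMG sessions with
  state-dependent oscillations and multiplicative, sound- and
  state-specific suppression of oscillation power: the learner defaults
  drop conditioned-sound NREM delta power to g = 0.35 of baseline and REM
  theta power to g = 0.60, recovering within 4–8 s of sound offset.
* **Scoring** — theta/delta power ratio, peak-to-peak variability and EMG
  power in 4-s windows, plus a rule-based NREM/REM/WAKE classifier.
* **Power pipeline** — sound-locked per-second band power over 24 s
  (8 s pre / during / post), normalized per epoch by the 8-s baseline
  mean, aggregated recording → animal → group (animals weighted equally).
* **Statistics** — block-wise linear mixed models
  (`power ~ sound * time + (1|animal) + (1|animal:session)`, Satterthwaite
  F tests, likelihood-ratio test for the random effects), the learner
  criterion (> 80% day-2 avoidance and ≥ 15 trials), Audiobox avoidance
  rates, 4-parameter logistic generalization fits, and one-way ANOVA with
  Tukey–Kramer post-hoc comparisons.

Recordings are exchanged as EDF (+ hypnogram/schedule CSVs); stimuli as
WAV; everything is reachable from R or from the thin `sleepgate` command
line (subcommands `stimgen`, `simulate`, `score`, `analyze`, `behavior`,
`report`).

## Worked example

```r
library(sleepgate)

## one conditioned-sound presentation during NREM sleep
sim <- simulatePresentationEpoch("NREM", "conditioned",
                                 profile = defaultProfiles("learner"),
                                 seed = 11)
sim$rec
#> EEGRecording: 25.0 s at 1000 Hz, channels: eeg_parietal, emg; 1 trigger(s)

## score it, then extract the sound-locked normalized delta power
ep <- processPresentation(sim$rec, sim$onsetS, soundType = "conditioned")
ep
#> EpochPower [NREM/delta, conditioned] animal a1 session s1 day 1
#>   normalized blocks: 1.000 / 0.423 / 0.910
```

Block 1 (pre-sound) is exactly 1 by construction; during the sound
(block 2) delta power collapses toward the configured gain of 0.35; after
offset (block 3) it recovers. A small cohort through the full
simulate → score → extract → normalize → aggregate path:

```r
cohort <- simulateEpochCohort(nAnimals = 3, sessionsPerSound = 4,
                              soundTypes = c("conditioned", "pre_control"),
                              states = "NREM", seed = 5)
agg <- aggregateEpochs(cohort$epochs)
subset(agg, time_s %in% c(8, 12, 16, 20))
#>     sound_type phase time_s mean_normalized n_animals
#> 15 conditioned  NREM      8       0.9647121         3
#> 23 conditioned  NREM     12       0.4312852         3
#> 31 conditioned  NREM     16       0.3873047         3
#> 39 conditioned  NREM     20       0.6748742         3
#> 16 pre_control  NREM      8       0.9717377         3
#> 24 pre_control  NREM     12       0.8577209         3
#> 32 pre_control  NREM     16       0.8494145         3
#> 40 pre_control  NREM     20       0.9456899         3
```

`time_s` counts seconds from the start of the 24-s epoch (the sound plays
over seconds 9–16). The conditioned sound drives the group-mean
normalized delta power to ≈ 0.39 by the end of the ramp while the
pre-control sound shows only a small late dip tied to the loudest
intensities, and both recover afterwards. The block-2 mixed model picks
this up as a sound×time interaction:

```r
fitBlockLMM(cohort$table, block = 2)
#> Block-2 linear mixed model (n = 192 rows) [singular fit]
#> Type III Analysis of Variance Table with Satterthwaite's method
#>                 Sum Sq Mean Sq NumDF  DenDF F value    Pr(>F)
#> sound_type      0.1273  0.1273     1 109.65   1.673    0.1986
#> time            1.2887  1.2887     1 166.00  16.936 6.076e-05 ***
#> sound_type:time 1.2944  1.2944     1 166.00  17.011 5.862e-05 ***
#> LRT vs fixed-effects-only: chi2(2) = 8.67, p = 0.0131
```

(The singular-fit note is expected here: per-epoch baseline normalization
removes most animal-level variance, so the animal intercept variance is
estimated at the boundary. It is reported, never hidden.)

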