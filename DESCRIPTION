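Package: sleepgate
Title: Sound-Evoked Disruption of Sleep Oscillations: Simulation, Scoring and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how sounds of different behavioural relevance gate
    into the sleeping rodent brain. The package synthesizes the auditory
    stimuli used in sleep-presentation experiments (pure tones, logarithmic
    frequency-modulated chirps, pseudo-random tone clouds, and a fixed
    intensity-ramp presentation scheme), simulates ground-truthed parietal
    EEG/EMG sessions with state-dependent oscillations and sound-evoked,
    sound-type- and sleep-state-dependent power suppression, scores vigilance
    states from spectral features (theta/delta power ratio, peak-to-peak
    variability, EMG power), extracts sound-locked per-second baseline-
    normalized band-power time courses, and runs the block-wise linear
    mixed-model and behavioural analyses (learner classification, avoidance
    rates, sigmoid generalization fits, ANOVA with Tukey-Kramer post-hoc
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    lme4,
    lmerTest,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
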