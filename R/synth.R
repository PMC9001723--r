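## Ground-truthed synthetic EEG/EMG: state-dependent oscillations plus
## sound-evoked, sound-type- and state-dependent power suppression.

## Band-limited unit-RMS Gaussian noise via FFT masking. Lengths are
## padded to highly composite sizes so the FFT stays fast.
bandNoise <- function(n, fs, fLo, fHi) {
  np <- stats::nextn(n, c(2L, 3L, 5L))
  x <- stats::rnorm(np)
  X <- stats::fft(x)
  f <- (seq_len(np) - 1L) * fs / np
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X[f < fLo | f > fHi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / np
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s
}

## Slow standardized process for amplitude envelopes / frequency wander:
## a per-segment constant plus a very-low-frequency wander (cutoff in Hz).
## The envelope cutoff is far below the 24-s epoch timescale so that
## within-epoch amplitude drift stays negligible against the baseline
## normalization (drift between the baseline and post-sound windows would
## otherwise bias the normalized power).
slowProcess <- function(n, fs, cutoff = 0.005, constShare = 0.7) {
  z0 <- stats::rnorm(1L)
  f1 <- fs / n
  if (cutoff <= f1) return(rep(z0, n))       # too short for any wander bin
  w <- bandNoise(n, fs, f1 / 2, cutoff)
  sqrt(constShare) * z0 + sqrt(1 - constShare) * w
}

## Broadband 1/f background noise, unit RMS (flat below fKnee).
pinkNoise <- function(n, fs, fKnee = 1) {
  np <- stats::nextn(n, c(2L, 3L, 5L))
  x <- stats::rnorm(np)
  X <- stats::fft(x)
  f <- (seq_len(np) - 1L) * fs / np
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, fKnee))
  shape[1L] <- 0                             # no DC
  y <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n)] / np
  y / stats::sd(y)
}

#' Default signal-generation parameters per vigilance state
#'
#' The defaults emulate the canonical spectral signatures of rodent sleep:
#' NREM as high-amplitude irregular delta activity (a 1-Hz regular slow
#' oscillation carrying 70% of the oscillation power plus band-limited
#' 2-4 Hz delta noise, under a slow log-normal envelope with CV 0.4), REM
#' as low-amplitude regular theta (a frequency-wandering 7.5-Hz sinusoid
#' with a small irregular component, envelope CV 0.15), and wakefulness as
#' low-amplitude desynchronized activity with high muscle tone. The
#' regular and irregular components occupy separate frequency bins so that
#' the per-second band-power estimator keeps a moderate coefficient of
#' variation (about 0.4 in NREM, 0.3 in REM).
#'
#' @return Named list of [StateParams-class] for WAKE, NREM, REM.
#' @export
defaultStateParams <- function() {
  list(
    WAKE = methods::new("StateParams", state = "WAKE", bandCenterHz = 8,
                        bandWidthHz = 8, oscAmplitudeUv = 10,
                        regularFraction = 0, regularFreqHz = 8,
                        amplitudeIrregularity = 0.2, broadbandNoiseUv = 15,
                        emgToneUv = 30),
    NREM = methods::new("StateParams", state = "NREM", bandCenterHz = 3,
                        bandWidthHz = 2, oscAmplitudeUv = 50,
                        regularFraction = 0.7, regularFreqHz = 1,
                        amplitudeIrregularity = 0.4, broadbandNoiseUv = 10,
                        emgToneUv = 5),
    REM = methods::new("StateParams", state = "REM", bandCenterHz = 7.5,
                       bandWidthHz = 3, oscAmplitudeUv = 22,
                       regularFraction = 0.97, regularFreqHz = 7.5,
                       amplitudeIrregularity = 0.15, broadbandNoiseUv = 4,
                       emgToneUv = 4)
  )
}

## Cross-state invariants of a StateParams set.
validateStateParamsSet <- function(params) {
  stopifnot(all(c("WAKE", "NREM", "REM") %in% names(params)))
  if (params$NREM@amplitudeIrregularity <= params$REM@amplitudeIrregularity)
    stop("NREM amplitude irregularity must exceed REM's")
  if (params$WAKE@emgToneUv <= max(params$NREM@emgToneUv, params$REM@emgToneUv))
    stop("WAKE EMG tone must exceed sleep EMG tone")
  invisible(TRUE)
}

## One bout of state-dependent EEG components + EMG.
simulateBout <- function(state, nSamples, fs, sp) {
  env <- exp(sqrt(log(1 + sp@amplitudeIrregularity^2)) *
               slowProcess(nSamples, fs) -
               log(1 + sp@amplitudeIrregularity^2) / 2)
  oscRms <- sp@oscAmplitudeUv
  regular <- numeric(nSamples)
  if (sp@regularFraction > 0) {
    ## 3% relative frequency jitter for theta-range regular components;
    ## slow oscillations (< 2 Hz) are phase-stable on the epoch timescale,
    ## where window-phase drift would otherwise leak into the 1-s
    ## band-power estimate near the demeaned DC bin
    fWander <- if (sp@regularFreqHz >= 2)
      0.03 * sp@regularFreqHz *
        slowProcess(nSamples, fs, cutoff = 0.2, constShare = 0.3)
    else numeric(nSamples)
    phase <- stats::runif(1L, 0, 2 * pi) +
      2 * pi * cumsum(rep(sp@regularFreqHz, nSamples) + fWander) / fs
    regular <- sqrt(2) * oscRms * sqrt(sp@regularFraction) * sin(phase)
  }
  irregular <- numeric(nSamples)
  if (sp@regularFraction < 1) {
    irregular <- oscRms * sqrt(1 - sp@regularFraction) *
      bandNoise(nSamples, fs, sp@bandCenterHz - sp@bandWidthHz / 2,
                sp@bandCenterHz + sp@bandWidthHz / 2)
  }
  list(osc = env * (regular + irregular),
       background = sp@broadbandNoiseUv * pinkNoise(nSamples, fs),
       emg = stats::rnorm(nSamples, sd = sp@emgToneUv))
}

#' Simulate a ground-truthed EEG/EMG session
#'
#' Generates a parietal EEG and an EMG channel following a vigilance-state
#' bout plan. Within each bout the EEG is the state-band oscillation
#' (regular + irregular components under a slow log-normal amplitude
#' envelope) plus broadband 1/f background; the EMG is white noise at the
#' state muscle tone. The generative oscillation and background components
#' are retained in the recording so that sound-evoked suppression can act
#' on the oscillation alone.
#'
#' @param boutPlan A [Hypnogram-class]: the ground-truth state sequence.
#' @param params Named list of [StateParams-class] per state
#'   (default [defaultStateParams()]).
#' @param fs Sampling rate (default 1000 Hz, the analysis rate).
#' @param seed Integer seed or `NULL`.
#' @return An [EEGRecording-class] with channels `eeg_parietal`, `emg` and
#'   components `osc`, `background`.
#' @examples
#' plan <- boutHypnogram(c(NREM = 60, REM = 60))
#' rec <- simulateSession(plan, seed = 1)
#' @export
simulateSession <- function(boutPlan, params = defaultStateParams(),
                            fs = 1000, seed = NULL) {
  stopifnot(methods::is(boutPlan, "Hypnogram"))
  e <- epochs(boutPlan)
  if (nrow(e) == 0L) stop("empty bout plan")
  validateStateParamsSet(params)
  maxBand <- max(vapply(params, function(p)
    p@bandCenterHz + p@bandWidthHz / 2, numeric(1L)))
  stopifnot(fs >= 2 * maxBand)
  withSeed(seed, {
    parts <- lapply(seq_len(nrow(e)), function(i) {
      st <- e$state[i]
      n <- round((e$end_s[i] - e$start_s[i]) * fs)
      if (st == "UNKNOWN") st <- "WAKE"
      simulateBout(st, n, fs, params[[st]])
    })
    osc <- unlist(lapply(parts, `[[`, "osc"))
    bg <- unlist(lapply(parts, `[[`, "background"))
    emg <- unlist(lapply(parts, `[[`, "emg"))
    methods::new("EEGRecording",
                 channels = cbind(eeg_parietal = osc + bg, emg = emg),
                 fs = fs,
                 components = list(osc = osc, background = bg))
  })
}

#' Build a single-run hypnogram from named bout durations
#'
#' Convenience constructor: `boutHypnogram(c(NREM = 60, REM = 60))` gives a
#' contiguous two-bout plan starting at 0.
#'
#' @param durations Named numeric vector of bout durations (s); names are
#'   states.
#' @return A [Hypnogram-class].
#' @export
boutHypnogram <- function(durations) {
  ends <- unname(cumsum(durations))
  methods::new("Hypnogram", epochs = data.frame(
    start_s = c(0, ends[-length(ends)]),
    end_s = ends,
    state = unname(names(durations)),
    row.names = NULL))
}

#' Default sound-evoked suppression profiles
#'
#' Learner defaults are calibrated to the reported effect sizes: the
#' conditioned sound suppresses NREM delta power to 35% of baseline and REM
#' theta power to 60%, engaging at low intensities (30 dB SPL); the
#' post-control sound generalizes during NREM only (gain ~0.45) with a
#' later onset (38 dB SPL); the pre-control sound produces at most a small
#' late drop tied to the loudest intensities (65 dB SPL threshold), and no
#' REM effect. Non-learners show no clear effect for any sound (gains in
#' [0.9, 1]). Recovery after sound offset spans 4-8 s (default 6 s).
#'
#' @param cohort `"learner"` or `"nonlearner"`.
#' @return A [SuppressionProfile-class].
#' @export
defaultProfiles <- function(cohort = c("learner", "nonlearner")) {
  cohort <- match.arg(cohort)
  if (cohort == "learner") {
    p <- rbind(
      data.frame(sound_type = "conditioned", state = c("NREM", "REM"),
                 gain = c(0.35, 0.60), threshold_dbspl = 30),
      data.frame(sound_type = "post_control", state = c("NREM", "REM"),
                 gain = c(0.45, 1.0), threshold_dbspl = 38),
      data.frame(sound_type = "pre_control", state = c("NREM", "REM"),
                 gain = c(0.90, 1.0), threshold_dbspl = 65))
  } else {
    p <- expand.grid(sound_type = c("conditioned", "post_control",
                                    "pre_control"),
                     state = c("NREM", "REM"), stringsAsFactors = FALSE)
    p$gain <- 0.95
    p$threshold_dbspl <- 40
  }
  p$onset_latency_s <- 0.4
  p$recovery_s <- 6
  methods::new("SuppressionProfile", profile = p)
}

#' Suppression profile with unit gains (null model)
#'
#' All gains exactly 1 for every sound and state: sounds leave the EEG
#' untouched. Used for type-I-error control of the full pipeline.
#'
#' @param soundTypes Sound labels to cover.
#' @return A [SuppressionProfile-class].
#' @export
nullProfiles <- function(soundTypes = c("conditioned", "post_control",
                                        "pre_control")) {
  p <- expand.grid(sound_type = soundTypes, state = c("NREM", "REM"),
                   stringsAsFactors = FALSE)
  p$gain <- 1
  p$threshold_dbspl <- 30
  p$onset_latency_s <- 0.4
  p$recovery_s <- 6
  methods::new("SuppressionProfile", profile = p)
}

## Amplitude-gain time course over the recording for one presentation.
suppressionGain <- function(timeS, schedule, onsetS, gain, thresholdDb,
                            latencyS, recoveryS) {
  p <- pulses(schedule)
  supra <- p[!p$is_zero & p$intensity_dbspl >= thresholdDb, , drop = FALSE]
  a <- rep(1, length(timeS))
  if (nrow(supra) == 0L || gain == 1) return(a)
  t1 <- onsetS + (min(supra$onset_s) - schedule@rampOnset)
  tOff <- onsetS + schedule@totalRampDuration
  aInf <- sqrt(gain)
  during <- timeS >= t1 & timeS < tOff
  a[during] <- aInf + (1 - aInf) * exp(-(timeS[during] - t1) / latencyS)
  aOff <- aInf + (1 - aInf) * exp(-(tOff - t1) / latencyS)
  after <- timeS >= tOff
  a[after] <- aOff + (1 - aOff) * pmin(1, (timeS[after] - tOff) / recoveryS)
  a
}

#' Apply a sound-evoked suppression to a synthetic recording
#'
#' From the first pulse whose intensity reaches the profile's threshold,
#' the state-band oscillation amplitude relaxes exponentially toward
#' `sqrt(g)` (so the oscillation *power* reaches `g`) with the profile's
#' onset time constant; after sound offset the gain returns linearly to 1
#' over the recovery duration. The broadband background is untouched. The
#' EMG can gain a brief twitch transient at suppression onset, without any
#' state change. A trigger row is appended to the recording.
#'
#' @param rec A synthetic [EEGRecording-class] (with components).
#' @param schedule A [StimulusSchedule-class].
#' @param profile A [SuppressionProfile-class].
#' @param stateAtOnset Sleep state at sound onset (`"NREM"`/`"REM"`).
#' @param onsetS Time (s) in the recording at which the ramp onset
#'   (schedule t = 0) is placed.
#' @param emgTwitch Add a small EMG twitch at suppression onset.
#' @return The modified [EEGRecording-class].
#' @export
applySoundResponse <- function(rec, schedule, profile, stateAtOnset,
                               onsetS, emgTwitch = TRUE) {
  stopifnot(methods::is(rec, "EEGRecording"),
            methods::is(schedule, "StimulusSchedule"),
            methods::is(profile, "SuppressionProfile"))
  if (!stateAtOnset %in% c("NREM", "REM"))
    stop("stateAtOnset must be NREM or REM")
  if (!all(c("osc", "background") %in% names(rec@components)) ||
      !length(rec@components$osc))
    stop("recording lacks generative components; suppression needs a synthetic recording")
  pr <- profileTable(profile)
  row <- pr[pr$sound_type == schedule@soundId & pr$state == stateAtOnset, ]
  if (nrow(row) != 1L)
    stop("no suppression profile for sound '", schedule@soundId,
         "' in state ", stateAtOnset)
  fs <- sampleRate(rec)
  n <- nrow(rec@channels)
  timeS <- (seq_len(n) - 0.5) / fs
  a <- suppressionGain(timeS, schedule, onsetS, row$gain,
                       row$threshold_dbspl, row$onset_latency_s,
                       row$recovery_s)
  osc <- rec@components$osc * a
  eeg <- osc + rec@components$background
  emg <- rec@channels[, "emg"]
  if (emgTwitch && row$gain < 1 && any(a < 1)) {
    t1 <- timeS[which(a < 1)[1L]]
    idx <- which(timeS >= t1 & timeS < t1 + 0.15)
    emg[idx] <- emg[idx] + stats::rnorm(length(idx), sd = 2 * stats::sd(emg))
  }
  rec@channels <- cbind(eeg_parietal = eeg, emg = emg)
  rec@components$osc <- osc
  rec@triggers <- rbind(rec@triggers,
                        data.frame(time_s = onsetS,
                                   sound_id = schedule@soundId))
  methods::validObject(rec)
  rec
}

#' Simulate a sleep session carrying a sequence of presentations
#'
#' One long single-state bout holding several intensity-ramp
#' presentations, spaced widely enough (26 s by default) that each
#' epoch's 8-s baseline lies beyond the previous presentation's recovery
#' window. Mirrors the experimental sessions, where several sounds were
#' presented within one sleep bout, and is considerably faster than
#' simulating each presentation as its own recording.
#'
#' @param state `"NREM"` or `"REM"`.
#' @param soundSeq Character vector: the sound type of each presentation,
#'   in order.
#' @param profile A [SuppressionProfile-class].
#' @param params State parameters.
#' @param seed Integer seed or `NULL`.
#' @param spacingS Onset-to-onset spacing (s), >= 26.
#' @param fs Sampling rate.
#' @return List with `rec` (the [EEGRecording-class]) and `onsets`
#'   (ramp-onset time of each presentation).
#' @export
simulatePresentationSession <- function(state, soundSeq,
                                        profile = defaultProfiles("learner"),
                                        params = defaultStateParams(),
                                        seed = NULL, spacingS = 26,
                                        fs = 1000) {
  stopifnot(length(soundSeq) >= 1L, spacingS >= 26)
  onsets <- 9 + (seq_along(soundSeq) - 1L) * spacingS
  total <- max(onsets) + 17
  pr <- profileTable(profile)
  withSeed(seed, {
    rec <- simulateSession(boutHypnogram(stats::setNames(total, state)),
                           params, fs = fs)
    n <- nrow(rec@channels)
    gains <- rep(1, n)
    for (i in seq_along(soundSeq)) {
      row <- pr[pr$sound_type == soundSeq[i] & pr$state == state, ]
      if (nrow(row) != 1L)
        stop("no suppression profile for sound '", soundSeq[i],
             "' in state ", state)
      if (row$gain == 1) next
      sch <- rampSchedule(soundId = soundSeq[i])
      ## gain differs from 1 only between suppression onset and the end
      ## of recovery; restrict the computation to that slice
      i0 <- max(1L, floor(onsets[i] * fs))
      i1 <- min(n, ceiling((onsets[i] + 8 + row$recovery_s) * fs))
      idx <- i0:i1
      gains[idx] <- gains[idx] *
        suppressionGain((idx - 0.5) / fs, sch, onsets[i], row$gain,
                        row$threshold_dbspl, row$onset_latency_s,
                        row$recovery_s)
    }
    osc <- rec@components$osc * gains
    rec@channels <- cbind(eeg_parietal = osc + rec@components$background,
                          emg = rec@channels[, "emg"])
    rec@components$osc <- osc
    rec@triggers <- rbind(rec@triggers,
                          data.frame(time_s = onsets, sound_id = soundSeq))
    list(rec = rec, onsets = onsets)
  })
}

#' Simulate one sound-presentation epoch
#'
#' A 25-s single-state recording with one intensity-ramp presentation whose
#' sound window spans seconds 8.5-16.5, leaving the full 8-s pre, during
#' and post analysis windows inside the recording.
#'
#' @param state `"NREM"` or `"REM"`.
#' @param soundType Sound label matching the profile (e.g. "conditioned").
#' @param profile A [SuppressionProfile-class].
#' @param params State parameters (default [defaultStateParams()]).
#' @param seed Integer seed or `NULL`.
#' @param fs Sampling rate (default 1000).
#' @return List with `rec` (the [EEGRecording-class]), `onsetS` and
#'   `truthState`.
#' @export
simulatePresentationEpoch <- function(state, soundType,
                                      profile = defaultProfiles("learner"),
                                      params = defaultStateParams(),
                                      seed = NULL, fs = 1000) {
  plan <- boutHypnogram(stats::setNames(25, state))
  onsetS <- 8.5
  withSeed(seed, {
    rec <- simulateSession(plan, params, fs = fs)
    sch <- rampSchedule(soundId = soundType)
    rec <- applySoundResponse(rec, sch, profile, state, onsetS)
    list(rec = rec, onsetS = onsetS, truthState = state)
  })
}
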