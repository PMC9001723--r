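## Stimulus synthesis: pure tones, logarithmic FM chirps, tone clouds, and
## the fixed intensity-ramp presentation scheme.

RAMP_MIN_DB <- 24.6
RAMP_MAX_DB <- 73.5
PULSE_DURATION_S <- 0.25
PULSE_SPACING_S <- 1 / 3    # 0.25 s pulse + ~0.083 s gap, left-aligned

#' Synthesize a pure tone
#'
#' The pre-control stimulus of the frequency-modulated experiment: a pure
#' tone at a fixed frequency (chosen between the conditioned and
#' post-control sweeps, typically 10-24 kHz), with 5-ms raised-cosine
#' on/off ramps and unit peak amplitude before calibration.
#'
#' @param freqHz Tone frequency in Hz; must be below the Nyquist rate.
#' @param durationS Duration in seconds.
#' @param fs Sampling rate (default 200 kHz).
#' @param rampS On/off raised-cosine ramp duration (s).
#' @return A [SoundWaveform-class].
#' @examples
#' tone <- makePureTone(10000, 0.1)
#' duration(tone)
#' @export
makePureTone <- function(freqHz, durationS, fs = 200000, rampS = 0.005) {
  stopifnot(length(freqHz) == 1L, length(durationS) == 1L, durationS > 0)
  if (!is.finite(freqHz) || freqHz <= 0)
    stop("tone frequency must be positive, got ", freqHz)
  if (freqHz >= fs / 2)
    stop("tone frequency ", freqHz, " Hz is at or above Nyquist (fs/2 = ",
         fs / 2, " Hz)")
  t <- seq(0, durationS, by = 1 / fs)[-1L]
  x <- applyCosineRamps(sin(2 * pi * freqHz * t), fs, rampS)
  methods::new("SoundWaveform", samples = x, fs = fs, kind = "pure_tone",
               freqMeta = list(freq_hz = freqHz))
}

#' Synthesize a logarithmic frequency-modulated chirp
#'
#' Conditioned and post-control stimuli: sweeps with an exponential
#' (log-linear) frequency trajectory `f(t) = startHz * 2^(+/- rate * t)`,
#' spanning `octaveSpan` octaves at `rateOctPerS` octaves/s (defaults: two
#' octaves at 50 oct/s, i.e. 40 ms). The downward chirp is the mirror image
#' of the upward one, descending from `startHz`.
#'
#' @param startHz Start frequency (Hz).
#' @param octaveSpan Octaves spanned (>= 2 by default design).
#' @param rateOctPerS Sweep rate in octaves per second.
#' @param direction `"up"` or `"down"`.
#' @param fs Sampling rate (default 200 kHz).
#' @param rampS On/off raised-cosine ramp duration (s).
#' @return A [SoundWaveform-class] with kind `"chirp_up"` or `"chirp_down"`.
#' @examples
#' up <- makeChirp(10500)       # 10.5 -> 42 kHz over 40 ms
#' duration(up)
#' @export
makeChirp <- function(startHz, octaveSpan = 2, rateOctPerS = 50,
                      direction = c("up", "down"), fs = 200000,
                      rampS = 0.005) {
  direction <- match.arg(direction)
  stopifnot(startHz > 0, octaveSpan > 0, rateOctPerS > 0)
  sgn <- if (direction == "up") 1 else -1
  endHz <- startHz * 2^(sgn * octaveSpan)
  if (max(startHz, endHz) >= fs / 2)
    stop("chirp reaches ", max(startHz, endHz),
         " Hz, at or above Nyquist (fs/2 = ", fs / 2, " Hz)")
  if (min(startHz, endHz) < 20)
    stop("chirp descends to ", min(startHz, endHz), " Hz, below 20 Hz")
  durationS <- octaveSpan / rateOctPerS
  t <- seq(0, durationS, by = 1 / fs)[-1L]
  r <- sgn * rateOctPerS
  ## phase = 2*pi * integral of startHz * 2^(r u) du
  phase <- 2 * pi * startHz * (2^(r * t) - 1) / (r * log(2))
  x <- applyCosineRamps(sin(phase), fs, rampS)
  methods::new("SoundWaveform", samples = x, fs = fs,
               kind = paste0("chirp_", direction),
               freqMeta = list(start_hz = startHz, octave_span = octaveSpan,
                               rate_oct_per_s = rateOctPerS,
                               direction = direction, end_hz = endHz))
}

#' Build a tone-cloud specification
#'
#' @param fLowHz,fHighHz Frequency window limits (Hz). The window is
#'   partitioned into three contiguous equal-width subranges.
#' @return A [CloudSpec-class].
#' @export
cloudSpec <- function(fLowHz, fHighHz) {
  methods::new("CloudSpec", fLowHz = fLowHz, fHighHz = fHighHz,
               nSubranges = 3L, tonesPerSubrange = 2L)
}

#' Frequency windows of the five experimental sound clouds
#'
#' The cloud generalization experiment ranked five clouds by frequency
#' distance from the conditioned cloud: pre-control 3000-4662 Hz,
#' post-control 1 4811-7478 Hz, post-control 2 7718-11995 Hz, and
#' post-control 3 and conditioned sharing 12379-19240 Hz (distinguished
#' only by tone order).
#'
#' @return Named list of [CloudSpec-class] objects.
#' @export
cloudWindows <- function() {
  list(pre_control    = cloudSpec(3000, 4662),
       post_control_1 = cloudSpec(4811, 7478),
       post_control_2 = cloudSpec(7718, 11995),
       post_control_3 = cloudSpec(12379, 19240),
       conditioned    = cloudSpec(12379, 19240))
}

## Contiguous equal-width subrange boundaries of a cloud window.
cloudSubranges <- function(spec) {
  edges <- seq(spec@fLowHz, spec@fHighHz, length.out = spec@nSubranges + 1L)
  data.frame(subrange = seq_len(spec@nSubranges),
             lo = edges[-length(edges)], hi = edges[-1L])
}

#' Draw the tone sequence of a sound cloud
#'
#' Samples the six tone frequencies and their order: the six-tone sequence
#' splits into two halves of three, each half containing exactly one tone
#' per subrange, and no two consecutive tones (including across the half
#' boundary) share a subrange. Each tone frequency is drawn uniformly
#' within its subrange. Rejection sampling over half-2 orderings is bounded
#' (4 of 6 permutations are always admissible, so it terminates).
#'
#' @param spec A [CloudSpec-class].
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return `data.frame` with columns `position` (1-6), `half` (1-2),
#'   `subrange` (1-3) and `freq_hz`.
#' @examples
#' drawCloudTones(cloudSpec(3000, 4662), seed = 1)
#' @export
drawCloudTones <- function(spec, seed = NULL) {
  stopifnot(methods::is(spec, "CloudSpec"))
  sub <- cloudSubranges(spec)
  withSeed(seed, {
    half1 <- sample(3L)
    half2 <- sample(3L)
    attempts <- 1L
    while (half2[1L] == half1[3L]) {
      half2 <- sample(3L)
      attempts <- attempts + 1L
      if (attempts > 1000L) stop("cloud ordering rejection sampling failed")
    }
    ord <- c(half1, half2)
    freq <- stats::runif(6L, min = sub$lo[ord], max = sub$hi[ord])
    data.frame(position = 1:6, half = rep(1:2, each = 3L),
               subrange = ord, freq_hz = freq)
  })
}

#' Synthesize a sound cloud
#'
#' Concatenates six pure-tone segments drawn by [drawCloudTones()]; the
#' total cloud duration equals one presentation pulse (0.25 s by default,
#' ~41.7 ms per tone), each segment carrying its own raised-cosine ramps.
#' Same spec and seed give identical waveforms.
#'
#' @param spec A [CloudSpec-class].
#' @param seed Integer seed, or `NULL`.
#' @param durationS Total cloud duration (s).
#' @param fs Sampling rate (default 200 kHz).
#' @param rampS Per-tone raised-cosine ramp duration (s).
#' @return A [SoundWaveform-class] with kind `"cloud"`; the tone table is
#'   available as `freqMeta(wave)$tones`.
#' @export
makeSoundCloud <- function(spec, seed = NULL, durationS = PULSE_DURATION_S,
                           fs = 200000, rampS = 0.005) {
  tones <- drawCloudTones(spec, seed)
  if (max(tones$freq_hz) >= fs / 2)
    stop("cloud tones exceed Nyquist for fs = ", fs)
  nPer <- floor(durationS * fs / 6)
  t <- seq_len(nPer) / fs
  segs <- lapply(tones$freq_hz, function(f)
    applyCosineRamps(sin(2 * pi * f * t), fs, rampS))
  methods::new("SoundWaveform", samples = unlist(segs), fs = fs,
               kind = "cloud",
               freqMeta = list(tones = tones, f_low_hz = spec@fLowHz,
                               f_high_hz = spec@fHighHz))
}

#' Frequency metadata of a waveform
#' @param object A [SoundWaveform-class].
#' @return The kind-specific metadata list.
#' @export
freqMeta <- function(object) {
  stopifnot(methods::is(object, "SoundWaveform"))
  object@freqMeta
}

#' Build the fixed intensity-ramp presentation schedule
#'
#' One presentation plays a sound in a fixed scheme: three zero-amplitude
#' pulses (speaker-artefact control) in a leading 1-s block, then eight 1-s
#' intensity blocks of three pulses each (24 sound pulses over eight
#' seconds), with intensities stepping from `minDb` to `maxDb` dB SPL in
#' `nBlocks` equal dB steps. Within a block, pulses are left-aligned on a
#' 1/3-s grid (0.25-s slots with ~83-ms gaps).
#'
#' @param wave A [SoundWaveform-class]; its duration must fit a pulse slot
#'   (<= 0.25 s).
#' @param minDb,maxDb Intensity endpoints in dB SPL (24.6 and 73.5).
#' @param nBlocks Number of intensity blocks (8).
#' @param pulsesPerBlock Pulses per block (3).
#' @param soundId Label recorded in the schedule.
#' @param render If `TRUE`, also render the full pressure waveform with
#'   each pulse scaled by [dbToAmplitude()] (calibrated so `maxDb` maps to
#'   full scale).
#' @return A list with elements `schedule` (a [StimulusSchedule-class]) and
#'   `samples` (the rendered waveform, or `NULL` when `render = FALSE`).
#' @examples
#' ramp <- buildIntensityRamp(makeChirp(10500), render = FALSE)
#' ramp$schedule
#' @export
buildIntensityRamp <- function(wave, minDb = RAMP_MIN_DB, maxDb = RAMP_MAX_DB,
                               nBlocks = 8L, pulsesPerBlock = 3L,
                               soundId = soundKind(wave), render = TRUE) {
  stopifnot(methods::is(wave, "SoundWaveform"), minDb < maxDb, nBlocks >= 1L)
  pd <- duration(wave)
  if (pd > PULSE_DURATION_S + 1e-9)
    stop(sprintf("pulse duration %.3f s exceeds the %.2f-s block slot",
                 pd, PULSE_DURATION_S))
  schedule <- rampSchedule(soundId = soundId, pulseDuration = pd,
                           minDb = minDb, maxDb = maxDb, nBlocks = nBlocks,
                           pulsesPerBlock = pulsesPerBlock)
  rendered <- NULL
  if (render) {
    fs <- sampleRate(wave)
    p <- schedule@pulses
    total <- ceiling((nBlocks + 1L) * fs)   # zero block + nBlocks blocks
    rendered <- numeric(total)
    w <- samples(wave)
    calib <- 10^(-maxDb / 20)               # loudest level -> full scale
    for (i in seq_len(nrow(p))) {
      if (p$is_zero[i]) next
      i0 <- round(p$onset_s[i] * fs)
      rendered[i0 + seq_along(w)] <-
        w * dbToAmplitude(p$intensity_dbspl[i], calib)
    }
  }
  list(schedule = schedule, samples = rendered)
}

#' Construct a presentation schedule without rendering audio
#'
#' The schedule alone (pulse onsets, durations, intensities) is what the
#' electrophysiology simulator and the power pipeline consume; rendering the
#' 200-kHz pressure waveform is only needed for stimulus export.
#'
#' @param soundId Label for the scheduled sound.
#' @param pulseDuration Duration (s) of each pulse.
#' @inheritParams buildIntensityRamp
#' @return A [StimulusSchedule-class]; its `rampOnset` (1 s, after the
#'   zero-amplitude block) is the analysis timeline's t = 0.
#' @export
rampSchedule <- function(soundId = "sound", pulseDuration = PULSE_DURATION_S,
                         minDb = RAMP_MIN_DB, maxDb = RAMP_MAX_DB,
                         nBlocks = 8L, pulsesPerBlock = 3L) {
  stopifnot(pulseDuration > 0, pulseDuration <= PULSE_DURATION_S + 1e-9)
  levels <- seq(minDb, maxDb, length.out = nBlocks)
  blockStart <- c(0, seq_len(nBlocks))            # block 0 = zero-amplitude
  onsets <- unlist(lapply(blockStart, function(b)
    b + (seq_len(pulsesPerBlock) - 1L) * PULSE_SPACING_S))
  isZero <- rep(c(TRUE, rep(FALSE, nBlocks)), each = pulsesPerBlock)
  intensity <- rep(c(-Inf, levels), each = pulsesPerBlock)
  intensity[isZero] <- 0
  pulses <- data.frame(onset_s = onsets, duration_s = pulseDuration,
                       intensity_dbspl = intensity, is_zero = isZero)
  pulses$intensity_dbspl[pulses$is_zero] <- 0
  methods::new("StimulusSchedule", pulses = pulses, soundId = soundId,
               rampOnset = 1, totalRampDuration = as.numeric(nBlocks))
}

#' Estimate the sweep rate of a chirp from its waveform
#'
#' Recovers the instantaneous frequency from the analytic signal (Hilbert
#' transform, unwrapped phase) and regresses `log2(f)` on time; for a
#' logarithmic chirp the slope is the signed sweep rate in octaves/s. The
#' raised-cosine ramp regions plus a small margin are excluded to avoid
#' Hilbert edge effects.
#'
#' @param wave A [SoundWaveform-class].
#' @param trimS Seconds trimmed from each end before the regression.
#' @return List with `rateOctPerS` (regression slope), `r2` and the trimmed
#'   instantaneous-frequency series (`t`, `freq_hz`).
#' @export
chirpSweepRate <- function(wave, trimS = 0.007) {
  stopifnot(methods::is(wave, "SoundWaveform"))
  x <- samples(wave)
  fs <- sampleRate(wave)
  ph <- unwrapPhase(Arg(analyticSignal(x)))
  instf <- diff(ph) * fs / (2 * pi)
  t <- (seq_along(instf) - 0.5) / fs
  keep <- t > trimS & t < (length(x) / fs - trimS) & instf > 0
  fit <- stats::lm(log2(instf[keep]) ~ t[keep])
  list(rateOctPerS = unname(stats::coef(fit)[2L]),
       r2 = summary(fit)$r.squared,
       t = t[keep], freq_hz = instf[keep])
}
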