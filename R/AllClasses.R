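## S4 classes for the central data objects.

VALID_STATES <- c("WAKE", "NREM", "REM", "UNKNOWN")
VALID_SOUND_KINDS <- c("pure_tone", "chirp_up", "chirp_down", "cloud")

#' SoundWaveform: a synthesized auditory stimulus
#'
#' Holds the sample vector of one stimulus in `[-1, 1]`, its sampling rate
#' (200 kHz by default, well above the ultrasonic content of the stimuli),
#' the stimulus family and family-specific frequency metadata.
#'
#' @slot samples Numeric vector of samples in `[-1, 1]`.
#' @slot fs Sampling rate in samples/s.
#' @slot kind One of `"pure_tone"`, `"chirp_up"`, `"chirp_down"`, `"cloud"`.
#' @slot freqMeta Named list of kind-specific parameters (tone frequency;
#'   chirp start frequency, octave span and sweep rate; cloud tone table).
#' @export
setClass("SoundWaveform",
  representation(samples = "numeric", fs = "numeric", kind = "character",
                 freqMeta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) < 1L) msg <- c(msg, "waveform must be non-empty")
    if (any(!is.finite(object@samples)) || max(abs(object@samples)) > 1 + 1e-9)
      msg <- c(msg, "all |samples| must be <= 1 and finite")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar")
    if (!object@kind %in% VALID_SOUND_KINDS)
      msg <- c(msg, sprintf("kind must be one of %s",
                            paste(VALID_SOUND_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' StimulusSchedule: the fixed intensity-ramp presentation scheme
#'
#' An ordered pulse table realizing one 8-s presentation: three
#' zero-amplitude speaker-control pulses followed by 24 sound pulses in
#' eight 1-s blocks of three pulses each, with intensities stepping from
#' 24.6 to 73.5 dB SPL in eight equal dB steps.
#'
#' @slot pulses `data.frame` with columns `onset_s`, `duration_s`,
#'   `intensity_dbspl`, `is_zero` (logical), ordered by onset.
#' @slot soundId Label of the scheduled sound.
#' @slot rampOnset Time (s, schedule clock) of the first non-zero pulse;
#'   the analysis timeline's t = 0.
#' @slot totalRampDuration Duration (s) of the non-zero ramp, 8 by design.
#' @export
setClass("StimulusSchedule",
  representation(pulses = "data.frame", soundId = "character",
                 rampOnset = "numeric", totalRampDuration = "numeric"),
  validity = function(object) {
    p <- object@pulses
    msg <- character()
    need <- c("onset_s", "duration_s", "intensity_dbspl", "is_zero")
    if (!all(need %in% names(p)))
      return(sprintf("pulses must have columns %s", paste(need, collapse = ", ")))
    if (is.unsorted(p$onset_s, strictly = TRUE))
      msg <- c(msg, "pulse onsets must be strictly increasing")
    nz <- p[!p$is_zero, , drop = FALSE]
    z <- p[p$is_zero, , drop = FALSE]
    if (nrow(z) && nrow(nz) && max(z$onset_s) >= min(nz$onset_s))
      msg <- c(msg, "zero-amplitude pulses must precede all non-zero pulses")
    if (nrow(nz)) {
      lev <- unique(nz$intensity_dbspl)
      if (is.unsorted(nz$intensity_dbspl))
        msg <- c(msg, "intensities must be nondecreasing across the ramp")
      if (any(table(nz$intensity_dbspl) != nrow(nz) / length(lev)))
        msg <- c(msg, "each intensity level must carry the same pulse count")
    }
    if (any(p$duration_s <= 0)) msg <- c(msg, "pulse durations must be positive")
    if (length(msg)) msg else TRUE
  })

#' CloudSpec: specification of a tone-cloud frequency window
#'
#' A cloud is a concatenation of six pure tones drawn pseudo-randomly from a
#' frequency window partitioned into three contiguous subranges, two tones
#' per subrange.
#'
#' @slot fLowHz,fHighHz Window limits in Hz.
#' @slot nSubranges Number of contiguous subranges (3).
#' @slot tonesPerSubrange Tones drawn per subrange (2).
#' @export
setClass("CloudSpec",
  representation(fLowHz = "numeric", fHighHz = "numeric",
                 nSubranges = "integer", tonesPerSubrange = "integer"),
  prototype(nSubranges = 3L, tonesPerSubrange = 2L),
  validity = function(object) {
    msg <- character()
    if (object@fLowHz <= 0 || object@fHighHz <= object@fLowHz)
      msg <- c(msg, "need 0 < fLowHz < fHighHz")
    if (object@nSubranges != 3L || object@tonesPerSubrange != 2L)
      msg <- c(msg, "cloud design uses 3 subranges with 2 tones each")
    if (length(msg)) msg else TRUE
  })

#' StateParams: signal-generation parameters for one vigilance state
#'
#' Parameters of the synthetic EEG/EMG generator for a single state. The
#' state-band oscillation is modelled as a regular (amplitude-modulated
#' sinusoid) plus an irregular (band-limited Gaussian noise) component under
#' a common slow log-normal amplitude envelope, on top of broadband 1/f
#' noise; the EMG channel is white noise at a state-dependent tone.
#'
#' @slot state `"WAKE"`, `"NREM"` or `"REM"`.
#' @slot bandCenterHz,bandWidthHz Centre/width (Hz) of the irregular
#'   oscillation band (NREM inside 0-4 Hz, REM inside 6-10 Hz).
#' @slot oscAmplitudeUv Total RMS amplitude (uV) of the state oscillation.
#' @slot regularFraction Fraction of oscillation power in the regular
#'   sinusoidal component.
#' @slot regularFreqHz Frequency (Hz) of the regular component.
#' @slot amplitudeIrregularity Coefficient of variation of the slow
#'   amplitude envelope (high in NREM, low in REM).
#' @slot broadbandNoiseUv RMS (uV) of the broadband 1/f background.
#' @slot emgToneUv RMS (uV) of the EMG channel.
#' @export
setClass("StateParams",
  representation(state = "character", bandCenterHz = "numeric",
                 bandWidthHz = "numeric", oscAmplitudeUv = "numeric",
                 regularFraction = "numeric", regularFreqHz = "numeric",
                 amplitudeIrregularity = "numeric",
                 broadbandNoiseUv = "numeric", emgToneUv = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@state %in% c("WAKE", "NREM", "REM"))
      msg <- c(msg, "state must be WAKE, NREM or REM")
    lo <- object@bandCenterHz - object@bandWidthHz / 2
    hi <- object@bandCenterHz + object@bandWidthHz / 2
    if (object@state == "NREM" && (lo < 0 || hi > 4))
      msg <- c(msg, "NREM oscillation band must lie within 0-4 Hz")
    if (object@state == "REM" && (lo < 6 || hi > 10))
      msg <- c(msg, "REM oscillation band must lie within 6-10 Hz")
    if (object@regularFraction < 0 || object@regularFraction > 1)
      msg <- c(msg, "regularFraction must be in [0, 1]")
    if (any(c(object@oscAmplitudeUv, object@broadbandNoiseUv,
              object@emgToneUv) < 0))
      msg <- c(msg, "amplitudes must be non-negative")
    if (object@amplitudeIrregularity < 0)
      msg <- c(msg, "amplitudeIrregularity must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' SuppressionProfile: sound-evoked power suppression parameters
#'
#' One row per (sound type, sleep state): the asymptotic multiplicative gain
#' `g` on state-band oscillation *power* (amplitude is scaled by `sqrt(g)`),
#' the intensity threshold above which the suppression engages, the onset
#' time constant, and the recovery duration after sound offset.
#'
#' @slot profile `data.frame` with columns `sound_type`, `state`, `gain`,
#'   `threshold_dbspl`, `onset_latency_s`, `recovery_s`.
#' @export
setClass("SuppressionProfile",
  representation(profile = "data.frame"),
  validity = function(object) {
    p <- object@profile
    need <- c("sound_type", "state", "gain", "threshold_dbspl",
              "onset_latency_s", "recovery_s")
    if (!all(need %in% names(p)))
      return(sprintf("profile needs columns %s", paste(need, collapse = ", ")))
    msg <- character()
    if (any(p$gain <= 0 | p$gain > 1)) msg <- c(msg, "gain must be in (0, 1]")
    if (any(p$onset_latency_s <= 0)) msg <- c(msg, "onset latency must be > 0")
    if (any(p$recovery_s <= 0)) msg <- c(msg, "recovery duration must be > 0")
    if (anyDuplicated(p[c("sound_type", "state")]))
      msg <- c(msg, "one row per (sound_type, state)")
    if (length(msg)) msg else TRUE
  })

#' EEGRecording: a multichannel EEG/EMG recording
#'
#' Channels (uV) as columns of a matrix sharing one sampling rate, plus the
#' sound-presentation triggers. Synthetic recordings additionally carry the
#' generative components (state-band oscillation vs. background) so that
#' sound-evoked suppression can act on the oscillation alone, and the
#' ground-truth hypnogram of the simulation plan.
#'
#' @slot channels Numeric matrix, one named column per channel
#'   (canonically `eeg_parietal` and `emg`).
#' @slot fs Sampling rate in samples/s (1000 Hz is the analysis rate;
#'   acquisition-rate recordings are downsampled first).
#' @slot triggers `data.frame` with columns `time_s`, `sound_id`.
#' @slot components List of named numeric vectors decomposing synthetic
#'   channels (e.g. `osc`, `background` for the EEG channel); empty for
#'   recordings read from disk.
#' @export
setClass("EEGRecording",
  representation(channels = "matrix", fs = "numeric", triggers = "data.frame",
                 components = "list"),
  prototype(triggers = data.frame(time_s = numeric(), sound_id = character()),
            components = list()),
  validity = function(object) {
    msg <- character()
    if (is.null(colnames(object@channels)))
      msg <- c(msg, "channels matrix must have column names")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar")
    if (!all(c("time_s", "sound_id") %in% names(object@triggers)))
      msg <- c(msg, "triggers must have columns time_s, sound_id")
    for (cmp in object@components)
      if (length(cmp) && length(cmp) != nrow(object@channels))
        msg <- c(msg, "components must match the channel length")
    if (length(msg)) msg else TRUE
  })

#' Hypnogram: per-epoch vigilance-state labels
#'
#' Ordered, non-overlapping, contiguous epochs labelled WAKE/NREM/REM/UNKNOWN.
#'
#' @slot epochs `data.frame` with columns `start_s`, `end_s`, `state`.
#' @export
setClass("Hypnogram",
  representation(epochs = "data.frame"),
  validity = function(object) {
    e <- object@epochs
    if (!all(c("start_s", "end_s", "state") %in% names(e)))
      return("epochs must have columns start_s, end_s, state")
    msg <- character()
    if (!all(e$state %in% VALID_STATES))
      msg <- c(msg, sprintf("states must be in {%s}",
                            paste(VALID_STATES, collapse = ", ")))
    if (any(e$end_s <= e$start_s)) msg <- c(msg, "epochs need end_s > start_s")
    if (nrow(e) > 1L) {
      if (is.unsorted(e$start_s, strictly = TRUE))
        msg <- c(msg, "epochs must be ordered by start time")
      else if (any(abs(e$start_s[-1L] - e$end_s[-nrow(e)]) > 1e-9))
        msg <- c(msg, "epochs must be contiguous and non-overlapping")
    }
    if (length(msg)) msg else TRUE
  })

#' EpochPower: a sound-locked 24-s band-power time course
#'
#' Twenty-four consecutive 1-s band-power values aligned to sound onset
#' (seconds 1-8 pre = block 1, 9-16 during = block 2, 17-24 post = block 3),
#' raw and baseline-normalized (divided by the mean over the 8 pre-onset
#' seconds, so the block-1 normalized mean is exactly 1).
#'
#' @slot values Raw band powers (uV^2), length 24.
#' @slot normalized Baseline-normalized powers, length 24.
#' @slot band `"delta"` (NREM readout, 0-4 Hz) or `"theta"` (REM, 6-10 Hz).
#' @slot state Sleep state at sound onset (`"NREM"`/`"REM"`).
#' @slot soundType Stimulus label (e.g. conditioned / pre_control).
#' @slot animalId,sessionId Identifiers for two-stage aggregation.
#' @slot day Experimental day (conditioning day index).
#' @slot excluded TRUE when the epoch was flagged (zero/near-zero baseline).
#' @export
setClass("EpochPower",
  representation(values = "numeric", normalized = "numeric", band = "character",
                 state = "character", soundType = "character",
                 animalId = "character", sessionId = "character",
                 day = "integer", excluded = "logical"),
  prototype(day = 1L, excluded = FALSE),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != 24L) msg <- c(msg, "values must have length 24")
    if (any(object@values < 0)) msg <- c(msg, "band powers must be >= 0")
    if (!object@band %in% c("delta", "theta"))
      msg <- c(msg, "band must be delta or theta")
    if (!object@state %in% c("NREM", "REM"))
      msg <- c(msg, "state must be NREM or REM")
    if (!object@excluded) {
      if (length(object@normalized) != 24L)
        msg <- c(msg, "normalized must have length 24")
      else if (abs(mean(object@normalized[1:8]) - 1) > 1e-8)
        msg <- c(msg, "block-1 normalized mean must equal 1")
    }
    if (length(msg)) msg else TRUE
  })
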