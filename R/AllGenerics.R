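## Generics and accessors. Slot access from user code goes through these.

#' @name sleepgate-accessors
#' @title Accessors for sleepgate S4 classes
#' @description Small accessor generics: `samples()`, `sampleRate()`,
#'   `soundKind()`, `duration()`, `pulses()`, `epochs()`, `channelNames()`,
#'   `getChannel()`, `triggers()`, `normalizedPower()`, `rawPower()`,
#'   `profileTable()`.
#' @param object An object of the documented class.
#' @param name Channel name for `getChannel()`.
#' @return The corresponding slot content (see individual methods).
NULL

#' @rdname sleepgate-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("soundKind", function(object) standardGeneric("soundKind"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("pulses", function(object) standardGeneric("pulses"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("triggers", function(object) standardGeneric("triggers"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("normalizedPower", function(object) standardGeneric("normalizedPower"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("rawPower", function(object) standardGeneric("rawPower"))
#' @rdname sleepgate-accessors
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))

#' @rdname sleepgate-accessors
#' @export
setMethod("samples", "SoundWaveform", function(object) object@samples)
#' @rdname sleepgate-accessors
#' @export
setMethod("sampleRate", "SoundWaveform", function(object) object@fs)
#' @rdname sleepgate-accessors
#' @export
setMethod("sampleRate", "EEGRecording", function(object) object@fs)
#' @rdname sleepgate-accessors
#' @export
setMethod("soundKind", "SoundWaveform", function(object) object@kind)
#' @rdname sleepgate-accessors
#' @export
setMethod("duration", "SoundWaveform",
          function(object) length(object@samples) / object@fs)
#' @rdname sleepgate-accessors
#' @export
setMethod("duration", "EEGRecording",
          function(object) nrow(object@channels) / object@fs)
#' @rdname sleepgate-accessors
#' @export
setMethod("pulses", "StimulusSchedule", function(object) object@pulses)
#' @rdname sleepgate-accessors
#' @export
setMethod("epochs", "Hypnogram", function(object) object@epochs)
#' @rdname sleepgate-accessors
#' @export
setMethod("channelNames", "EEGRecording",
          function(object) colnames(object@channels))
#' @rdname sleepgate-accessors
#' @export
setMethod("getChannel", "EEGRecording", function(object, name) {
  if (!name %in% colnames(object@channels))
    stop("no channel named '", name, "'")
  object@channels[, name]
})
#' @rdname sleepgate-accessors
#' @export
setMethod("triggers", "EEGRecording", function(object) object@triggers)
#' @rdname sleepgate-accessors
#' @export
setMethod("normalizedPower", "EpochPower", function(object) object@normalized)
#' @rdname sleepgate-accessors
#' @export
setMethod("rawPower", "EpochPower", function(object) object@values)
#' @rdname sleepgate-accessors
#' @export
setMethod("profileTable", "SuppressionProfile", function(object) object@profile)

setMethod("show", "SoundWaveform", function(object) {
  cat(sprintf("SoundWaveform [%s]: %.4f s at %g Hz, peak %.3f\n",
              object@kind, duration(object), object@fs,
              max(abs(object@samples))))
})

setMethod("show", "StimulusSchedule", function(object) {
  nz <- sum(!object@pulses$is_zero)
  cat(sprintf(
    "StimulusSchedule '%s': %d pulses (%d non-zero), %.1f-%.1f dB SPL, ramp onset %.2f s\n",
    object@soundId, nrow(object@pulses), nz,
    min(object@pulses$intensity_dbspl[!object@pulses$is_zero]),
    max(object@pulses$intensity_dbspl), object@rampOnset))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %.1f s at %g Hz, channels: %s; %d trigger(s)\n",
              duration(object), object@fs,
              paste(colnames(object@channels), collapse = ", "),
              nrow(object@triggers)))
})

setMethod("show", "Hypnogram", function(object) {
  e <- object@epochs
  tab <- tapply(e$end_s - e$start_s, e$state, sum)
  cat(sprintf("Hypnogram: %d epoch(s), %.1f s total (%s)\n", nrow(e),
              sum(e$end_s - e$start_s),
              paste(sprintf("%s %.0fs", names(tab), tab), collapse = ", ")))
})

setMethod("show", "EpochPower", function(object) {
  cat(sprintf(
    "EpochPower [%s/%s, %s] animal %s session %s day %d%s\n  normalized blocks: %.3f / %.3f / %.3f\n",
    object@state, object@band, object@soundType, object@animalId,
    object@sessionId, object@day, if (object@excluded) " (excluded)" else "",
    mean(object@normalized[1:8]), mean(object@normalized[9:16]),
    mean(object@normalized[17:24])))
})

setMethod("show", "SuppressionProfile", function(object) {
  cat("SuppressionProfile:\n")
  print(object@profile, row.names = FALSE)
})

setMethod("show", "StateParams", function(object) {
  cat(sprintf(
    "StateParams [%s]: band %.1f+/-%.1f Hz, osc %.0f uV (regular %.0f%% @ %.1f Hz), env CV %.2f, noise %.0f uV, EMG %.0f uV\n",
    object@state, object@bandCenterHz, object@bandWidthHz / 2,
    object@oscAmplitudeUv, 100 * object@regularFraction, object@regularFreqHz,
    object@amplitudeIrregularity, object@broadbandNoiseUv, object@emgToneUv))
})
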