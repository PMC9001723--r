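## Sound-locked per-second normalized band-power time courses and the
## recording -> animal -> group aggregation behind the block-wise analyses.

BASELINE_EPS <- 1e-12

#' Downsample a recording to the analysis rate
#'
#' Anti-alias low-pass filtering (zero-phase FIR, cutoff 0.4 x target rate)
#' followed by decimation; trigger times are unchanged (they are in
#' seconds). Acquisition-rate recordings (30/32 kHz) are reduced to the
#' 1000-Hz analysis rate this way.
#'
#' @param rec An [EEGRecording-class].
#' @param targetFs Target sampling rate; must divide `sampleRate(rec)`.
#' @return The downsampled [EEGRecording-class] (components are dropped).
#' @export
downsampleRecording <- function(rec, targetFs = 1000) {
  stopifnot(methods::is(rec, "EEGRecording"))
  fs <- sampleRate(rec)
  if (targetFs > fs) stop("target rate exceeds the recording rate")
  if (targetFs == fs) return(rec)
  q <- fs / targetFs
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the recording rate")
  q <- round(q)
  ntaps <- 512L
  fir <- as.numeric(signal::fir1(ntaps, 0.4 * targetFs / (fs / 2)))
  keep <- seq(1L, nrow(rec@channels), by = q)
  ch <- apply(rec@channels, 2L, function(x)
    signal::filtfilt(fir, 1, x)[keep])
  colnames(ch) <- colnames(rec@channels)
  methods::new("EEGRecording", channels = ch, fs = targetFs,
               triggers = rec@triggers, components = list())
}

#' Normalize a 24-s power time course to its baseline
#'
#' Element-wise division by the mean of the first eight values (the 8 s
#' before sound onset), so the block-1 normalized mean is exactly 1.
#' Epochs whose baseline mean is zero or near-zero cannot be normalized
#' and are flagged for exclusion rather than clamped.
#'
#' @param values Numeric vector of 24 per-second band powers.
#' @return List with `normalized` (length 24, or `NULL` when flagged) and
#'   `excluded` (logical).
#' @export
normalizeToBaseline <- function(values) {
  stopifnot(length(values) == 24L, all(values >= 0))
  b <- mean(values[1:8])
  if (!is.finite(b) || b <= BASELINE_EPS) {
    warning("zero/near-zero baseline; epoch flagged for exclusion")
    return(list(normalized = NULL, excluded = TRUE))
  }
  list(normalized = values / b, excluded = FALSE)
}

#' Extract a sound-locked band-power epoch
#'
#' Computes 24 consecutive 1-s band powers aligned to sound onset (8 pre,
#' 8 during, 8 post) from the parietal EEG, in the state-dependent readout
#' band: delta (0-4 Hz) when the sound fell into NREM sleep, theta
#' (6-10 Hz) for REM. Values are baseline-normalized per epoch.
#'
#' @param rec An [EEGRecording-class] at 1000 Hz (higher rates are
#'   downsampled first).
#' @param onsetS Sound (ramp) onset time in seconds; `[onsetS - 8,
#'   onsetS + 16]` must lie inside the recording.
#' @param state Sleep state at onset, `"NREM"` or `"REM"`.
#' @param soundType,animalId,sessionId,day Epoch metadata.
#' @return An [EpochPower-class].
#' @export
extractEpochPower <- function(rec, onsetS, state, soundType = "sound",
                              animalId = "a1", sessionId = "s1", day = 1L) {
  stopifnot(methods::is(rec, "EEGRecording"))
  if (!state %in% c("NREM", "REM"))
    stop("epochs are extracted only for NREM or REM onsets, got ", state)
  if (sampleRate(rec) > 1000) rec <- downsampleRecording(rec, 1000)
  fs <- sampleRate(rec)
  n <- nrow(rec@channels)
  if (onsetS - 8 < 0 || onsetS + 16 > n / fs)
    stop("epoch window [onset - 8 s, onset + 16 s] extends past the recording")
  band <- if (state == "NREM") "delta" else "theta"
  lims <- if (state == "NREM") DELTA_BAND else THETA_BAND
  eeg <- getChannel(rec, "eeg_parietal")
  i0 <- round((onsetS - 8) * fs)
  su <- bandpowerSetup(fs, fs, lims[1L], lims[2L])
  vals <- vapply(seq_len(24L), function(k) {
    bandpowerCore(eeg[(i0 + (k - 1L) * fs + 1L):(i0 + k * fs)], su)
  }, numeric(1L))
  norm <- normalizeToBaseline(vals)
  methods::new("EpochPower", values = vals,
               normalized = if (norm$excluded) numeric() else norm$normalized,
               band = band, state = state, soundType = soundType,
               animalId = animalId, sessionId = sessionId,
               day = as.integer(day), excluded = norm$excluded)
}

#' Long-format table of epoch powers
#'
#' One row per (epoch, second): the representation consumed by the
#' block-wise linear mixed models. Seconds 1-8 of each block are coded in
#' `time`; `block` is 1 (pre), 2 (during) or 3 (post).
#'
#' @param epochList List of [EpochPower-class] objects.
#' @param dropExcluded Drop flagged epochs (default TRUE).
#' @return `data.frame` with columns `normalized_power`, `block`, `time`,
#'   `sound_type`, `phase` (sleep state), `band`, `day`, `animal_id`,
#'   `session_id`.
#' @export
epochPowerTable <- function(epochList, dropExcluded = TRUE) {
  if (methods::is(epochList, "EpochPower")) epochList <- list(epochList)
  rows <- lapply(epochList, function(ep) {
    if (ep@excluded && dropExcluded) return(NULL)
    data.frame(normalized_power = ep@normalized,
               block = rep(1:3, each = 8L),
               time = rep(1:8, times = 3L),
               sound_type = ep@soundType, phase = ep@state, band = ep@band,
               day = ep@day, animal_id = ep@animalId,
               session_id = ep@sessionId)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(normalized_power = numeric(), block = integer(),
                      time = integer(), sound_type = character(),
                      phase = character(), band = character(),
                      day = integer(), animal_id = character(),
                      session_id = character())
  out
}

#' Two-stage aggregation of normalized power time courses
#'
#' Epochs are first averaged over all sessions of each animal and then,
#' unweighted, over animals, so animals with unequal session counts carry
#' equal weight in the grand mean. Grouping defaults to (sound type,
#' state); adding `"day"` gives day-wise means.
#'
#' @param epochList List of [EpochPower-class] objects (flagged epochs are
#'   skipped) or a long table from [epochPowerTable()].
#' @param by Grouping columns among `sound_type`, `phase`, `day`.
#' @return `data.frame` with the grouping columns, `time_s` (1-24 relative
#'   to onset - 8), `mean_normalized`, and `n_animals`.
#' @export
aggregateEpochs <- function(epochList, by = c("sound_type", "phase")) {
  tab <- if (is.data.frame(epochList)) epochList else epochPowerTable(epochList)
  if (nrow(tab) == 0L) {
    warning("no epochs to aggregate")
    return(data.frame())
  }
  tab$time_s <- (tab$block - 1L) * 8L + tab$time
  ## stage 1: per-animal mean over sessions
  f1 <- stats::aggregate(
    tab["normalized_power"],
    by = tab[c(by, "animal_id", "time_s")], FUN = mean)
  ## stage 2: unweighted mean over animals
  f2 <- stats::aggregate(f1["normalized_power"],
                         by = f1[c(by, "time_s")], FUN = mean)
  names(f2)[names(f2) == "normalized_power"] <- "mean_normalized"
  nA <- stats::aggregate(f1["animal_id"], by = f1[c(by, "time_s")],
                         FUN = function(a) length(unique(a)))
  f2$n_animals <- nA$animal_id[match(
    do.call(paste, f2[c(by, "time_s")]),
    do.call(paste, nA[c(by, "time_s")]))]
  f2[order(do.call(paste, f2[by]), f2$time_s), , drop = FALSE]
}

#' Score a presentation and extract its power epoch
#'
#' The per-presentation pipeline stage: scores the recording with the
#' spectral classifier, reads the state at sound onset from the scored
#' hypnogram, and extracts the sound-locked normalized band-power epoch.
#' Presentations scored WAKE or UNKNOWN at onset are rejected (returns
#' `NULL`).
#'
#' @param rec An [EEGRecording-class].
#' @param onsetS Sound onset time (s).
#' @param soundType,animalId,sessionId,day Epoch metadata.
#' @param thresholds Classifier thresholds ([defaultThresholds()]).
#' @return An [EpochPower-class], or `NULL` when the onset state is not
#'   sleep.
#' @export
processPresentation <- function(rec, onsetS, soundType = "sound",
                                animalId = "a1", sessionId = "s1", day = 1L,
                                thresholds = defaultThresholds()) {
  hyp <- classifyEpochs(computeFeatures(rec), thresholds)
  st <- stateAt(hyp, onsetS)
  if (!st %in% c("NREM", "REM")) return(NULL)
  extractEpochPower(rec, onsetS, st, soundType = soundType,
                    animalId = animalId, sessionId = sessionId, day = day)
}

#' Simulate a cohort of sound-presentation epochs through the full pipeline
#'
#' For each (animal, session, sound, state) cell this simulates a
#' presentation epoch, scores it, and extracts the normalized band-power
#' time course — the complete simulate -> score -> extract -> normalize
#' path. Child seeds are derived deterministically from the master seed.
#'
#' @param nAnimals Number of animals (paper-scale default 6).
#' @param sessionsPerSound Presentations per animal, sound and state
#'   (paper-scale default 7).
#' @param soundTypes Sound labels; must exist in the profile.
#' @param states Sleep states to simulate.
#' @param profile A [SuppressionProfile-class].
#' @param params State parameters.
#' @param day Day label stored in the epochs.
#' @param seed Master seed.
#' @return List with `epochs` (list of [EpochPower-class]) and `table`
#'   (the long table from [epochPowerTable()]).
#' @export
simulateEpochCohort <- function(nAnimals = 6L, sessionsPerSound = 7L,
                                soundTypes = c("conditioned", "post_control",
                                               "pre_control"),
                                states = c("NREM", "REM"),
                                profile = defaultProfiles("learner"),
                                params = defaultStateParams(),
                                day = 1L, seed = 1L) {
  eps <- list()
  sess <- 0L
  for (a in seq_len(nAnimals)) for (st in states)
    for (snd in soundTypes) for (s in seq_len(sessionsPerSound)) {
      sess <- sess + 1L
      sim <- simulatePresentationEpoch(
        st, snd, profile, params,
        seed = childSeed(seed, a, match(st, c("NREM", "REM")),
                         match(snd, soundTypes), s, day))
      ep <- processPresentation(sim$rec, sim$onsetS, soundType = snd,
                                animalId = sprintf("a%02d", a),
                                sessionId = sprintf("s%05d", sess),
                                day = day)
      if (!is.null(ep)) eps[[length(eps) + 1L]] <- ep
    }
  list(epochs = eps, table = epochPowerTable(eps))
}
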