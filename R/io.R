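## Readers/writers: hypnogram and schedule CSVs, long power tables,
## WAV stimulus export, and a minimal EDF+ recording interchange.

#' Write / read a hypnogram CSV
#'
#' Plain CSV with columns `start_s`, `end_s`, `state`. Reading validates
#' the state labels and the non-overlap/contiguity invariants (through the
#' class validity), rejecting malformed files.
#'
#' @param hyp A [Hypnogram-class].
#' @param path File path.
#' @return `writeHypnogramCSV` returns `path` invisibly; `readHypnogramCSV`
#'   returns a [Hypnogram-class].
#' @export
writeHypnogramCSV <- function(hyp, path) {
  stopifnot(methods::is(hyp, "Hypnogram"))
  utils::write.csv(epochs(hyp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHypnogramCSV
#' @export
readHypnogramCSV <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("Hypnogram", epochs = e[c("start_s", "end_s", "state")])
}

#' Write / read a stimulus schedule CSV
#'
#' Columns `onset_s`, `duration_s`, `intensity_dbspl`, `is_zero`,
#' `sound_id` (one value repeated), plus the ramp onset stored in the
#' first row's `ramp_onset_s`.
#'
#' @param schedule A [StimulusSchedule-class].
#' @param path File path.
#' @return `writeScheduleCSV` returns `path` invisibly; `readScheduleCSV`
#'   a [StimulusSchedule-class].
#' @export
writeScheduleCSV <- function(schedule, path) {
  stopifnot(methods::is(schedule, "StimulusSchedule"))
  p <- pulses(schedule)
  p$sound_id <- schedule@soundId
  p$ramp_onset_s <- schedule@rampOnset
  utils::write.csv(p, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleCSV
#' @export
readScheduleCSV <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("StimulusSchedule",
               pulses = p[c("onset_s", "duration_s", "intensity_dbspl",
                            "is_zero")],
               soundId = as.character(p$sound_id[1L]),
               rampOnset = p$ramp_onset_s[1L],
               totalRampDuration = 8)
}

#' Write / read a long power table CSV
#' @param table Long table from [epochPowerTable()].
#' @param path File path.
#' @return `writePowerTableCSV` returns `path` invisibly;
#'   `readPowerTableCSV` the `data.frame`.
#' @export
writePowerTableCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePowerTableCSV
#' @export
readPowerTableCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a stimulus waveform as WAV
#'
#' Single-channel RIFF/WAV at the waveform's sampling rate, 16-bit PCM or
#' 32-bit IEEE float. Identical waveforms produce byte-identical files.
#'
#' @param wave A [SoundWaveform-class].
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(wave, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- samples(wave)
  fs <- as.integer(sampleRate(wave))
  con <- file(path, "wb")
  on.exit(close(con))
  bytesPerSample <- if (format == "pcm16") 2L else 4L
  dataBytes <- length(x) * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * bytesPerSample, con, size = 4, endian = "little")
  writeBin(bytesPerSample, con, size = 2, endian = "little")  # block align
  writeBin(8L * bytesPerSample, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [writeWav()]
#' @param path WAV path.
#' @return List with `samples` and `fs`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fmtCode <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmtCode <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (id == "data") {
      n <- size / (bits / 8L)
      x <- if (fmtCode == 1L)
        readBin(con, "integer", n, size = 2, endian = "little") / 32767
      else readBin(con, "numeric", n, size = 4, endian = "little")
      return(list(samples = x, fs = fs))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

## ---- minimal EDF+C ----------------------------------------------------

edfPad <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF+
#'
#' Minimal continuous EDF+ writer: 1-s data records, 16-bit samples with
#' per-channel physical scaling (uV), and an `EDF Annotations` signal
#' carrying the sound triggers as time-stamped annotation lists. The
#' recording is zero-padded to a whole number of records.
#'
#' @param rec An [EEGRecording-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(methods::is(rec, "EEGRecording"))
  fs <- sampleRate(rec)
  stopifnot(abs(fs - round(fs)) < 1e-9)
  fs <- as.integer(round(fs))
  ch <- rec@channels
  nRec <- as.integer(ceiling(nrow(ch) / fs))
  if (nrow(ch) < nRec * fs)
    ch <- rbind(ch, matrix(0, nRec * fs - nrow(ch), ncol(ch),
                           dimnames = list(NULL, colnames(ch))))
  nSig <- ncol(ch)
  ## round the physical range up to the header's 3-decimal precision so
  ## the scaling written and the scaling read back agree exactly
  physMax <- vapply(seq_len(nSig), function(j)
    ceiling(max(abs(ch[, j]), 1e-3) * 1000) / 1000, numeric(1L))
  ## annotation TALs per record
  ## TALs are NUL-terminated, so they are assembled as raw vectors
  tals <- lapply(seq_len(nRec) - 1L, function(r) {
    out <- c(charToRaw(sprintf("+%d\x14\x14", r)), as.raw(0L))
    tr <- rec@triggers
    if (nrow(tr)) {
      inRec <- tr[tr$time_s >= r & tr$time_s < r + 1, , drop = FALSE]
      for (k in seq_len(nrow(inRec)))
        out <- c(out, charToRaw(sprintf("+%.3f\x14%s\x14", inRec$time_s[k],
                                        inRec$sound_id[k])), as.raw(0L))
    }
    out
  })
  annotBytes <- 2L * ceiling((max(lengths(tals)) + 2L) / 2L)
  annotBytes <- max(annotBytes, 60L)
  nAll <- nSig + 1L
  headerBytes <- 256L * (nAll + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edfPad("0", 8))
  wr(edfPad("X X X X", 80))
  wr(edfPad("Startdate X X X X", 80))
  wr(edfPad("01.01.00", 8)); wr(edfPad("00.00.00", 8))
  wr(edfPad(headerBytes, 8))
  wr(edfPad("EDF+C", 44))
  wr(edfPad(nRec, 8)); wr(edfPad("1", 8)); wr(edfPad(nAll, 4))
  labels <- c(colnames(ch), "EDF Annotations")
  for (l in labels) wr(edfPad(l, 16))
  for (i in seq_len(nAll)) wr(edfPad("", 80))                  # transducer
  wr(paste0(vapply(c(rep("uV", nSig), ""), edfPad, "", width = 8),
            collapse = ""))
  for (i in seq_len(nAll))
    wr(edfPad(if (i <= nSig) sprintf("%.3f", -physMax[i]) else "-1", 8))
  for (i in seq_len(nAll))
    wr(edfPad(if (i <= nSig) sprintf("%.3f", physMax[i]) else "1", 8))
  for (i in seq_len(nAll)) wr(edfPad("-32767", 8))
  for (i in seq_len(nAll)) wr(edfPad("32767", 8))
  for (i in seq_len(nAll)) wr(edfPad("", 80))                  # prefilter
  for (i in seq_len(nAll))
    wr(edfPad(if (i <= nSig) fs else annotBytes %/% 2L, 8))
  for (i in seq_len(nAll)) wr(edfPad("", 32))
  dig <- vapply(seq_len(nSig), function(j)
    as.integer(round(ch[, j] / physMax[j] * 32767)), integer(nRec * fs))
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(nSig))
      writeBin(dig[idx, j], con, size = 2, endian = "little")
    tal <- tals[[r]]
    writeBin(c(tal, raw(annotBytes - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF+ recording
#'
#' Parses the channels written by [writeEDF()] (and other continuous
#' 16-bit EDF files with uniform record layout), rescaling to physical
#' units and recovering triggers from the annotations signal.
#'
#' @param path EDF path.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  invisible(as.integer(rd(8)))        # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nAll <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nAll), function(i) rd(16), ""))
  for (i in seq_len(nAll)) rd(80)
  dims <- vapply(seq_len(nAll), function(i) trimws(rd(8)), "")
  physMin <- as.numeric(vapply(seq_len(nAll), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nAll), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nAll), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nAll), function(i) rd(8), ""))
  for (i in seq_len(nAll)) rd(80)
  nsamp <- as.integer(vapply(seq_len(nAll), function(i) rd(8), ""))
  for (i in seq_len(nAll)) rd(32)
  isAnnot <- labels == "EDF Annotations"
  sig <- vector("list", nAll)
  for (i in seq_len(nAll)) sig[[i]] <- vector("list", nRec)
  for (r in seq_len(nRec)) {
    for (i in seq_len(nAll)) {
      if (isAnnot[i]) {
        sig[[i]][[r]] <- readBin(con, "raw", 2L * nsamp[i])
      } else {
        sig[[i]][[r]] <- readBin(con, "integer", nsamp[i], size = 2,
                                 endian = "little")
      }
    }
  }
  dataIdx <- which(!isAnnot)
  chans <- lapply(dataIdx, function(i) {
    d <- unlist(sig[[i]])
    physMin[i] + (d - digMin[i]) * (physMax[i] - physMin[i]) /
      (digMax[i] - digMin[i])
  })
  names(chans) <- labels[dataIdx]
  fsOut <- nsamp[dataIdx[1L]] / recDur
  trig <- data.frame(time_s = numeric(), sound_id = character())
  for (i in which(isAnnot)) {
    rawAll <- unlist(sig[[i]])
    breaks <- c(0L, which(rawAll == as.raw(0L)))
    for (k in seq_len(length(breaks) - 1L)) {
      if (breaks[k + 1L] - 1L < breaks[k] + 1L) next
      seg <- rawAll[(breaks[k] + 1L):(breaks[k + 1L] - 1L)]
      parts <- strsplit(rawToChar(seg), "\x14", fixed = TRUE)[[1L]]
      if (length(parts) >= 2L && nzchar(parts[2L])) {
        t0 <- suppressWarnings(as.numeric(parts[1L]))
        if (is.finite(t0))
          trig <- rbind(trig, data.frame(time_s = t0, sound_id = parts[2L]))
      }
    }
  }
  methods::new("EEGRecording",
               channels = do.call(cbind, chans), fs = fsOut,
               triggers = trig, components = list())
}
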