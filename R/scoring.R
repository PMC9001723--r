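## Sleep-scoring features and epoch classification.
##
## The two discriminant features follow the validation analysis of the
## experimental paradigm: the theta/delta band-power ratio (6-10 Hz over
## 0-4 Hz) and the peak-to-peak variability (SD of absolute local-extremum
## amplitudes), computed in non-overlapping 4-s windows, plus EMG power to
## separate wakefulness.

DELTA_BAND <- c(0, 4)
THETA_BAND <- c(6, 10)

#' Band power of a signal segment
#'
#' Power (uV^2) in the half-open band `[fLo, fHi)` from a Hann-tapered
#' periodogram of the (demeaned) segment: one FFT per analysis window, the
#' one-sided periodogram normalized so that the sum over a partition of
#' `[0, fs/2)` approximates the time-domain variance (Parseval). Half-open
#' band edges avoid double counting shared bin frequencies, so band powers
#' are exactly additive over disjoint bands.
#'
#' @param x Numeric signal segment (uV).
#' @param fs Sampling rate (Hz).
#' @param fLo,fHi Band edges (Hz), `0 <= fLo < fHi <= fs/2`.
#' @return Band power in uV^2.
#' @examples
#' fs <- 1000; t <- seq_len(fs) / fs
#' bandpower(sin(2 * pi * 3 * t), fs, 0, 4)   # ~0.5, the sine variance
#' @export
bandpower <- function(x, fs, fLo, fHi) {
  stopifnot(fLo >= 0, fLo < fHi, fHi <= fs / 2)
  n <- length(x)
  if (n < fs) warning("bandpower window shorter than 1 s")
  if (fLo > 0 && n < fs / fLo)
    warning("window shorter than one cycle of the lower band edge")
  bandpowerCore(x, bandpowerSetup(n, fs, fLo, fHi))
}

## Precomputed taper/bin layout for repeated equal-length band powers.
bandpowerSetup <- function(n, fs, fLo, fHi) {
  w <- hannWindow(n)
  nh <- floor(n / 2)
  f <- (0:nh) * fs / n
  mult <- c(1, rep(2, nh - 1L), if (n %% 2L == 0L) 1 else 2)
  sel <- which(f >= fLo & f < fHi)
  list(w = w, scale = n * sum(w^2), sel = sel, mult = mult[sel], nh = nh)
}

bandpowerCore <- function(x, su) {
  X <- stats::fft((x - mean(x)) * su$w)[su$sel]
  sum((Re(X)^2 + Im(X)^2) * su$mult) / su$scale
}

#' Peak-to-peak variability of a raw EEG trace
#'
#' Identifies all local extrema (positive and negative peaks, i.e. strict
#' sign changes of the first difference; plateaus of equal samples count
#' once, at the plateau centre) and returns the population standard
#' deviation of the absolute peak amplitudes. High-amplitude irregular
#' NREM activity yields large values; regular low-amplitude REM theta
#' yields small ones. The measure is scale-equivariant.
#'
#' @param x Numeric signal (uV), length >= 3.
#' @return SD (uV) of absolute peak amplitudes; 0 with a warning when fewer
#'   than two peaks exist.
#' @export
peakToPeakSD <- function(x) {
  stopifnot(length(x) >= 3L)
  pk <- findPeaks(x)
  if (length(pk) < 2L) {
    warning("fewer than two peaks; returning 0")
    return(0)
  }
  a <- abs(x[pk])
  sqrt(mean((a - mean(a))^2))                   # population SD
}

## Indices of local extrema; plateaus collapse to their centre sample.
findPeaks <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer())
  runs <- rle(s[nz])
  nRuns <- length(runs$values)
  if (nRuns < 2L) return(integer())
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-nRuns] + 1L)
  ## extremum between the end of run i and the start of run i+1; any
  ## zero-difference plateau between them collapses to its centre
  iEnd <- nz[ends[-nRuns]]        # last strict step of each run (index in d)
  iNext <- nz[starts[-1L]]        # first strict step of the following run
  as.integer(floor((iEnd + 1L + iNext) / 2))
}

#' Compute scoring features in non-overlapping windows
#'
#' One feature row per `windowS`-second window tiling the recording:
#' `theta_delta_ratio` (band power 6-10 Hz over 0-4 Hz of the parietal
#' EEG), `p2p_sd` (uV), and `emg_power` (uV^2, EMG variance). Recordings
#' above 1000 Hz are downsampled to the 1000-Hz analysis rate first.
#'
#' @param rec An [EEGRecording-class] with channels `eeg_parietal`, `emg`.
#' @param windowS Window length in seconds (4 by convention).
#' @return `data.frame` with columns `window_start_s`, `theta_delta_ratio`,
#'   `p2p_sd`, `emg_power`.
#' @export
computeFeatures <- function(rec, windowS = 4) {
  stopifnot(methods::is(rec, "EEGRecording"))
  if (sampleRate(rec) > 1000) rec <- downsampleRecording(rec, 1000)
  fs <- sampleRate(rec)
  eeg <- getChannel(rec, "eeg_parietal")
  emg <- if ("emg" %in% channelNames(rec)) getChannel(rec, "emg")
         else numeric(length(eeg))
  wlen <- round(windowS * fs)
  nWin <- floor(length(eeg) / wlen)
  if (nWin < 1L) stop("recording shorter than one scoring window")
  ratio <- p2p <- emgP <- numeric(nWin)
  for (k in seq_len(nWin)) {
    idx <- ((k - 1L) * wlen + 1L):(k * wlen)
    delta <- bandpower(eeg[idx], fs, DELTA_BAND[1L], DELTA_BAND[2L])
    theta <- bandpower(eeg[idx], fs, THETA_BAND[1L], THETA_BAND[2L])
    ratio[k] <- if (delta > 0) theta / delta else Inf
    p2p[k] <- peakToPeakSD(eeg[idx])
    emgP[k] <- stats::var(emg[idx]) * (wlen - 1) / wlen
  }
  data.frame(window_start_s = (seq_len(nWin) - 1L) * windowS,
             theta_delta_ratio = ratio, p2p_sd = p2p, emg_power = emgP)
}

#' Default classifier thresholds
#'
#' Ratio cut 1 (theta/delta ratio is orders of magnitude below 1 in NREM
#' and above 1 in REM), EMG power cut 200 uV^2 (between the sleep atonia
#' and waking muscle tone of the default generator; on real data this is a
#' per-animal calibration).
#'
#' @return Named list with `ratioCut`, `emgCut` and optional `p2pCut`.
#' @export
defaultThresholds <- function() list(ratioCut = 1, emgCut = 200, p2pCut = NULL)

#' Classify scoring windows into vigilance states
#'
#' Rule-based epoch classifier over [computeFeatures()] rows: WAKE when EMG
#' power exceeds the EMG cut; otherwise REM when the theta/delta ratio
#' exceeds the ratio cut; otherwise NREM. Windows with missing features
#' become UNKNOWN. An optional 3-window majority smoothing removes isolated
#' single-window state flips.
#'
#' @param features `data.frame` from [computeFeatures()].
#' @param thresholds List as from [defaultThresholds()].
#' @param windowS Window length (s) used to build the features.
#' @param smooth Apply 3-window majority smoothing (default TRUE).
#' @return A [Hypnogram-class] whose epochs tile the scored windows.
#' @export
classifyEpochs <- function(features, thresholds = defaultThresholds(),
                           windowS = 4, smooth = TRUE) {
  stopifnot(all(c("theta_delta_ratio", "p2p_sd", "emg_power") %in%
                names(features)))
  state <- ifelse(is.na(features$theta_delta_ratio) |
                    is.na(features$emg_power), "UNKNOWN",
           ifelse(features$emg_power > thresholds$emgCut, "WAKE",
           ifelse(features$theta_delta_ratio > thresholds$ratioCut,
                  "REM", "NREM")))
  if (!is.null(thresholds$p2pCut))
    state[state == "NREM" & features$p2p_sd < thresholds$p2pCut] <- "UNKNOWN"
  if (smooth && length(state) >= 3L) {
    sm <- state
    for (k in 2:(length(state) - 1L)) {
      tri <- state[(k - 1L):(k + 1L)]
      tab <- table(tri)
      if (max(tab) >= 2L && !state[k] %in% names(tab)[tab >= 2L])
        sm[k] <- names(tab)[which.max(tab)]
    }
    state <- sm
  }
  start <- features$window_start_s
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  methods::new("Hypnogram", epochs = data.frame(
    start_s = start[starts],
    end_s = start[ends] + windowS,
    state = runs$values))
}

#' State at a time point from a hypnogram
#' @param hyp A [Hypnogram-class].
#' @param timeS Time (s).
#' @return State label, `"UNKNOWN"` outside the hypnogram.
#' @export
stateAt <- function(hyp, timeS) {
  e <- epochs(hyp)
  hit <- which(e$start_s <= timeS & timeS < e$end_s)
  if (length(hit) == 0L) "UNKNOWN" else e$state[hit[1L]]
}
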