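## Small shared helpers: decibel conversion, seeded evaluation, tapers.

#' Convert sound pressure level to a linear amplitude gain
#'
#' Maps a level in dB SPL to a linear full-scale gain through a calibration
#' constant, `gain = calibration_const * 10^(db_spl / 20)`. The calibration
#' constant plays the role of the hardware calibration that relates a
#' reference level to digital full scale.
#'
#' @param dbSpl Level in dB SPL.
#' @param calibrationConst Positive constant mapping a reference level to
#'   full scale. The default anchors 73.5 dB SPL (the loudest level of the
#'   presentation ramp) to a gain of 1.
#' @return Linear amplitude gain (same length as `dbSpl`).
#' @examples
#' dbToAmplitude(73.5)           # 1
#' dbToAmplitude(53.5) * 10      # one tenth the amplitude per -20 dB
#' @export
dbToAmplitude <- function(dbSpl, calibrationConst = 10^(-73.5 / 20)) {
  stopifnot(is.numeric(dbSpl), length(calibrationConst) == 1L,
            calibrationConst > 0)
  calibrationConst * 10^(dbSpl / 20)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not perturb the caller's
#' random stream. With `seed = NULL` the expression uses the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed from a master seed
#'
#' Maps a master seed plus an index path (e.g. replicate, animal, session)
#' to a new seed below `.Machine$integer.max`, so multi-animal and
#' multi-replicate simulations are reproducible from one seed.
#'
#' @param master Master seed (integer-like).
#' @param ... Integer indices identifying the branch.
#' @return An integer seed.
#' @examples
#' childSeed(1, 3, 2) == childSeed(1, 3, 2)
#' @export
childSeed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (i in idx) s <- (s * 69069 + 1234567 + as.double(i)) %% 2147483629
  as.integer(s) + 1L
}

## Raised-cosine on/off amplitude ramps applied in place.
applyCosineRamps <- function(x, fs, rampS = 0.005) {
  n <- length(x)
  nr <- round(rampS * fs)
  if (nr < 1L || 2L * nr > n) return(x)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
  x
}

hannWindow <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    if (n == 1L) return(1)
    key <- as.character(n)
    w <- cache[[key]]
    if (is.null(w)) {
      w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
      cache[[key]] <- w
    }
    w
  }
})

## Analytic signal via the FFT construction (zero negative frequencies,
## double positive ones); used for instantaneous-frequency estimation.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Phase unwrapping for instantaneous-frequency estimation.
unwrapPhase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}
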