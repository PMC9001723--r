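# Stimulus synthesis: tones, chirps, clouds, and the intensity-ramp scheme.

test_that("pure tone has the requested frequency and amplitude", {
  fs <- 200000
  tone <- makePureTone(10000, 0.1, fs = fs)
  expect_s4_class(tone, "SoundWaveform")
  expect_equal(duration(tone), 0.1)
  # dominant spectral peak at 10 kHz
  x <- samples(tone)
  X <- Mod(fft(x))[1:(length(x) / 2)]
  peakHz <- (which.max(X) - 1) * fs / length(x)
  expect_equal(peakHz, 10000, tolerance = 1e-3)
  # RMS of the un-ramped interior is peak / sqrt(2)
  interior <- x[1001:(length(x) - 1000)]
  expect_equal(sqrt(mean(interior^2)), 1 / sqrt(2), tolerance = 1e-3)
  expect_lte(max(abs(x)), 1)
})

test_that("degenerate tone frequencies are rejected", {
  expect_error(makePureTone(0, 0.1), "positive")
  expect_error(makePureTone(-100, 0.1), "positive")
  expect_error(makePureTone(120000, 0.1, fs = 200000), "Nyquist")
})

test_that("chirps follow a log-linear frequency trajectory", {
  up <- makeChirp(10500, octaveSpan = 2, rateOctPerS = 50, direction = "up")
  expect_equal(duration(up), 0.04)                     # 2 octaves / 50 oct/s
  expect_equal(freqMeta(up)$end_hz, 42000)             # 10500 * 2^2
  down <- makeChirp(10500, direction = "down")
  expect_equal(freqMeta(down)$end_hz, 2625)            # 10500 / 2^2
  # regression of log2(instantaneous frequency) on time recovers the rate
  expect_equal(chirpSweepRate(up)$rateOctPerS, 50, tolerance = 0.01)
  expect_equal(chirpSweepRate(down)$rateOctPerS, -50, tolerance = 0.01)
  # holds across other parameterizations too
  other <- makeChirp(8000, octaveSpan = 2.5, rateOctPerS = 40)
  expect_equal(chirpSweepRate(other)$rateOctPerS, 40, tolerance = 0.01)
})

test_that("chirps violating the frequency limits are rejected", {
  expect_error(makeChirp(30000, octaveSpan = 2, direction = "up"), "Nyquist")
  expect_error(makeChirp(60, octaveSpan = 2, direction = "down"), "20 Hz")
})

test_that("sound clouds satisfy the subrange and ordering constraints", {
  spec <- cloudSpec(3000, 4662)
  for (seed in 1:300) {
    tones <- drawCloudTones(spec, seed = seed)
    expect_equal(nrow(tones), 6L)
    expect_true(all(tones$freq_hz >= 3000 & tones$freq_hz <= 4662))
    # two tones per subrange overall, one per subrange within each half
    expect_equal(as.integer(table(tones$subrange)), rep(2L, 3))
    expect_equal(sort(tones$subrange[1:3]), 1:3)
    expect_equal(sort(tones$subrange[4:6]), 1:3)
    # no two consecutive tones share a subrange, across the half boundary too
    expect_true(all(diff(tones$subrange) != 0))
  }
})

test_that("cloud synthesis is seed-deterministic and bounded", {
  spec <- cloudSpec(12379, 19240)
  a <- makeSoundCloud(spec, seed = 42)
  b <- makeSoundCloud(spec, seed = 42)
  expect_identical(samples(a), samples(b))
  expect_equal(duration(a), 0.25, tolerance = 1e-4)
  expect_lte(max(abs(samples(a))), 1)
  c2 <- makeSoundCloud(spec, seed = 43)
  expect_false(identical(samples(a), samples(c2)))
})

test_that("the intensity ramp realizes the fixed presentation scheme", {
  ramp <- buildIntensityRamp(makeChirp(10500), render = TRUE)
  p <- pulses(ramp$schedule)
  nz <- p[!p$is_zero, ]
  expect_equal(nrow(nz), 24L)
  expect_equal(sum(p$is_zero), 3L)
  # the three zero-amplitude pulses precede all sound pulses
  expect_lt(max(p$onset_s[p$is_zero]), min(nz$onset_s))
  levels <- unique(nz$intensity_dbspl)
  expect_equal(length(levels), 8L)
  expect_equal(min(levels), 24.6)
  expect_equal(max(levels), 73.5)
  # equal dB spacing: (73.5 - 24.6) / 7
  expect_equal(unique(round(diff(levels), 6)), round(48.9 / 7, 6))
  expect_true(!is.unsorted(nz$intensity_dbspl))
  # rendered pulse peaks respect dbToAmplitude exactly (73.5 dB -> 1)
  fs <- 200000
  calib <- 10^(-73.5 / 20)
  for (i in c(4, 16, 27)) {  # first sound pulse, a middle one, the loudest
    i0 <- round(p$onset_s[i] * fs)
    seg <- ramp$samples[(i0 + 1):(i0 + round(p$duration_s[i] * fs))]
    expect_equal(max(abs(seg)), dbToAmplitude(p$intensity_dbspl[i], calib),
                 tolerance = 1e-6)
  }
  # zero-amplitude block renders silence
  expect_equal(max(abs(ramp$samples[1:(fs - 100)])), 0)
})

test_that("over-long pulses are rejected by the scheduler", {
  expect_error(buildIntensityRamp(makePureTone(5000, 0.5)), "block slot")
})

test_that("decibel-to-amplitude conversion follows the dB law", {
  expect_equal(dbToAmplitude(50) / dbToAmplitude(30), 10)
  expect_equal(dbToAmplitude(56.02) / dbToAmplitude(50), 2, tolerance = 1e-3)
  expect_equal(dbToAmplitude(73.5), 1)
  expect_true(all(diff(dbToAmplitude(seq(20, 70, by = 5))) > 0))
})
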