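# Sound-locked power extraction, normalization, aggregation, downsampling.

test_that("baseline normalization divides by the 8-s pre-onset mean", {
  expect_equal(normalizeToBaseline(rep(3, 24))$normalized, rep(1, 24))
  v <- c(rep(2, 8), rep(0.7, 8), rep(2, 8))
  n <- normalizeToBaseline(v)
  expect_equal(n$normalized[9:16], rep(0.35, 8))
  expect_false(n$excluded)
  expect_warning(z <- normalizeToBaseline(c(rep(0, 8), rep(1, 16))),
                 "baseline")
  expect_true(z$excluded)
  expect_null(z$normalized)
})

test_that("epoch extraction is onset-locked with state-dependent bands", {
  sim <- simulatePresentationEpoch("NREM", "conditioned", seed = 2)
  ep <- extractEpochPower(sim$rec, sim$onsetS, "NREM")
  expect_s4_class(ep, "EpochPower")
  expect_equal(ep@band, "delta")
  expect_equal(mean(normalizedPower(ep)[1:8]), 1)       # block-1 identity
  expect_equal(length(rawPower(ep)), 24L)
  epR <- extractEpochPower(simulatePresentationEpoch("REM", "conditioned",
                                                     seed = 2)$rec,
                           8.5, "REM")
  expect_equal(epR@band, "theta")
  # windows outside the recording and non-sleep onsets are rejected
  expect_error(extractEpochPower(sim$rec, 2, "NREM"), "past the recording")
  expect_error(extractEpochPower(sim$rec, 23, "NREM"), "past the recording")
  expect_error(extractEpochPower(sim$rec, 8.5, "WAKE"), "NREM or REM")
})

test_that("stationary epochs without sound effects stay near unity", {
  sim <- simulatePresentationEpoch("NREM", "pre_control",
                                   nullProfiles(), seed = 11)
  ep <- extractEpochPower(sim$rec, sim$onsetS, "NREM")
  expect_equal(mean(normalizedPower(ep)[9:24]), 1, tolerance = 0.45)
})

test_that("suppressed epochs approach the configured gain", {
  vals <- vapply(1:25, function(i) {
    ep <- quickEpoch("NREM", "conditioned", seed = 400 + i)
    mean(normalizedPower(ep)[12:16])
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.35), 0.06)
})

test_that("aggregation weights animals equally regardless of sessions", {
  eps <- c(list(flatEpoch(1, "A", "s1"), flatEpoch(2, "A", "s2")),
           lapply(1:10, function(i) flatEpoch(3, "B", paste0("t", i))))
  agg <- aggregateEpochs(eps)
  # animal A mean 1.5, animal B mean 3 -> grand mean 2.25 outside block 1
  expect_equal(unique(agg$mean_normalized[agg$time_s > 8]), 2.25)
  expect_equal(unique(agg$mean_normalized[agg$time_s <= 8]), 1)
  expect_true(all(agg$n_animals == 2))
  # order invariance
  agg2 <- aggregateEpochs(rev(eps))
  expect_equal(agg2$mean_normalized, agg$mean_normalized)
  # duplicating a session of an included animal acts only via that animal
  eps3 <- c(eps, list(flatEpoch(3, "B", "t11")))
  expect_equal(aggregateEpochs(eps3)$mean_normalized, agg$mean_normalized)
  # single animal, single session: grand mean equals the epoch
  single <- aggregateEpochs(list(flatEpoch(2, "A", "s1")))
  expect_equal(unique(single$mean_normalized[single$time_s > 8]), 2)
})

test_that("day-wise grouping splits the aggregate", {
  eps <- list(flatEpoch(2, "A", "s1", day = 1), flatEpoch(4, "A", "s2", day = 2))
  agg <- aggregateEpochs(eps, by = c("sound_type", "phase", "day"))
  expect_equal(sort(unique(agg$day)), 1:2)
  expect_equal(unique(agg$mean_normalized[agg$day == 2 & agg$time_s > 8]), 4)
})

test_that("long-format tables carry one row per epoch-second", {
  tab <- epochPowerTable(list(flatEpoch(2, "A", "s1")))
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$time, rep(1:8, 3))
  expect_equal(tab$block, rep(1:3, each = 8))
  expect_equal(unique(tab$phase), "NREM")
})

test_that("downsampling preserves the passband and rejects aliases", {
  fs <- 30000
  t <- seq_len(3 * fs) / fs
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 600 * t)
  rec <- methods::new("EEGRecording",
                      channels = cbind(eeg_parietal = x, emg = x * 0),
                      fs = fs)
  dn <- downsampleRecording(rec, 1000)
  expect_equal(sampleRate(dn), 1000)
  expect_equal(nrow(dn@channels) * 30L, length(x))        # length ratio 30
  y <- getChannel(dn, "eeg_parietal")[500:2500]
  t2 <- seq_along(y) / 1000
  # 100-Hz component preserved in amplitude within 1%
  amp100 <- sqrt(2 * bandpower(y, 1000, 90, 110))
  expect_equal(amp100, 1, tolerance = 0.01)
  # 600-Hz component (above the new Nyquist) attenuated by > 40 dB
  p600 <- bandpower(getChannel(rec, "eeg_parietal")[1:30000], fs, 590, 610)
  pAlias <- bandpower(y, 1000, 350, 450)
  expect_lt(pAlias / p600, 1e-4)
  expect_error(downsampleRecording(dn, 30000), "exceeds")
  expect_error(downsampleRecording(rec, 999), "divide")
})

test_that("the scored pipeline rejects wake presentations", {
  rec <- simulateSession(boutHypnogram(c(WAKE = 25)), seed = 6)
  expect_null(processPresentation(rec, 8.5))
  simN <- simulatePresentationEpoch("NREM", "conditioned", seed = 6)
  ep <- processPresentation(simN$rec, simN$onsetS, soundType = "conditioned")
  expect_s4_class(ep, "EpochPower")
  expect_equal(ep@state, "NREM")
})
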