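# Synthetic EEG/EMG generation and sound-evoked suppression.

test_that("simulated bouts carry the intended spectral signatures", {
  recN <- simulateSession(boutHypnogram(c(NREM = 60)), seed = 1)
  recR <- simulateSession(boutHypnogram(c(REM = 60)), seed = 1)
  eegN <- getChannel(recN, "eeg_parietal")
  eegR <- getChannel(recR, "eeg_parietal")
  expect_gt(bandpower(eegN, 1000, 0, 4), bandpower(eegN, 1000, 6, 10))
  ratioN <- bandpower(eegN, 1000, 6, 10) / bandpower(eegN, 1000, 0, 4)
  ratioR <- bandpower(eegR, 1000, 6, 10) / bandpower(eegR, 1000, 0, 4)
  expect_gt(ratioR, ratioN)
  # EMG tone orders WAKE above sleep
  recW <- simulateSession(boutHypnogram(c(WAKE = 60)), seed = 1)
  expect_gt(var(getChannel(recW, "emg")), var(getChannel(recN, "emg")))
})

test_that("simulation is seed-deterministic and validates its inputs", {
  plan <- boutHypnogram(c(NREM = 20))
  a <- simulateSession(plan, seed = 7)
  b <- simulateSession(plan, seed = 7)
  expect_identical(a@channels, b@channels)
  expect_error(simulateSession(methods::new("Hypnogram",
    epochs = data.frame(start_s = numeric(), end_s = numeric(),
                        state = character()))), "empty")
  bad <- defaultStateParams()
  bad$NREM@amplitudeIrregularity <- 0.01
  expect_error(simulateSession(plan, bad), "irregularity")
})

test_that("unit gain leaves the recording untouched", {
  plan <- boutHypnogram(c(NREM = 30))
  rec <- simulateSession(plan, seed = 3)
  out <- applySoundResponse(rec, rampSchedule(soundId = "pre_control"),
                            nullProfiles(), "NREM", onsetS = 10)
  expect_identical(out@channels[, "eeg_parietal"],
                   rec@channels[, "eeg_parietal"])
  expect_equal(nrow(triggers(out)), 1L)
})

test_that("suppression gain follows the onset/asymptote/recovery contract", {
  sch <- rampSchedule(soundId = "conditioned")
  t <- seq(0, 40, by = 0.01)
  g <- 0.35
  a <- sleepgate:::suppressionGain(t, sch, onsetS = 10, gain = g,
                                   thresholdDb = 30, latencyS = 0.4,
                                   recoveryS = 6)
  # threshold of 30 dB is first crossed by the second intensity block
  expect_true(all(a[t < 11] == 1))
  # asymptote sqrt(g) reached well before sound offset
  expect_equal(min(a), sqrt(g), tolerance = 1e-6)
  expect_equal(a[findInterval(17.9, t)], sqrt(g), tolerance = 0.01)
  # linear recovery back to 1 at offset + recovery
  expect_equal(a[findInterval(24.2, t)], 1, tolerance = 0.01)
  expect_true(all(a[t > 24.1] == 1))
  # unknown sound type is rejected
  rec <- simulateSession(boutHypnogram(c(NREM = 30)), seed = 4)
  expect_error(applySoundResponse(rec, rampSchedule(soundId = "mystery"),
                                  defaultProfiles(), "NREM", 10),
               "no suppression profile")
})

test_that("default profiles encode the calibrated effect sizes", {
  p <- profileTable(defaultProfiles("learner"))
  gOf <- function(s, st) p$gain[p$sound_type == s & p$state == st]
  expect_equal(gOf("conditioned", "NREM"), 0.35)
  expect_equal(gOf("conditioned", "REM"), 0.60)
  expect_lt(gOf("post_control", "NREM"), 0.6)
  expect_equal(gOf("post_control", "REM"), 1.0)
  expect_gte(gOf("pre_control", "NREM"), 0.85)
  # pre-control engages only at the loudest intensities
  expect_gte(p$threshold_dbspl[p$sound_type == "pre_control"][1], 59.6)
  np <- profileTable(defaultProfiles("nonlearner"))
  expect_true(all(np$gain >= 0.9 & np$gain <= 1.0))
  expect_true(all(p$recovery_s >= 4 & p$recovery_s <= 8))
})

test_that("the pipeline recovers configured suppression gains", {
  # parameter recovery: mean normalized during-sound plateau within +/-0.05
  # of the configured power gain
  for (g in c(0.2, 0.6, 1.0)) {
    prof <- nullProfiles()
    pt <- profileTable(prof)
    pt$gain[pt$sound_type == "conditioned"] <- g
    pt$threshold_dbspl[pt$sound_type == "conditioned"] <- 30
    prof@profile <- pt
    eps <- list()
    for (a in 1:5) {
      sess <- simulatePresentationSession("NREM", rep("conditioned", 30),
                                          prof, seed = round(g * 100) + a,
                                          fs = 200)
      for (i in seq_along(sess$onsets))
        eps[[length(eps) + 1L]] <- extractEpochPower(
          sess$rec, sess$onsets[i], "NREM", soundType = "conditioned",
          animalId = sprintf("a%d", a), sessionId = sprintf("a%d_%d", a, i))
    }
    tab <- epochPowerTable(eps)
    plateau <- tab$normalized_power[tab$block == 2 & tab$time >= 4]
    expect_lt(abs(mean(plateau) - g), 0.05)
  }
})

test_that("presentation epochs are reproducible and carry triggers", {
  a <- simulatePresentationEpoch("REM", "conditioned", seed = 5)
  b <- simulatePresentationEpoch("REM", "conditioned", seed = 5)
  expect_identical(a$rec@channels, b$rec@channels)
  expect_equal(triggers(a$rec)$sound_id, "conditioned")
  expect_equal(a$onsetS, 8.5)
})
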