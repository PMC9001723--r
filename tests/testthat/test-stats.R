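# Mixed models, learner criterion, avoidance, sigmoid and ANOVA/Tukey.

test_that("learner criterion applies the 80% / 15-trial boundaries", {
  mk <- function(d2n, d2avoid, d1n = 10) {
    rbind(data.frame(animal_id = "a", day = 1, trial_index = seq_len(d1n),
                     avoided = TRUE),
          data.frame(animal_id = "a", day = 2, trial_index = seq_len(d2n),
                     avoided = seq_len(d2n) <= d2avoid))
  }
  expect_equal(classifyLearner(mk(20, 17)), "learner")       # 85%, 30 trials
  # 90% day-2 avoidance but only 12 cumulative trials
  expect_equal(classifyLearner(mk(10, 9, d1n = 2)), "nonlearner")
  # exactly 80% is not "more than 80%"
  expect_equal(classifyLearner(mk(20, 16)), "nonlearner")
  expect_equal(classifyLearner(mk(20, 17)[1:10, ]), "UNKNOWN") # no day 2
})

test_that("learner criterion is monotone in avoidance and trial count", {
  set.seed(1)
  for (i in 1:50) {
    n2 <- sample(5:25, 1)
    k <- sample(0:n2, 1)
    tr <- data.frame(animal_id = "a", day = 2, trial_index = seq_len(n2),
                     avoided = seq_len(n2) <= k)
    base <- classifyLearner(tr)
    # flipping one failure to success never demotes a learner
    if (k < n2) {
      tr2 <- tr; tr2$avoided[k + 1] <- TRUE
      if (base == "learner")
        expect_equal(classifyLearner(tr2), "learner")
    }
    # adding an avoided trial never demotes
    tr3 <- rbind(tr, data.frame(animal_id = "a", day = 2,
                                trial_index = n2 + 1, avoided = TRUE))
    if (base == "learner") expect_equal(classifyLearner(tr3), "learner")
  }
})

test_that("avoidance rates count visits without nose pokes", {
  v <- data.frame(animal_id = "a1", day = 1, sound = "cond",
                  nosepoked = c(rep(FALSE, 7), rep(TRUE, 3)))
  av <- avoidanceBySound(v)
  expect_equal(av$avoidance_pct, 70)
  expect_equal(av$n_visits, 10)
  # early/late phases take the first and last two days per sound
  v2 <- do.call(rbind, lapply(1:6, function(d)
    data.frame(animal_id = "a1", day = d, sound = "cond",
               nosepoked = rep(d > 2, 5))))
  expect_equal(avoidanceBySound(v2, "early")$avoidance_pct, 100)
  expect_equal(avoidanceBySound(v2, "late")$avoidance_pct, 0)
})

test_that("simulated Audiobox behaviour meets the stability targets", {
  v <- simulateAudioboxVisits(nAnimals = 6, visitsPerDay = 12, nDays = 4,
                              seed = 8)
  av <- avoidanceBySound(v)
  safe <- av$avoidance_pct[av$sound == "safe"]
  cond <- av$avoidance_pct[av$sound == "cond"]
  expect_gt(mean(100 - safe), 50)   # > 50% nose poking in safe visits
  expect_gt(mean(cond), 80)         # > 80% avoidance in conditioned visits
})

test_that("sigmoid fits recover step, flat and noisy 4PL data", {
  # perfect step: midpoint between ranks 2 and 3
  step <- fitSigmoid(1:4, c(0, 0, 100, 100))
  expect_true(step$converged)
  expect_equal(unname(step$parameters["midpoint"]), 2.5, tolerance = 0.2)
  # constant data: zero slope, floor == ceiling
  flat <- fitSigmoid(1:5, rep(42, 5))
  expect_equal(unname(flat$parameters["slope"]), 0)
  expect_equal(unname(flat$parameters["floor"]),
               unname(flat$parameters["ceiling"]))
  # parameter recovery on noisy synthetic 4PL data
  set.seed(14)
  x <- rep(1:5, each = 6)
  truth <- c(fl = 20, ce = 90, mid = 3, sl = 2.2)
  y <- truth["fl"] + (truth["ce"] - truth["fl"]) /
    (1 + exp(-truth["sl"] * (x - truth["mid"]))) + rnorm(length(x), 0, 4)
  fit <- fitSigmoid(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["floor"]), 20, tolerance = 0.25)
  expect_equal(unname(fit$parameters["ceiling"]), 90, tolerance = 0.1)
  expect_equal(unname(fit$parameters["midpoint"]), 3, tolerance = 0.15)
})

test_that("ANOVA with Tukey-Kramer matches its oracles", {
  # identical group means: F ~ 0, nothing significant
  same <- data.frame(sound = rep(c("a", "b", "c"), each = 4),
                     avoidance_pct = rep(c(50, 55, 45, 50), 3))
  res <- anovaTukey(same)
  expect_lt(res$F, 1e-20)
  expect_true(all(res$tukey$p_adj > 0.99))
  # two balanced groups: Tukey p equals the pooled-variance t-test p
  set.seed(3)
  two <- data.frame(sound = rep(c("a", "b"), each = 8),
                    avoidance_pct = c(rnorm(8, 50, 8), rnorm(8, 62, 8)))
  res2 <- anovaTukey(two)
  tp <- t.test(avoidance_pct ~ sound, data = two, var.equal = TRUE)$p.value
  expect_equal(res2$tukey$p_adj, tp, tolerance = 1e-6)
  # adjusted p values never undercut the unadjusted pairwise p values
  set.seed(4)
  multi <- data.frame(sound = rep(c("a", "b", "c", "d"), times = c(5, 7, 6, 8)),
                      avoidance_pct = rnorm(26, 50, 10) +
                        rep(c(0, 5, 10, 15), times = c(5, 7, 6, 8)))
  res3 <- anovaTukey(multi)
  for (i in seq_len(nrow(res3$tukey))) {
    gg <- strsplit(res3$tukey$comparison[i], "-")[[1]]
    praw <- t.test(multi$avoidance_pct[multi$sound == gg[1]],
                   multi$avoidance_pct[multi$sound == gg[2]],
                   var.equal = TRUE)$p.value
    expect_gte(res3$tukey$p_adj[i] + 1e-9, praw)
  }
  # graded avoidance across sounds produces a clear main effect
  v <- simulateAudioboxVisits(seed = 5)
  res4 <- anovaTukey(avoidanceBySound(v))
  expect_lt(res4$p, 0.001)
  expect_error(anovaTukey(data.frame(sound = "a", avoidance_pct = 1)),
               "two sounds")
})

test_that("block LMMs detect the learner effect and report the LRT", {
  eps <- list()
  withSeed(91, {
    for (a in 1:6) {
      sq <- sample(rep(c("conditioned", "pre_control"), each = 4))
      sess <- simulatePresentationSession("NREM", sq,
                                          defaultProfiles("learner"),
                                          seed = 9100 + a, fs = 200)
      for (i in seq_along(sq))
        eps[[length(eps) + 1L]] <- extractEpochPower(
          sess$rec, sess$onsets[i], "NREM", soundType = sq[i],
          animalId = sprintf("a%d", a), sessionId = sprintf("a%d_%d", a, i))
    }
  })
  tab <- epochPowerTable(eps)
  m2 <- fitBlockLMM(tab, 2)
  # strong sound-time interaction during the sound window
  expect_lt(m2$anova["sound_type:time", "Pr(>F)"], 0.001)
  # conditioned (reference level) declines over the ramp; pre-control does
  # not, so its interaction coefficient is positive
  expect_lt(m2$coefficients[["time"]], 0)
  expect_gt(m2$coefficients[["sound_typepre_control:time"]], 0)
  expect_equal(m2$lrt$df, 2)                    # two variance parameters
  expect_gte(m2$lrt$chisq, 0)
  # block 1 precedes the sound: the normalization identity pins every
  # sound's baseline mean at exactly 1, so no sound effect can exist there
  for (snd in c("conditioned", "pre_control")) {
    b1 <- tab$normalized_power[tab$block == 1 & tab$sound_type == snd]
    expect_equal(mean(b1), 1, tolerance = 1e-9)
  }
  # whereas block 2 shows a two-thirds power drop for the conditioned sound
  b2c <- tab$normalized_power[tab$block == 2 & tab$time >= 4 &
                                tab$sound_type == "conditioned"]
  expect_lt(mean(b2c), 0.5)
})

test_that("the block-2 model has power against the learner effect", {
  # small replicate study at the paper's design scale, conditioned vs
  # pre-control during NREM: the interaction should be detected every time
  hits <- vapply(1:5, function(r) {
    eps <- list()
    withSeed(7000 + r, {
      for (a in 1:6) {
        sq <- sample(rep(c("conditioned", "pre_control"), each = 7))
        sess <- simulatePresentationSession("NREM", sq,
                                            defaultProfiles("learner"),
                                            seed = 7000 + r * 10 + a,
                                            fs = 200)
        for (i in seq_along(sq))
          eps[[length(eps) + 1L]] <- extractEpochPower(
            sess$rec, sess$onsets[i], "NREM", soundType = sq[i],
            animalId = sprintf("a%d", a), sessionId = sprintf("a%d_%d", a, i))
      }
    })
    m <- fitBlockLMM(epochPowerTable(eps), 2, lrt = FALSE)
    m$anova["sound_type:time", "Pr(>F)"] < 0.05
  }, logical(1))
  expect_true(all(hits))
})
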