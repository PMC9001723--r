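## Block-wise linear mixed models, learner classification, and the
## avoidance/generalization behavioural analyses.

#' Fit the block-wise linear mixed model
#'
#' REML linear mixed model on one block of the long power table, with the
#' requested fixed effects (time is continuous, 1-8 s within the block)
#' and random intercepts for animal and for session nested in animal.
#' F tests per fixed term use Satterthwaite denominator degrees of
#' freedom; coefficients are reported as estimated effect sizes. A
#' likelihood-ratio test (ML refits) against the fixed-effects-only linear
#' model quantifies the contribution of the random effects, with chi-square
#' df equal to the number of variance parameters removed.
#'
#' @param table Long table from [epochPowerTable()].
#' @param block Block to analyse: 1 (pre), 2 (during) or 3 (post).
#' @param fixed Right-hand side of the fixed-effects formula (default
#'   `"sound_type * time"`; use e.g. `"phase + sound_type * time"` when the
#'   table pools sleep states).
#' @param random Random-effects specification (default
#'   `"(1 | animal_id) + (1 | animal_id:session_id)"`).
#' @return List of class `"sleepgateLMM"`: `fit` (the `lmerMod`), `anova`
#'   (Satterthwaite F table), `coefficients` (estimated effect sizes),
#'   `varcor`, `singular` (logical), and `lrt` (`chisq`, `df`, `p`).
#' @export
fitBlockLMM <- function(table, block,
                        fixed = "sound_type * time",
                        random = "(1 | animal_id) + (1 | animal_id:session_id)",
                        lrt = TRUE) {
  stopifnot(block %in% 1:3)
  d <- table[table$block == block, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for block ", block)
  d$time <- as.numeric(d$time)
  form <- stats::as.formula(paste("normalized_power ~", fixed, "+", random))
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  aov <- stats::anova(fit, ddf = "Satterthwaite")
  lrtRes <- NULL
  if (lrt) {
    ## LRT against the fixed-effects-only model (ML fits)
    fitML <- suppressMessages(lme4::refitML(fit))
    lmForm <- stats::as.formula(paste("normalized_power ~", fixed))
    fit0 <- stats::lm(lmForm, data = d)
    nVar <- length(lme4::getME(fitML, "theta"))
    chisq <- max(0, 2 * (as.numeric(stats::logLik(fitML)) -
                           as.numeric(stats::logLik(fit0))))
    lrtRes <- list(chisq = chisq, df = nVar,
                   p = stats::pchisq(chisq, df = nVar, lower.tail = FALSE))
  }
  lrt <- lrtRes
  out <- list(fit = fit, anova = aov,
              coefficients = lme4::fixef(fit),
              varcor = lme4::VarCorr(fit), singular = singular, lrt = lrt,
              block = block, n = nrow(d))
  class(out) <- "sleepgateLMM"
  out
}

#' @export
print.sleepgateLMM <- function(x, ...) {
  cat(sprintf("Block-%d linear mixed model (n = %d rows)%s\n", x$block, x$n,
              if (x$singular) " [singular fit]" else ""))
  print(x$anova)
  if (!is.null(x$lrt))
    cat(sprintf("LRT vs fixed-effects-only: chi2(%d) = %.2f, p = %.3g\n",
                x$lrt$df, x$lrt$chisq, x$lrt$p))
  invisible(x)
}

## P value of one fixed-effect term from a fitted block LMM.
termP <- function(lmm, term) {
  a <- lmm$anova
  hit <- rownames(a) == term
  if (!any(hit)) stop("no term '", term, "' in the model")
  a[hit, "Pr(>F)"]
}

#' Classify an animal as learner or non-learner
#'
#' Learner iff avoidance on conditioning day 2 exceeds 80% and at least 15
#' conditioning trials were accumulated by then; exactly 80% or fewer than
#' 15 trials gives non-learner. Without day-2 trials the animal is
#' `"UNKNOWN"`.
#'
#' @param trials `data.frame` with columns `animal_id` (optional), `day`,
#'   `avoided` (logical) — one row per conditioning trial.
#' @param avoidanceCut Avoidance threshold (strict), default 0.80.
#' @param minTrials Minimum cumulative trials through day 2, default 15.
#' @return `"learner"`, `"nonlearner"` or `"UNKNOWN"`.
#' @export
classifyLearner <- function(trials, avoidanceCut = 0.80, minTrials = 15L) {
  stopifnot(all(c("day", "avoided") %in% names(trials)))
  d2 <- trials[trials$day == 2L, , drop = FALSE]
  if (nrow(d2) == 0L) return("UNKNOWN")
  avoidance <- mean(d2$avoided)
  nCum <- sum(trials$day <= 2L)
  if (avoidance > avoidanceCut && nCum >= minTrials) "learner" else "nonlearner"
}

#' Per-sound avoidance rates in the Audiobox
#'
#' Avoidance is the percentage of corner visits without a nose poke, per
#' sound and animal, within a training phase (early = first two days of a
#' sound's exposure, late = last two days).
#'
#' @param visits `data.frame` with columns `animal_id`, `day`, `sound`,
#'   `nosepoked` (logical).
#' @param phase `"early"`, `"late"` or `"all"`.
#' @return `data.frame` with columns `animal_id`, `sound`, `n_visits`,
#'   `avoidance_pct`. Sounds without visits are omitted.
#' @export
avoidanceBySound <- function(visits, phase = c("all", "early", "late")) {
  phase <- match.arg(phase)
  stopifnot(all(c("animal_id", "day", "sound", "nosepoked") %in%
                names(visits)))
  if (phase != "all") {
    keep <- unlist(lapply(split(visits, visits$sound), function(v) {
      days <- sort(unique(v$day))
      sel <- if (phase == "early") utils::head(days, 2L)
             else utils::tail(days, 2L)
      rownames(v)[v$day %in% sel]
    }))
    visits <- visits[rownames(visits) %in% keep, , drop = FALSE]
  }
  if (nrow(visits) == 0L) return(data.frame())
  agg <- stats::aggregate(nosepoked ~ animal_id + sound, data = visits,
                          FUN = function(x) c(n = length(x),
                                              av = 100 * mean(!x)))
  data.frame(animal_id = agg$animal_id, sound = agg$sound,
             n_visits = agg$nosepoked[, "n"],
             avoidance_pct = agg$nosepoked[, "av"])
}

#' Four-parameter logistic fit of avoidance against sound rank
#'
#' Least-squares 4PL fit `y = floor + (ceiling - floor) /
#' (1 + exp(-slope * (x - midpoint)))` describing the generalization
#' gradient of avoidance across sounds ranked by frequency distance from
#' the safe sound.
#'
#' @param x Sound rank (numeric).
#' @param y Avoidance (%) at each rank.
#' @return List with `parameters` (floor, ceiling, midpoint, slope),
#'   `fitted`, `residuals` and `converged`. Non-convergence is reported,
#'   with residuals of the best candidate, not silently dropped.
#' @export
fitSigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  lo <- min(y); hi <- max(y)
  if (hi - lo < 1e-8) {
    ## degenerate flat data: slope ~ 0, floor ~ ceiling
    return(list(parameters = c(floor = lo, ceiling = hi,
                               midpoint = mean(x), slope = 0),
                fitted = rep(mean(y), length(y)),
                residuals = y - mean(y), converged = TRUE))
  }
  dx <- max(diff(range(x)), 1e-6)
  ## midpoint guess from the half-maximum crossing
  yc <- (lo + hi) / 2
  ord <- order(x)
  cross <- which(diff(sign(y[ord] - yc)) != 0)
  midCross <- if (length(cross))
    mean(x[ord][cross[1L] + 0:1]) else mean(range(x))
  ## a ladder of starts guards against singular gradients at symmetric
  ## initial values on step-like data
  starts <- expand.grid(sl = c(1, 2.5, 6, 15) / dx,
                        mid = c(midCross, midCross + 0.013 * dx))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fl + (ce - fl) / (1 + exp(-sl * (x - mid))),
                        start = list(fl = lo, ce = hi,
                                     mid = starts$mid[i], sl = starts$sl[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    pred <- rep(mean(y), length(y))
    return(list(parameters = NULL, fitted = pred, residuals = y - pred,
                converged = FALSE, message = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  list(parameters = c(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
                      midpoint = unname(cf["mid"]), slope = unname(cf["sl"])),
       fitted = stats::fitted(fit), residuals = stats::resid(fit),
       converged = TRUE)
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' One-way ANOVA of per-animal avoidance across sounds, followed by
#' Tukey-Kramer adjusted pairwise comparisons (the studentized-range
#' procedure with the unequal-n generalization).
#'
#' @param avoidance `data.frame` with columns `sound` and `avoidance_pct`
#'   (one row per animal x sound), e.g. from [avoidanceBySound()].
#' @return List with `F`, `df`, `p`, and `tukey` (a `data.frame` of
#'   pairwise differences with adjusted p values).
#' @export
anovaTukey <- function(avoidance) {
  stopifnot(all(c("sound", "avoidance_pct") %in% names(avoidance)))
  avoidance$sound <- factor(avoidance$sound)
  if (nlevels(avoidance$sound) < 2L)
    stop("need at least two sounds for an ANOVA")
  fit <- stats::aov(avoidance_pct ~ sound, data = avoidance)
  s <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$sound
  list(F = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]),
       p = s[["Pr(>F)"]][1L],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Simulate audio-terrace conditioning trials
#'
#' Bernoulli avoidance outcomes per trial with a day-dependent success
#' probability (learning curve), for exercising the learner criterion.
#'
#' @param nDays Days of conditioning.
#' @param trialsPerDay Trials per day.
#' @param pAvoidByDay Success probability per day (recycled).
#' @param animalId Label.
#' @param seed Integer seed or `NULL`.
#' @return `data.frame` with columns `animal_id`, `day`, `trial_index`,
#'   `avoided`.
#' @export
simulateTerraceTrials <- function(nDays = 4L, trialsPerDay = 10L,
                                  pAvoidByDay = c(0.5, 0.9, 0.95, 0.95),
                                  animalId = "a01", seed = NULL) {
  p <- rep_len(pAvoidByDay, nDays)
  withSeed(seed, {
    do.call(rbind, lapply(seq_len(nDays), function(d)
      data.frame(animal_id = animalId, day = d,
                 trial_index = seq_len(trialsPerDay),
                 avoided = stats::runif(trialsPerDay) < p[d])))
  })
}

#' Simulate Audiobox visits
#'
#' Corner visits with per-sound nose-poke probabilities: safe visits are
#' mostly poked (> 50%), conditioned visits mostly avoided (> 80%
#' avoidance), and novel sounds interpolate according to their frequency
#' distance from the conditioned sound.
#'
#' @param nAnimals Number of animals.
#' @param visitsPerDay Visits per animal, sound and day.
#' @param nDays Days of exposure.
#' @param pAvoid Named per-sound avoidance probabilities.
#' @param seed Integer seed or `NULL`.
#' @return `data.frame` with columns `animal_id`, `day`, `sound`,
#'   `nosepoked`.
#' @export
simulateAudioboxVisits <- function(nAnimals = 6L, visitsPerDay = 10L,
                                   nDays = 4L,
                                   pAvoid = c(safe = 0.3, novel1 = 0.35,
                                              novel2 = 0.6, novel3 = 0.8,
                                              cond = 0.9),
                                   seed = NULL) {
  withSeed(seed, {
    grid <- expand.grid(animal = seq_len(nAnimals), day = seq_len(nDays),
                        sound = names(pAvoid), visit = seq_len(visitsPerDay),
                        stringsAsFactors = FALSE)
    data.frame(animal_id = sprintf("a%02d", grid$animal), day = grid$day,
               sound = grid$sound,
               nosepoked = stats::runif(nrow(grid)) >=
                 pAvoid[grid$sound])
  })
}
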