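# Shared fixture builders: everything is generated in code at test time.

# One scored presentation epoch through the full pipeline.
quickEpoch <- function(state = "NREM", sound = "conditioned",
                       profile = defaultProfiles("learner"), seed = 1) {
  sim <- simulatePresentationEpoch(state, sound, profile, seed = seed)
  extractEpochPower(sim$rec, sim$onsetS, state, soundType = sound)
}

# Long table of null epochs from one multi-presentation session per animal,
# with randomized presentation order (as in the experimental protocol).
nullCohortTable <- function(nAnimals = 6, perSound = 7,
                            sounds = c("conditioned", "post_control",
                                       "pre_control"),
                            state = "NREM", seed = 1, fs = 200) {
  eps <- list()
  withSeed(seed, {
    for (a in seq_len(nAnimals)) {
      sq <- sample(rep(sounds, each = perSound))
      sess <- simulatePresentationSession(state, sq, nullProfiles(),
                                          seed = seed * 1000 + a, fs = fs)
      for (i in seq_along(sq)) {
        eps[[length(eps) + 1L]] <- extractEpochPower(
          sess$rec, sess$onsets[i], state, soundType = sq[i],
          animalId = sprintf("a%d", a),
          sessionId = sprintf("a%d_s%d", a, i))
      }
    }
  })
  epochPowerTable(eps)
}

# Hand-built EpochPower with a flat normalized profile equal to `level`
# outside block 1 (block 1 is identically 1).
flatEpoch <- function(level, animalId, sessionId, sound = "s",
                      state = "NREM", day = 1L) {
  vals <- c(rep(1, 8), rep(level, 16))
  methods::new("EpochPower", values = vals, normalized = vals,
               band = "delta", state = state, soundType = sound,
               animalId = animalId, sessionId = sessionId,
               day = as.integer(day), excluded = FALSE)
}
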