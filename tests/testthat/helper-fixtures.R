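# Shared small fixtures, generated in code at test time.

small_design <- function(n_participants = 2, n_repetitions = 2,
                         tasks = c("reach_eye", "tray_lift"),
                         conditions = default_conditions()[c("healthy", "trunk_lean")]) {
  study_design(n_participants = n_participants, tasks = tasks,
               conditions = conditions, n_repetitions = n_repetitions)
}

fixture_profile <- function(participant = 1, seed = 42) {
  participant_profile(participant, seed)
}

fixture_trajectory <- function(condition = "trunk_lean", task = "reach_eye",
                               n_repetitions = 3, seed = 7, participant = 1) {
  synthesize_trajectory(task, default_conditions()[[condition]],
                        fixture_profile(participant), n_repetitions, seed)
}

# A tiny linearly-structured frame problem: healthy features cluster near
# 0, compensatory near 1, on the first feature; the rest are noise.
fixture_clusters <- function(n = 60, seed = 1, sep = 1) {
  set.seed(seed)
  nf <- 40L
  X <- matrix(runif(2 * n * nf, 0, 0.2), 2 * n, nf,
              dimnames = list(NULL, feature_names()))
  X[seq_len(n), 1] <- runif(n, 0, 0.2)            # healthy low
  X[n + seq_len(n), 1] <- runif(n, sep, sep + 0.2) # compensatory high
  y <- rep(c("healthy", "compensatory"), each = n)
  list(x = X, y = y)
}
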