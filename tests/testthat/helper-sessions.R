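# Shared fixture builders. Everything is generated in code; no files.

# Manual trial table from vectors, with dyad_decision defaulting to the
# nominated member's own choice (the generator's arbitration rule).
make_trials <- function(c1, c2, correct_interval,
                        delta_c = ifelse(correct_interval == 2L, 0.07, -0.07),
                        nominated = rep(1L, length(c1)),
                        dyad_decision = NULL) {
  n <- length(c1)
  choice1 <- ifelse(c1 > 0, 2L, 1L)
  choice2 <- ifelse(c2 > 0, 2L, 1L)
  if (is.null(dyad_decision)) {
    own <- ifelse(nominated == 1L, choice1, choice2)
    dyad_decision <- ifelse(choice1 == choice2, choice1, own)
  }
  data.frame(trial_index = 0:(n - 1L), delta_c = delta_c,
             c1 = as.integer(c1), c2 = as.integer(c2),
             correct_interval = as.integer(correct_interval),
             nominated = as.integer(nominated),
             dyad_decision = as.integer(dyad_decision))
}

default_session <- function(seed, esc1 = 0, esc2 = 0,
                            sigma1 = 0.06, sigma2 = 0.09) {
  simulate_session(session_config(
    members = list(observer_params(sigma = sigma1, escalation_rate = esc1),
                   observer_params(sigma = sigma2, escalation_rate = esc2)),
    seed = seed))
}

# Independent re-implementation of the confidence-following heuristic used
# as the oracle for the alpha = 0 reduction: on each trial take the interval
# of the member with the larger |transformed confidence|; equal-magnitude
# disagreements are resolved by the provided uniform draws (one slot per
# trial, < 0.5 -> interval 1). Written from the policy definition, not by
# calling the learner.
heuristic_decisions <- function(trials, tie_draws) {
  t1 <- pmin(abs(trials$c1), 4L)
  t2 <- pmin(abs(trials$c2), 4L)
  i1 <- ifelse(trials$c1 > 0, 2L, 1L)
  i2 <- ifelse(trials$c2 > 0, 2L, 1L)
  out <- integer(nrow(trials))
  for (k in seq_len(nrow(trials))) {
    out[k] <- if (i1[k] == i2[k]) i1[k]
    else if (t1[k] > t2[k]) i1[k]
    else if (t2[k] > t1[k]) i2[k]
    else if (tie_draws[k] < 0.5) 1L else 2L
  }
  out
}

# Trials where equal-magnitude disagreements (random tie-breaks) never
# occur: bump member 1's magnitude where needed so the heuristic is fully
# deterministic.
session_without_ties <- function(seed) {
  tr <- default_session(seed)
  disagree <- sign(tr$c1) != sign(tr$c2)
  tie <- disagree & pmin(abs(tr$c1), 4) == pmin(abs(tr$c2), 4)
  bump <- tie & abs(tr$c1) < 4  # bumping within 1..4 changes the collapsed magnitude
  tr$c1[bump] <- as.integer(sign(tr$c1[bump]) * (abs(tr$c1[bump]) + 1L))
  drop <- tie & !bump
  tr <- tr[!drop, , drop = FALSE]
  tr$trial_index <- 0:(nrow(tr) - 1L)
  # rebuild the joint decision under the default arbitration
  choice1 <- ifelse(tr$c1 > 0, 2L, 1L)
  choice2 <- ifelse(tr$c2 > 0, 2L, 1L)
  own <- ifelse(tr$nominated == 1L, choice1, choice2)
  tr$dyad_decision <- ifelse(choice1 == choice2, choice1, own)
  tr
}
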