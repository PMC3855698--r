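#' Collapse the confidence scale for the learner's state space
#'
#' The raw signed confidence alphabet has 10 values (-5..-1, 1..5), giving a
#' 10 x 10 = 100-state space for a confidence pair — too large for a
#' 256-trial session. The learner therefore relabels magnitudes 5 as 4
#' (signs preserved), reducing each member's alphabet to 8 values and the
#' pair space to 64 states.
#'
#' @param conf Signed confidence(s) in `{-5..-1, 1..5}`.
#' @return Integer vector of transformed confidences in `{-4..-1, 1..4}`.
#' @export
#' @examples
#' transform_confidence(c(-5, -1, 1, 5))  # -4 -1  1  4
transform_confidence <- function(conf) {
  assert_confidence(conf)
  as.integer(sign(conf) * pmin(abs(conf), 4L))
}

#' Transformed confidence-pair state
#'
#' Applies [transform_confidence()] to both members' signed confidences.
#' Vectorized; one row per trial.
#'
#' @param c1,c2 Signed confidences of members 1 and 2.
#' @return A `data.frame` with integer columns `tc1`, `tc2`.
#' @export
#' @examples
#' transform_state(5, -3)  # tc1 = 4, tc2 = -3
transform_state <- function(c1, c2) {
  if (length(c1) != length(c2))
    stop("`c1` and `c2` must have equal length", call. = FALSE)
  data.frame(tc1 = transform_confidence(c1), tc2 = transform_confidence(c2))
}

# Map a transformed confidence in {-4..-1, 1..4} to an index 1..8.
tc_index <- function(tc) ifelse(tc < 0L, tc + 5L, tc + 4L)

# Map a transformed state (tc1, tc2) to an index in 1..64.
state_index <- function(tc1, tc2) (tc_index(tc1) - 1L) * 8L + tc_index(tc2)

state_labels <- function() {
  tc <- c(-4:-1, 1:4)
  as.vector(outer(tc, tc, function(a, b) sprintf("(%+d,%+d)", a, b)))
}

#' Create an empty action-value table
#'
#' A tabular Q function over the 64 reduced confidence-pair states and two
#' actions (joint decision = interval 1 or 2). All values start at 0; with
#' rewards in `{-1, +1}` and a learning rate in `[0, 1]` every value stays
#' in `[-1, 1]`. Visit counts are tracked per (state, action) pair.
#'
#' @return An object of class `q_table`: list with a 64 x 2 numeric matrix
#'   `q` and a 64 x 2 integer matrix `visits`, rows labelled by state.
#' @export
q_table <- function() {
  dn <- list(state_labels(), c("interval1", "interval2"))
  structure(list(q = matrix(0, 64L, 2L, dimnames = dn),
                 visits = matrix(0L, 64L, 2L, dimnames = dn)),
            class = "q_table")
}

#' @export
print.q_table <- function(x, ...) {
  nv <- sum(x$visits > 0L)
  cat(sprintf("<q_table> 64 states x 2 actions; %d visited pairs; Q range [%.3g, %.3g]\n",
              nv, min(x$q), max(x$q)))
  invisible(x)
}

#' Serialise a Q table to a long data frame
#'
#' @param x A [q_table()].
#' @param ... Unused.
#' @return `data.frame` with columns `tc1`, `tc2`, `action`, `q`, `visits`.
#' @export
as.data.frame.q_table <- function(x, ...) {
  tc <- c(-4:-1, 1:4)
  grid <- expand.grid(tc2 = tc, tc1 = tc, action = c(1L, 2L),
                      KEEP.OUT.ATTRS = FALSE)
  idx <- state_index(grid$tc1, grid$tc2)
  data.frame(tc1 = grid$tc1, tc2 = grid$tc2, action = grid$action,
             q = x$q[cbind(idx, grid$action)],
             visits = x$visits[cbind(idx, grid$action)])
}

#' Single-step temporal-difference update
#'
#' The prediction error is `delta = reward - q_before` and the updated value
#' is `q_after = q_before + alpha * delta`. Only the visited (state, action)
#' pair changes; this helper computes the arithmetic for one such pair.
#'
#' @param q_before Current value of the visited (state, action) pair.
#' @param reward Trial feedback: +1 (correct) or -1 (incorrect).
#' @param alpha Learning rate in `[0, 1]`.
#' @return An object of class `td_update` with fields `q_before`, `reward`,
#'   `alpha`, `delta` (prediction error) and `q_after`.
#' @export
#' @examples
#' td_update(0, +1, 0.5)    # delta = 1,    q_after = 0.5
#' td_update(0.5, -1, 0.1)  # delta = -1.5, q_after = 0.35
td_update <- function(q_before, reward, alpha) {
  if (!is_number(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!is_number(q_before))
    stop("`q_before` must be a single finite number", call. = FALSE)
  if (!(is_number(reward) && reward %in% c(-1, 1)))
    stop("`reward` must be -1 or +1", call. = FALSE)
  delta <- reward - q_before
  structure(list(q_before = q_before, reward = reward, alpha = alpha,
                 delta = delta, q_after = q_before + alpha * delta),
            class = "td_update")
}

#' @export
print.td_update <- function(x, ...) {
  cat(sprintf("<td_update> q %.4g -> %.4g (r=%+d, alpha=%.3g, delta=%.4g)\n",
              x$q_before, x$q_after, x$reward, x$alpha, x$delta))
  invisible(x)
}

# Confidence-following preference for a transformed state: the interval
# indicated by the member with the larger |transformed confidence|; 0 marks
# an equal-magnitude disagreement that needs a random tie-break.
confidence_preference_code <- function(tc1, tc2) {
  i1 <- interval_of(tc1)
  i2 <- interval_of(tc2)
  ifelse(abs(tc1) > abs(tc2), i1,
         ifelse(abs(tc2) > abs(tc1), i2,
                ifelse(i1 == i2, i1, 0L)))
}

#' Greedy action over a confidence-pair state
#'
#' Returns the action with the larger Q value for the state. Ties (including
#' every first occurrence of a state, where both values are still 0) are
#' broken by the confidence-following rule: take the interval indicated by
#' the member with the larger absolute transformed confidence; if the two
#' magnitudes are equal and the members disagree, choose uniformly at random
#' (from the current global RNG stream — seed beforehand for
#' reproducibility).
#'
#' @param q A [q_table()].
#' @param tc1,tc2 Transformed confidences of the state (see
#'   [transform_state()]).
#' @return Action 1 or 2.
#' @export
greedy_action <- function(q, tc1, tc2) {
  if (!inherits(q, "q_table")) stop("`q` must be a q_table", call. = FALSE)
  if (!all(c(tc1, tc2) %in% c(-4:-1, 1:4)))
    stop("state confidences must be transformed values in {-4..-1, 1..4}",
         call. = FALSE)
  s <- state_index(tc1, tc2)
  q1 <- q$q[s, 1L]
  q2 <- q$q[s, 2L]
  if (q1 > q2) return(1L)
  if (q2 > q1) return(2L)
  pref <- confidence_preference_code(tc1, tc2)
  if (pref != 0L) return(as.integer(pref))
  if (runif(1) < 0.5) 1L else 2L
}

# Precompute per-trial integer codes used by the episode inner loop.
prep_episode <- function(trials) {
  validate_trials(trials)
  tc1 <- transform_confidence(trials$c1)
  tc2 <- transform_confidence(trials$c2)
  choice1 <- interval_of(trials$c1)
  choice2 <- interval_of(trials$c2)
  list(n = nrow(trials),
       sid = state_index(tc1, tc2),
       tc1 = tc1, tc2 = tc2,
       choice1 = choice1, choice2 = choice2,
       agree = choice1 == choice2,
       pref = confidence_preference_code(tc1, tc2),
       correct = as.integer(trials$correct_interval),
       dyad = as.integer(trials$dyad_decision))
}

# Lean episode core shared by run_episode and the grid-search fitters.
# Returns executed actions, greedy predictions, rewards and the full update
# audit. `tie_draws` is a vector of uniforms consumed on equal-magnitude
# disagreement ties (one slot per trial, used only when needed).
run_core <- function(prep, alpha, tie_draws, forced, update_on_agreement) {
  qv <- matrix(0, 64L, 2L)
  visits <- matrix(0L, 64L, 2L)
  n <- prep$n
  pred <- integer(n); act <- integer(n); rew <- integer(n)
  pe <- rep(NA_real_, n); qb <- numeric(n); qa <- numeric(n)
  for (t in seq_len(n)) {
    s <- prep$sid[t]
    q1 <- qv[s, 1L]; q2 <- qv[s, 2L]
    if (q1 > q2) g <- 1L
    else if (q2 > q1) g <- 2L
    else {
      g <- prep$pref[t]
      if (g == 0L) g <- if (tie_draws[t] < 0.5) 1L else 2L
    }
    pred[t] <- g
    a <- if (forced) prep$dyad[t] else if (prep$agree[t]) prep$choice1[t] else g
    act[t] <- a
    r <- if (a == prep$correct[t]) 1L else -1L
    rew[t] <- r
    q0 <- qv[s, a]
    qb[t] <- q0
    if (update_on_agreement || !prep$agree[t]) {
      d <- r - q0
      qv[s, a] <- q0 + alpha * d
      visits[s, a] <- visits[s, a] + 1L
      pe[t] <- d
    }
    qa[t] <- qv[s, a]
  }
  list(prediction = pred, action = act, reward = rew, pe = pe,
       q_before = qb, q_after = qa, q = qv, visits = visits)
}

#' Run the TD learner over one ordered session
#'
#' Replays a session trial by trial. On each trial the state is the
#' transformed confidence pair; the greedy prediction (with
#' confidence-following tie-break) is recorded; the *executed* action is,
#' in `"free"` mode, the agreed interval on agreement trials and the greedy
#' prediction on disagreement trials, and in `"forced"` mode the empirical
#' `dyad_decision` on every trial (used by the similarity objective: the
#' learner experiences what the humans did, while its greedy prediction is
#' still recorded for scoring). Reward is +1 if the executed action matches
#' `correct_interval` and -1 otherwise, and the TD update is applied to the
#' executed (state, action) pair. Q starts at zero.
#'
#' @param trials Trial table ordered by `trial_index` (see
#'   [simulate_session()] for the schema).
#' @param alpha Learning rate in `[0, 1]`.
#' @param mode `"free"` or `"forced"`.
#' @param seed Optional integer seed for the equal-magnitude tie-break
#'   draws; if `NULL` the current global RNG stream is used.
#' @param update_on_agreement Update Q on agreement trials too (default
#'   TRUE). Setting FALSE restricts learning to disagreement trials — a
#'   sensitivity-analysis switch.
#' @return An object of class `agent_trace`: `trace` (per-trial data.frame
#'   with state, prediction, executed action, reward, prediction error and
#'   Q audit), `q_table` (final [q_table()]), `cumulative_reward`, `alpha`,
#'   `mode`.
#' @export
#' @examples
#' trials <- simulate_session(session_config(seed = 3))
#' tr <- run_episode(trials, alpha = 0.2, seed = 1)
#' tr$cumulative_reward
run_episode <- function(trials, alpha, mode = c("free", "forced"),
                        seed = NULL, update_on_agreement = TRUE) {
  mode <- match.arg(mode)
  if (!is_number(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  prep <- prep_episode(trials)
  if (is.unsorted(trials$trial_index))
    stop("`trials` must be ordered by trial_index", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tie_draws <- runif(prep$n)
  res <- run_core(prep, alpha, tie_draws, forced = mode == "forced",
                  update_on_agreement = update_on_agreement)
  qt <- q_table()
  qt$q[] <- res$q
  qt$visits[] <- res$visits
  trace <- data.frame(trial_index = trials$trial_index,
                      tc1 = prep$tc1, tc2 = prep$tc2,
                      prediction = res$prediction, action = res$action,
                      reward = res$reward,
                      q_before = res$q_before, q_after = res$q_after,
                      prediction_error = res$pe, alpha = alpha)
  structure(list(trace = trace, q_table = qt,
                 cumulative_reward = sum(res$reward),
                 alpha = alpha, mode = mode),
            class = "agent_trace")
}

#' @export
print.agent_trace <- function(x, ...) {
  cat(sprintf("<agent_trace> %d trials, mode '%s', alpha=%.3g, cumulative reward %+d\n",
              nrow(x$trace), x$mode, x$alpha, x$cumulative_reward))
  invisible(x)
}
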