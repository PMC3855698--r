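test_that("state transform collapses magnitudes 4 and 5, keeps signs", {
  expect_identical(transform_state(5, -3), data.frame(tc1 = 4L, tc2 = -3L))
  expect_identical(transform_state(1, -1), data.frame(tc1 = 1L, tc2 = -1L))
  expect_identical(transform_confidence(c(-5, -4, -1, 1, 4, 5)),
                   c(-4L, -4L, -1L, 1L, 4L, 4L))
  expect_error(transform_confidence(0), "confidence")
  expect_error(transform_confidence(6), "confidence")
})

test_that("the 10x10 raw grid maps onto exactly 64 states", {
  grid <- expand.grid(c1 = dyadRL:::confidence_alphabet(),
                      c2 = dyadRL:::confidence_alphabet())
  expect_identical(nrow(grid), 100L)
  st <- transform_state(grid$c1, grid$c2)
  ids <- dyadRL:::state_index(st$tc1, st$tc2)
  expect_identical(length(unique(ids)), 64L)
  expect_true(all(ids %in% 1:64))
})

test_that("td_update implements the prediction-error arithmetic", {
  u <- td_update(0, +1, 0.5)
  expect_equal(u$delta, 1)
  expect_equal(u$q_after, 0.5)
  u2 <- td_update(0.5, -1, 0.1)
  expect_equal(u2$delta, -1.5)
  expect_equal(u2$q_after, 0.35)
  # alpha = 0 is the identity for any reward
  for (r in c(-1, 1)) expect_equal(td_update(0.3, r, 0)$q_after, 0.3)
  expect_error(td_update(0, 1, 1.5), "alpha")
  expect_error(td_update(0, 1, -0.1), "alpha")
  expect_error(td_update(0, 0.5, 0.5), "reward")
})

test_that("Q stays in [-1, 1] under any admissible update stream", {
  set.seed(11)
  for (rep in 1:30) {
    alpha <- runif(1)
    q <- 0
    for (k in 1:200) {
      q <- td_update(q, sample(c(-1, 1), 1), alpha)$q_after
      expect_true(abs(q) <= 1)
    }
  }
})

test_that("Q tracks 2p - 1 for a stationary Bernoulli reward", {
  # with constant alpha, Q is an exponentially weighted reward average whose
  # expectation converges to E[r] = 2p - 1; average the trajectory tail
  for (p in c(0.2, 0.8)) {
    set.seed(round(1000 * p))
    alpha <- 0.1
    q <- 0
    tail_vals <- numeric(0)
    for (k in 1:10000) {
      r <- if (runif(1) < p) 1 else -1
      q <- q + alpha * (r - q)
      if (k > 5000) tail_vals <- c(tail_vals, q)
    }
    expect_equal(mean(tail_vals), 2 * p - 1, tolerance = 0.05)
  }
})

test_that("greedy_action is argmax with confidence tie-breaking", {
  q <- q_table()
  sid <- dyadRL:::state_index(2L, -3L)
  q$q[sid, 1] <- 0.2
  q$q[sid, 2] <- -0.1
  expect_identical(greedy_action(q, 2L, -3L), 1L)
  q$q[sid, ] <- c(-0.5, 0.1)
  expect_identical(greedy_action(q, 2L, -3L), 2L)
  # first occurrence (all zeros): follow the higher |confidence|
  q0 <- q_table()
  expect_identical(greedy_action(q0, 2L, -3L), 1L)  # |-3| > |+2|, sign -> 1st
  expect_identical(greedy_action(q0, 3L, -2L), 2L)
  expect_error(greedy_action(q0, 5L, 1L), "transformed")
})

test_that("equal-magnitude tie-break is a fair seeded coin", {
  q0 <- q_table()
  set.seed(123)
  draws <- vapply(1:10000, function(i) greedy_action(q0, 2L, -2L), integer(1))
  expect_equal(mean(draws == 2L), 0.5, tolerance = 0.02)
  # and reproducible under the same seed
  set.seed(123)
  draws2 <- vapply(1:10000, function(i) greedy_action(q0, 2L, -2L), integer(1))
  expect_identical(draws, draws2)
})

test_that("all-agreement sessions are forced to the common choice", {
  set.seed(4)
  c1 <- sample(c(-3L, -2L, 2L, 3L), 60, replace = TRUE)
  tr <- make_trials(c1 = c1, c2 = c1,
                    correct_interval = sample(1:2, 60, replace = TRUE))
  for (alpha in c(0, 0.3, 1)) {
    out <- run_episode(tr, alpha, mode = "free", seed = 9)
    expect_identical(out$trace$action, ifelse(c1 > 0, 2L, 1L))
  }
})

test_that("alpha = 0 in free mode reduces to the confidence heuristic", {
  tr <- default_session(55)
  out <- run_episode(tr, alpha = 0, mode = "free", seed = 777)
  set.seed(777)
  draws <- runif(nrow(tr))  # same tie stream the learner consumed
  expect_identical(out$trace$action, heuristic_decisions(tr, draws))
})

test_that("repeated rewarded visits follow the closed-form recursion", {
  k <- 12L
  tr <- make_trials(c1 = rep(3L, k), c2 = rep(3L, k),
                    correct_interval = rep(2L, k))
  out <- run_episode(tr, alpha = 0.5, mode = "free", seed = 1)
  expect_equal(out$trace$q_after, 1 - 2^-(1:k), tolerance = 1e-12)
  expect_identical(out$cumulative_reward, k)
})

test_that("only the visited (state, action) pair changes", {
  tr <- make_trials(c1 = c(3L, -2L, 3L), c2 = c(3L, -2L, 3L),
                    correct_interval = c(2L, 1L, 2L))
  out <- run_episode(tr, alpha = 0.4, mode = "free", seed = 2)
  qt <- out$q_table
  touched <- which(qt$visits > 0L)
  expect_identical(length(touched), 2L)         # two distinct (s, a) pairs
  expect_true(all(qt$q[qt$visits == 0L] == 0))  # untouched entries exactly 0
  # forced mode executes the empirical decision, still records predictions
  tr2 <- default_session(66)
  outf <- run_episode(tr2, alpha = 0.2, mode = "forced", seed = 3)
  expect_identical(outf$trace$action, tr2$dyad_decision)
  expect_true(all(outf$trace$prediction %in% 1:2))
})

test_that("update_on_agreement = FALSE restricts learning to disagreements", {
  tr <- default_session(77)
  out <- run_episode(tr, alpha = 0.5, mode = "free", seed = 5,
                     update_on_agreement = FALSE)
  agree <- sign(tr$c1) == sign(tr$c2)
  expect_identical(sum(out$q_table$visits), sum(!agree))
  expect_true(all(is.na(out$trace$prediction_error[agree])))
})

test_that("agent trace serialises and q_table dumps to long form", {
  tr <- default_session(88)
  out <- run_episode(tr, alpha = 0.3, seed = 6)
  df <- as.data.frame(out$q_table)
  expect_identical(nrow(df), 128L)
  expect_identical(sum(df$visits), nrow(tr))
  expect_identical(nrow(out$trace), nrow(tr))
})
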