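test_that("split_bins makes contiguous near-equal bins, remainder first", {
  tr9 <- default_session(1)[1:9, ]
  expect_identical(attr(split_bins(tr9, 3), "sizes"), c(3L, 3L, 3L))
  tr <- default_session(1)
  b <- split_bins(tr, 3)
  expect_identical(attr(b, "sizes"), c(86L, 85L, 85L))
  expect_identical(unlist(b, use.names = FALSE), 1:256)  # concatenation restores
  expect_identical(attr(split_bins(tr, 1), "sizes"), 256L)
  expect_identical(attr(split_bins(tr9, 4), "sizes"), c(3L, 2L, 2L, 2L))
  expect_error(split_bins(tr9, 10), "exceeds")
  expect_error(split_bins(tr9, 0), "positive")
})

test_that("alpha_grid = {0} reproduces the confidence heuristic (both objectives)", {
  tr <- session_without_ties(101)  # deterministic heuristic
  oracle <- heuristic_decisions(tr, tie_draws = rep(0, nrow(tr)))
  acc <- fit_max_accuracy(tr, alpha_grid = 0, seed = 3)
  expect_identical(acc$decisions, oracle)
  # max similarity at alpha 0: aggregate decision is the nominated member's
  # greedy prediction, which with Q = 0 is the same heuristic
  sim <- fit_max_similarity(tr, alpha_grid = 0, seed = 3)
  expect_identical(sim$decisions, oracle)
  # and if the empirical decisions *are* the heuristic, similarity is 1
  tr2 <- tr
  tr2$dyad_decision <- oracle
  sim2 <- fit_max_similarity(tr2, alpha_grid = 0, seed = 3)
  expect_true(all(sim2$bins$similarity[!sim2$bins$fallback] == 1))
  expect_true(all(sim2$similarity == 1))
})

test_that("a deterministically correct confident member dominates the model", {
  set.seed(12)
  n <- 256L
  correct <- sample(1:2, n, replace = TRUE)
  c2 <- ifelse(correct == 2L, 4L, -4L)            # always right, confident
  c1 <- sample(c(-1L, 1L), n, replace = TRUE)      # guessing, unconfident
  tr <- make_trials(c1 = c1, c2 = c2, correct_interval = correct,
                    nominated = sample(1:2, n, replace = TRUE))
  res <- fit_max_accuracy(tr, alpha_grid = seq(0, 1, by = 0.1), seed = 4)
  disagree <- sign(tr$c1) != sign(tr$c2)
  expect_identical(res$decisions[disagree],
                   ifelse(c2 > 0, 2L, 1L)[disagree])
  # model decisions == member 2's decisions everywhere -> identical fits
  expect_equal(res$model_fit$slope / res$member_fits[[2]]$slope, 1,
               tolerance = 1e-6)
})

test_that("similarity is a proportion and winning objectives are monotone in the grid", {
  tr <- default_session(202)
  small <- fit_max_accuracy(tr, alpha_grid = c(0, 0.5), seed = 5)
  large <- fit_max_accuracy(tr, alpha_grid = c(0, 0.25, 0.5, 0.75, 1), seed = 5)
  expect_true(all(large$bins$slope >= small$bins$slope - 1e-12))
  sim <- fit_max_similarity(tr, alpha_grid = seq(0, 1, by = 0.25), seed = 5)
  ok <- !sim$bins$fallback
  expect_true(all(sim$bins$similarity[ok] >= 0 & sim$bins$similarity[ok] <= 1))
  sim_large <- fit_max_similarity(tr, alpha_grid = seq(0, 1, by = 0.125),
                                  seed = 5)
  agg <- function(x) tapply(x$bins$similarity[!x$bins$fallback],
                            paste(x$bins$member, x$bins$bin)[!x$bins$fallback],
                            identity)
  expect_true(all(unlist(agg(sim_large)) >= unlist(agg(sim)) - 1e-12))
})

test_that("learning restarts are isolated per bin", {
  tr <- default_session(303)
  res <- fit_max_accuracy(tr, alpha_grid = c(0.1, 0.4), seed = 6)
  bins <- split_bins(tr, 3)
  # re-running each winning (bin, alpha) standalone with the same derived
  # tie seed reproduces that bin's collapsed decisions: Q was all-zero at
  # the bin start and later bins cannot reach back
  for (b in seq_along(bins)) {
    sub <- tr[bins[[b]], ]
    sub$trial_index <- 0:(nrow(sub) - 1L)
    j <- match(res$bins$alpha[b], c(0.1, 0.4))
    standalone <- run_episode(sub, res$bins$alpha[b], mode = "free",
                              seed = dyadRL:::derive_seed(6, 1L, b, j))
    expect_identical(standalone$trace$action, res$decisions[bins[[b]]])
  }
})

test_that("max-similarity recovers a planted TD decision policy", {
  # empirical decisions generated by our own free-mode agent at alpha*;
  # forced-mode training then reproduces the generator's value trajectory
  # at alpha = alpha*, so similarity there is exactly 1
  tr <- session_without_ties(404)
  gen <- run_episode(tr, alpha = 0.3, mode = "free", seed = 41)
  tr$dyad_decision <- gen$trace$action
  fit <- fit_max_similarity(tr, alpha_grid = c(0.05, 0.3, 0.8), n_bins = 1,
                            seed = 42)
  # similarity at alpha* is exactly 1; the smallest-alpha tie-break can only
  # move the winner left along a similarity-1 plateau, never right
  expect_true(all(fit$bins$similarity == 1))
  expect_true(all(fit$bins$alpha <= 0.3 + 1e-12))
})

test_that("evaluate_dyad bundles empirical and model quantities coherently", {
  tr <- session_without_ties(505)
  oracle <- heuristic_decisions(tr, rep(0, nrow(tr)))
  tr$dyad_decision <- oracle
  ev <- evaluate_dyad(tr, objectives = c("max_accuracy", "max_similarity"),
                      alpha_grid = 0, seed = 7)
  # model decisions identical to empirical decisions -> concordance 1
  for (m in ev$models) {
    expect_identical(m$decisions, oracle)
    expect_equal(m$concordance, 1, tolerance = 1e-9)
  }
  expect_equal(ev$cb_dyad, ev$dyad$slope / max(ev$member1$slope,
                                               ev$member2$slope))
  expect_equal(ev$log_cb_dyad, log(ev$cb_dyad))
})

test_that("identical members give empirical CB centred near 1", {
  logs <- vapply(1:20, function(i) {
    tr <- default_session(9000 + i, sigma1 = 0.07, sigma2 = 0.07)
    emp <- dyadRL:::empirical_fits(tr, 10)
    log(emp$dyad$slope / emp$s_max)
  }, numeric(1))
  expect_lt(abs(mean(logs)), 0.1)
})

test_that("single-bin and three-bin fits differ only in the restart schedule", {
  tr <- default_session(606)
  one <- fit_max_accuracy(tr, alpha_grid = c(0, 0.5), n_bins = 1, seed = 8)
  three <- fit_max_accuracy(tr, alpha_grid = c(0, 0.5), n_bins = 3, seed = 8)
  expect_identical(length(one$decisions), length(three$decisions))
  expect_identical(nrow(one$bins), 1L)
  expect_identical(nrow(three$bins), 3L)
})

test_that("fallback alpha is used when a member is never nominated in a bin", {
  set.seed(13)
  n <- 60L
  c1 <- sample(c(-3L, -2L, 2L, 3L), n, replace = TRUE)
  c2 <- sample(c(-4L, -1L, 1L, 4L), n, replace = TRUE)
  tr <- make_trials(c1 = c1, c2 = c2,
                    correct_interval = sample(1:2, n, replace = TRUE),
                    nominated = rep(2L, n))  # member 1 never nominated
  fit <- fit_max_similarity(tr, alpha_grid = c(0, 0.5, 1), n_bins = 3,
                            seed = 9)
  m1 <- fit$bins[fit$bins$member == 1, ]
  expect_true(all(m1$fallback))
  expect_true(all(m1$alpha == 0))  # smallest grid alpha propagates
  expect_true(any(grepl("never nominated", fit$notes)))
})
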