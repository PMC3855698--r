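#' Split a session into contiguous, near-equal time bins
#'
#' Confidence reporting is non-stationary over a session, so the fitters
#' restart learning in each of `n_bins` contiguous segments instead of
#' tuning the learning rate continuously. Segment sizes differ by at most
#' one; remainder trials go to the earliest bins (256 trials, 3 bins ->
#' sizes 86, 85, 85). `n_bins = 1` models the whole session as one run.
#'
#' @param trials Ordered trial table.
#' @param n_bins Number of bins (default 3).
#' @return Object of class `bin_split`: list of row-index vectors, with a
#'   `sizes` attribute. Concatenating the indices restores the session
#'   order.
#' @export
#' @examples
#' attr(split_bins(simulate_session(session_config(seed = 1))), "sizes")
split_bins <- function(trials, n_bins = 3) {
  n <- nrow(trials)
  if (!is_count(n_bins)) stop("`n_bins` must be a positive integer", call. = FALSE)
  if (n_bins > n) stop("`n_bins` exceeds the number of trials", call. = FALSE)
  n_bins <- as.integer(n_bins)
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_len(n_bins), function(b) seq.int(starts[b], ends[b]))
  structure(out, sizes = sizes, class = "bin_split")
}

# Psychometric fit that degrades to a flagged zero-slope fit instead of
# erroring (used for per-bin model decisions, where e.g. a bin might contain
# a single response category).
safe_slope_fit <- function(delta_c, chose_second, slope_ceiling = Inf) {
  tryCatch(fit_psychometric(delta_c, chose_second, slope_ceiling),
           error = function(e) {
             structure(list(bias = NA_real_, sigma = NA_real_, slope = 0,
                            n_trials = length(delta_c), converged = FALSE,
                            capped = FALSE),
                       class = "psychometric_fit")
           })
}

# Empirical fits shared by both objectives: each member (from the sign of
# their confidence) and the dyad (from dyad_decision), plus the slope cap
# used for degenerate model fits.
empirical_fits <- function(trials, slope_ceiling_factor) {
  m1 <- fit_psychometric(trials$delta_c, trials$c1 > 0)
  m2 <- fit_psychometric(trials$delta_c, trials$c2 > 0)
  s_max <- max(m1$slope, m2$slope)
  if (s_max <= 0)
    stop("both members have non-positive fitted slopes; cannot form collective-benefit ratios",
         call. = FALSE)
  ceiling <- slope_ceiling_factor * s_max
  dyad <- safe_slope_fit(trials$delta_c, trials$dyad_decision == 2L, ceiling)
  list(member1 = m1, member2 = m2, dyad = dyad, s_max = s_max,
       ceiling = ceiling)
}

new_model_result <- function(objective, bins, decisions, model_fit, emp,
                             notes, extra = list()) {
  cb_model <- if (model_fit$slope > 0) model_fit$slope / emp$s_max else NA_real_
  concordance <- if (model_fit$slope > 0 && emp$dyad$slope > 0)
    model_fit$slope / emp$dyad$slope else NA_real_
  structure(c(list(objective = objective, bins = bins, decisions = decisions,
                   model_fit = model_fit, member_fits = list(emp$member1, emp$member2),
                   dyad_fit = emp$dyad, s_max = emp$s_max,
                   cb_model = cb_model, concordance = concordance,
                   notes = notes), extra),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s> s_model=%.4g cb_model=%.4g concordance=%.4g\n",
              x$objective, x$model_fit$slope, x$cb_model, x$concordance))
  cat("  per-bin winners:\n")
  print(x$bins, row.names = FALSE)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the accuracy-maximizing TD model to a dyad session
#'
#' Treats the dyad as one learning unit. For each time bin independently,
#' every learning rate on the grid is run from a zero Q table over that
#' bin's trials (free mode: agreed interval on agreement trials, greedy on
#' disagreement trials), and the rate whose decisions yield the steepest
#' within-bin psychometric slope wins (ties go to the smallest rate). The
#' winning decision sequences of all bins are then collapsed and a single
#' psychometric function is fitted over the whole session to give the model
#' slope, the model collective benefit `s_model / s_max` and the
#' concordance `s_model / s_dyad`.
#'
#' Degenerate within-bin fits (separation at ~85 trials is possible) are
#' capped at `slope_ceiling_factor` times the steeper member's slope and
#' recorded in `notes`.
#'
#' @param trials Ordered trial table for one dyad.
#' @param alpha_grid Learning-rate grid in `[0, 1]`; default 101 equispaced
#'   points.
#' @param n_bins Learning-restart bins (default 3; 1 = whole session).
#' @param seed Seed; each (bin, alpha) cell derives its tie-break stream
#'   from it (callers give each dyad its own seed, e.g.
#'   `derive_seed(master, dyad_id)` semantics).
#' @param update_on_agreement Update Q on agreement trials (default TRUE).
#' @param slope_ceiling_factor Cap factor for degenerate fits (default 10).
#' @param score_trials Fit within-bin slopes on `"all"` trials (default;
#'   agreement trials are forced to the common choice) or on
#'   `"disagreement"` trials only.
#' @return A `model_result`: per-bin winners (`bins`), collapsed model
#'   `decisions`, overall `model_fit`, member and dyad fits, `s_max`,
#'   `cb_model`, `concordance`, `notes`.
#' @export
fit_max_accuracy <- function(trials, alpha_grid = seq(0, 1, by = 0.01),
                             n_bins = 3, seed = 1L,
                             update_on_agreement = TRUE,
                             slope_ceiling_factor = 10,
                             score_trials = c("all", "disagreement")) {
  score_trials <- match.arg(score_trials)
  check_alpha_grid(alpha_grid)
  validate_trials(trials)
  emp <- empirical_fits(trials, slope_ceiling_factor)
  bins <- split_bins(trials, n_bins)
  notes <- character(0)
  decisions <- integer(nrow(trials))
  bin_rows <- vector("list", length(bins))

  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    sub <- trials[idx, , drop = FALSE]
    prep <- prep_episode(sub)
    best <- NULL
    for (j in seq_along(alpha_grid)) {
      set.seed(derive_seed(seed, 1L, b, j))
      tie_draws <- runif(prep$n)
      res <- run_core(prep, alpha_grid[j], tie_draws, forced = FALSE,
                      update_on_agreement = update_on_agreement)
      keep <- if (score_trials == "all") rep(TRUE, prep$n) else !prep$agree
      fit <- safe_slope_fit(sub$delta_c[keep], res$action[keep] == 2L,
                            emp$ceiling)
      if (is.null(best) || fit$slope > best$slope + 1e-12) {
        best <- list(j = j, slope = fit$slope, converged = fit$converged,
                     capped = fit$capped, actions = res$action)
      }
    }
    if (!best$converged)
      notes <- c(notes, sprintf("bin %d: winning fit degenerate%s", b,
                                if (best$capped) " (slope capped)" else ""))
    decisions[idx] <- best$actions
    bin_rows[[b]] <- data.frame(bin = b, alpha = alpha_grid[best$j],
                                slope = best$slope,
                                n_trials = length(idx),
                                converged = best$converged)
  }
  model_fit <- safe_slope_fit(trials$delta_c, decisions == 2L, emp$ceiling)
  if (!model_fit$converged)
    notes <- c(notes, "overall model fit degenerate")
  new_model_result("max_accuracy", do.call(rbind, bin_rows), decisions,
                   model_fit, emp, notes)
}

check_alpha_grid <- function(alpha_grid) {
  if (!is.numeric(alpha_grid) || length(alpha_grid) < 1L ||
      any(!is.finite(alpha_grid)) || any(alpha_grid < 0 | alpha_grid > 1))
    stop("`alpha_grid` must be a nonempty numeric vector within [0, 1]",
         call. = FALSE)
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("`alpha_grid` must be strictly increasing", call. = FALSE)
  invisible(alpha_grid)
}

#' Fit the similarity-maximizing TD models to a dyad session
#'
#' Treats the dyad as two parallel decision makers. For each member a
#' separate learner is trained in forced mode (the executed action — and the
#' TD update — follow the empirical joint decision and its reward on every
#' trial), restarted per bin, and scored only on the disagreement trials of
#' that bin where the member was nominated to indicate the joint decision:
#' similarity = fraction of those trials where the greedy prediction matches
#' the empirical decision. Per bin the learning rate maximizing similarity
#' wins (ties to the smallest rate). The aggregate model decision is the
#' common choice on agreement trials and the nominated member's greedy
#' prediction (at that member's winning rate for the bin) on disagreement
#' trials; the overall slope, collective benefit and concordance are
#' computed as in [fit_max_accuracy()].
#'
#' If a member is never nominated in a bin, their rate falls back to the
#' previous bin's winner (first bin: the smallest grid rate) and the event
#' is recorded in `notes`.
#'
#' @inheritParams fit_max_accuracy
#' @param train_signal `"forced"` (default; updates follow the executed
#'   empirical action) or `"greedy"` (updates follow the learner's own
#'   greedy action — a sensitivity-analysis switch).
#' @return A `model_result`; `bins` has one row per (member, bin) with the
#'   winning rate and similarity, and `similarity` gives each member's
#'   overall matched fraction at the winning rates.
#' @export
fit_max_similarity <- function(trials, alpha_grid = seq(0, 1, by = 0.01),
                               n_bins = 3, seed = 1L,
                               update_on_agreement = TRUE,
                               slope_ceiling_factor = 10,
                               train_signal = c("forced", "greedy")) {
  train_signal <- match.arg(train_signal)
  check_alpha_grid(alpha_grid)
  validate_trials(trials)
  emp <- empirical_fits(trials, slope_ceiling_factor)
  bins <- split_bins(trials, n_bins)
  notes <- character(0)
  n <- nrow(trials)
  agree_all <- interval_of(trials$c1) == interval_of(trials$c2)
  decisions <- ifelse(agree_all, interval_of(trials$c1), NA_integer_)
  bin_rows <- list()
  matched <- c(`1` = 0L, `2` = 0L)
  scored_n <- c(`1` = 0L, `2` = 0L)

  for (m in 1:2) {
    prev_alpha_j <- 1L
    for (b in seq_along(bins)) {
      idx <- bins[[b]]
      sub <- trials[idx, , drop = FALSE]
      prep <- prep_episode(sub)
      scored <- which(!prep$agree & sub$nominated == m)
      if (length(scored) == 0L) {
        notes <- c(notes,
                   sprintf("member %d never nominated in bin %d; falling back to alpha=%.3g",
                           m, b, alpha_grid[prev_alpha_j]))
        bin_rows[[length(bin_rows) + 1L]] <-
          data.frame(member = m, bin = b, alpha = alpha_grid[prev_alpha_j],
                     similarity = NA_real_, n_scored = 0L, fallback = TRUE)
        next
      }
      best <- NULL
      for (j in seq_along(alpha_grid)) {
        set.seed(derive_seed(seed, 2L, m, b, j))
        tie_draws <- runif(prep$n)
        res <- run_core(prep, alpha_grid[j], tie_draws,
                        forced = train_signal == "forced",
                        update_on_agreement = update_on_agreement)
        sim <- mean(res$prediction[scored] == prep$dyad[scored])
        if (is.null(best) || sim > best$sim + 1e-12)
          best <- list(j = j, sim = sim, pred = res$prediction)
      }
      prev_alpha_j <- best$j
      decisions[idx[scored]] <- best$pred[scored]
      matched[m] <- matched[m] + sum(best$pred[scored] == prep$dyad[scored])
      scored_n[m] <- scored_n[m] + length(scored)
      bin_rows[[length(bin_rows) + 1L]] <-
        data.frame(member = m, bin = b, alpha = alpha_grid[best$j],
                   similarity = best$sim, n_scored = length(scored),
                   fallback = FALSE)
    }
  }
  if (anyNA(decisions))
    stop("internal error: some disagreement trials received no model decision",
         call. = FALSE)
  model_fit <- safe_slope_fit(trials$delta_c, decisions == 2L, emp$ceiling)
  if (!model_fit$converged)
    notes <- c(notes, "overall model fit degenerate")
  similarity <- ifelse(scored_n > 0, matched / scored_n, NA_real_)
  new_model_result("max_similarity", do.call(rbind, bin_rows),
                   as.integer(decisions), model_fit, emp, notes,
                   extra = list(similarity = similarity))
}

#' Evaluate one dyad: empirical performance and fitted models
#'
#' Bundles the empirical member and dyad psychometric fits, the empirical
#' collective benefit `s_dyad / s_max`, and the fitted model(s) with their
#' model collective benefits and concordances. Cohort statistics should use
#' the log-transformed ratios (returned alongside).
#'
#' @inheritParams fit_max_accuracy
#' @param objectives Character vector among `"max_accuracy"`,
#'   `"max_similarity"`.
#' @param ... Passed on to the fitters (e.g. `update_on_agreement`,
#'   `score_trials`, `train_signal`).
#' @return Object of class `dyad_evaluation`: `member1`, `member2`, `dyad`
#'   fits, `s_max`, `cb_dyad`, `log_cb_dyad`, and `models` (named list of
#'   `model_result`).
#' @export
#' @examples
#' trials <- simulate_session(session_config(seed = 11))
#' ev <- evaluate_dyad(trials, objectives = "max_accuracy",
#'                     alpha_grid = seq(0, 1, by = 0.1))
#' ev$cb_dyad; ev$models$max_accuracy$cb_model
evaluate_dyad <- function(trials,
                          objectives = c("max_accuracy", "max_similarity"),
                          alpha_grid = seq(0, 1, by = 0.01), n_bins = 3,
                          seed = 1L, slope_ceiling_factor = 10, ...) {
  objectives <- match.arg(objectives, several.ok = TRUE)
  validate_trials(trials)
  emp <- empirical_fits(trials, slope_ceiling_factor)
  cb_dyad <- if (emp$dyad$slope > 0) emp$dyad$slope / emp$s_max else NA_real_
  models <- list()
  for (obj in objectives) {
    models[[obj]] <- switch(obj,
      max_accuracy = fit_max_accuracy(trials, alpha_grid, n_bins, seed,
                                      slope_ceiling_factor = slope_ceiling_factor,
                                      ...),
      max_similarity = fit_max_similarity(trials, alpha_grid, n_bins, seed,
                                          slope_ceiling_factor = slope_ceiling_factor,
                                          ...))
  }
  structure(list(member1 = emp$member1, member2 = emp$member2,
                 dyad = emp$dyad, s_max = emp$s_max,
                 cb_dyad = cb_dyad, log_cb_dyad = log(cb_dyad),
                 models = models),
            class = "dyad_evaluation")
}

#' @export
print.dyad_evaluation <- function(x, ...) {
  cat(sprintf("<dyad_evaluation> s1=%.4g s2=%.4g s_dyad=%.4g cb_dyad=%.4g\n",
              x$member1$slope, x$member2$slope, x$dyad$slope, x$cb_dyad))
  for (m in x$models)
    cat(sprintf("  %-14s s_model=%.4g cb_model=%.4g concordance=%.4g\n",
                m$objective, m$model_fit$slope, m$cb_model, m$concordance))
  invisible(x)
}
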