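#' Mean absolute confidence per time bin for one member
#'
#' Divides the session into contiguous time bins (via [split_bins()]) and
#' returns each bin's mean absolute confidence on the raw 1-5 reporting
#' scale (the behavioural escalation analysis is deliberately performed
#' before any state-space collapse).
#'
#' @param trials Ordered trial table.
#' @param member 1 or 2.
#' @param n_bins Number of time bins (default 3).
#' @return Object of class `escalation_summary`: `member`, `M` (vector of
#'   per-bin means, each in `[1, 5]`), `n_bins`.
#' @export
#' @examples
#' tr <- simulate_session(session_config(
#'   members = list(observer_params(0.07, escalation_rate = 0.003),
#'                  observer_params(0.07, escalation_rate = 0.003)),
#'   seed = 5))
#' confidence_by_bin(tr, member = 1)$M
confidence_by_bin <- function(trials, member, n_bins = 3) {
  validate_trials(trials)
  if (!member %in% c(1L, 2L)) stop("`member` must be 1 or 2", call. = FALSE)
  conf <- abs(trials[[if (member == 1) "c1" else "c2"]])
  bins <- split_bins(trials, n_bins)
  M <- vapply(bins, function(idx) mean(conf[idx]), numeric(1))
  structure(list(member = as.integer(member), M = M,
                 n_bins = as.integer(n_bins)),
            class = "escalation_summary")
}

#' @export
print.escalation_summary <- function(x, ...) {
  cat(sprintf("<escalation_summary> member %d: M = %s (index %.4g)\n",
              x$member, paste(format(x$M, digits = 4), collapse = ", "),
              escalation_index(x)))
  invisible(x)
}

#' Escalation index: change in mean absolute confidence over the session
#'
#' Quantifies confidence escalation from the first to the last time bin.
#' The default is the relative change `(M_last - M_first) / M_first`; the
#' absolute change `M_last - M_first` is available as a variant. Either way
#' the index depends only on the first and last bins and only on
#' confidence magnitudes, so it is unit-free and invariant to interval
#' relabelling.
#'
#' @param M An `escalation_summary` or a numeric vector of per-bin mean
#'   absolute confidences (first and last entries are used).
#' @param type `"relative"` (default) or `"absolute"`.
#' @return The escalation index (scalar).
#' @export
#' @examples
#' escalation_index(c(2, 2.5, 3))                      # 0.5
#' escalation_index(c(2, 2.5, 3), type = "absolute")   # 1
escalation_index <- function(M, type = c("relative", "absolute")) {
  type <- match.arg(type)
  if (inherits(M, "escalation_summary")) M <- M$M
  if (!is.numeric(M) || length(M) < 2L || any(!is.finite(M)))
    stop("`M` must be a numeric vector of at least 2 bin means", call. = FALSE)
  m1 <- M[1L]
  m3 <- M[length(M)]
  if (type == "absolute") return(m3 - m1)
  if (m1 <= 0) stop("first-bin mean must be > 0 for the relative index",
                    call. = FALSE)
  (m3 - m1) / m1
}

#' Dyadic cumulative escalation
#'
#' The dyad-level escalation measure is the sum of the two members'
#' escalation indices (symmetric in its arguments).
#'
#' @param summary1,summary2 `escalation_summary` objects (or numeric `M`
#'   vectors) for the two members of one session.
#' @param type Passed to [escalation_index()].
#' @return Scalar dyadic escalation.
#' @export
dyad_escalation <- function(summary1, summary2,
                            type = c("relative", "absolute")) {
  type <- match.arg(type)
  escalation_index(summary1, type) + escalation_index(summary2, type)
}

#' Correlate dyadic escalation with model collective benefit
#'
#' Pearson product-moment correlation between per-dyad cumulative
#' escalation and the collective benefit obtained by the fitted model, with
#' a two-sided p value from the t distribution with `n - 2` degrees of
#' freedom. A negative r means faster confidence escalation goes with less
#' model collective benefit.
#'
#' @param dyad_escalations Numeric vector of per-dyad escalation values.
#' @param cb_models Numeric vector of per-dyad model collective benefits
#'   (same length, n >= 3).
#' @return Object of class `escalation_correlation`: `r`, `p`, `n`.
#' @export
#' @examples
#' correlate_escalation_cb(c(0.1, 0.4, 0.9, 1.2), c(1.2, 1.1, 0.95, 0.9))
correlate_escalation_cb <- function(dyad_escalations, cb_models) {
  x <- as.numeric(dyad_escalations)
  y <- as.numeric(cb_models)
  if (length(x) != length(y))
    stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 dyads", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "escalation_correlation")
}

#' @export
print.escalation_correlation <- function(x, ...) {
  cat(sprintf("<escalation_correlation> r = %.3f, p = %.4g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Escalation summary table for a cohort
#'
#' Convenience wrapper: per-bin mean absolute confidences and escalation
#' indices for both members of every session, plus the dyadic sum.
#'
#' @param sessions List of trial tables.
#' @param n_bins Number of time bins (default 3).
#' @param type Escalation-index variant (see [escalation_index()]).
#' @return `data.frame` with one row per dyad: `dyad_id`, `M1_1..M1_k`,
#'   `M2_1..M2_k`, `index1`, `index2`, `dyad_escalation`, `index_type`.
#' @export
cohort_escalation <- function(sessions, n_bins = 3,
                              type = c("relative", "absolute")) {
  type <- match.arg(type)
  rows <- lapply(seq_along(sessions), function(i) {
    s1 <- confidence_by_bin(sessions[[i]], 1, n_bins)
    s2 <- confidence_by_bin(sessions[[i]], 2, n_bins)
    row <- data.frame(dyad_id = i)
    for (b in seq_len(n_bins)) row[[sprintf("M1_%d", b)]] <- s1$M[b]
    for (b in seq_len(n_bins)) row[[sprintf("M2_%d", b)]] <- s2$M[b]
    row$index1 <- escalation_index(s1, type)
    row$index2 <- escalation_index(s2, type)
    row$dyad_escalation <- row$index1 + row$index2
    row$index_type <- type
    row
  })
  do.call(rbind, rows)
}
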