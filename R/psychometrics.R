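#' Maximum psychometric slope from the noise parameter
#'
#' For a cumulative-Gaussian psychometric function
#' `P(delta_c) = pnorm((delta_c - b) / sigma)`, the maximum slope at the
#' point of inflection is `s = 1 / (sigma * sqrt(2 * pi))` — the height of
#' the Gaussian density at its mode. Sensitivity is reported as this slope:
#' steeper means less noise.
#'
#' @param sigma Noise standard deviation in contrast units (> 0).
#' @return The slope, in 1/contrast units.
#' @export
#' @examples
#' slope_from_sigma(1)            # 0.3989...
#' slope_from_sigma(1 / sqrt(2 * pi))  # 1
slope_from_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be finite and > 0", call. = FALSE)
  1 / (sigma * sqrt(2 * pi))
}

#' Fit a cumulative-Gaussian psychometric function by probit regression
#'
#' Maximum-likelihood probit fit of `P(chose 2nd) = pnorm((delta_c - b) /
#' sigma)`: a binomial GLM with probit link on `delta_c` (IRLS, deviance
#' tolerance 1e-8, at most 100 iterations), with intercept `-b/sigma` and
#' coefficient `1/sigma`. No lapse-rate parameter is included.
#'
#' Degenerate inputs are flagged rather than fatal: a single response
#' category, perfect separation (deviance numerically zero), a
#' non-positive contrast coefficient, or IRLS non-convergence all set
#' `converged = FALSE`. For separation the implied slope diverges; it is
#' then capped at `slope_ceiling` (and `capped = TRUE`). For an
#' anti-predictive or undefined fit the slope is reported as 0.
#'
#' @param delta_c Signed contrast differences (>= 2 distinct values
#'   required).
#' @param chose_second Logical (or 0/1) vector: TRUE where the second
#'   interval was chosen.
#' @param slope_ceiling Cap applied to the slope of a non-converged fit;
#'   default `Inf` (no cap). In model comparisons the caller typically sets
#'   this to 10x the steepest member slope.
#' @return An object of class `psychometric_fit` with fields `bias`,
#'   `sigma`, `slope`, `n_trials`, `converged`, `capped`.
#' @export
#' @examples
#' set.seed(1)
#' dc <- rep(c(-0.1, -0.05, 0.05, 0.1), each = 250)
#' y <- runif(1000) < pnorm(dc / 0.07)
#' fit_psychometric(dc, y)
fit_psychometric <- function(delta_c, chose_second, slope_ceiling = Inf) {
  if (length(delta_c) != length(chose_second))
    stop("`delta_c` and `chose_second` must have equal length", call. = FALSE)
  if (!is.numeric(delta_c) || any(!is.finite(delta_c)))
    stop("`delta_c` must be finite numeric", call. = FALSE)
  y <- as.numeric(as.logical(chose_second))
  if (any(is.na(y))) stop("`chose_second` must be logical or 0/1", call. = FALSE)
  if (length(unique(delta_c)) < 2L)
    stop("need >= 2 distinct `delta_c` values to fit a psychometric function",
         call. = FALSE)
  if (!is_number(slope_ceiling) && !identical(slope_ceiling, Inf))
    stop("`slope_ceiling` must be a single number", call. = FALSE)

  n <- length(y)
  both_categories <- length(unique(y)) == 2L
  fit <- suppressWarnings(
    glm.fit(cbind(1, delta_c), y, family = binomial("probit"),
            control = glm.control(epsilon = 1e-8, maxit = 100)))
  co <- unname(fit$coefficients)
  separated <- is.finite(fit$deviance) && fit$deviance < 1e-6 && both_categories
  ok_coef <- length(co) == 2L && all(is.finite(co)) && co[2L] > 0

  if (ok_coef) {
    sigma <- 1 / co[2L]
    bias <- -co[1L] / co[2L]
    slope <- slope_from_sigma(sigma)
  } else {
    sigma <- NA_real_
    bias <- NA_real_
    slope <- 0
  }
  converged <- both_categories && isTRUE(fit$converged) && !separated && ok_coef

  capped <- FALSE
  if (!converged && is.finite(slope_ceiling) && slope > slope_ceiling) {
    slope <- slope_ceiling
    capped <- TRUE
  }
  structure(list(bias = bias, sigma = sigma, slope = slope,
                 n_trials = n, converged = converged, capped = capped),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> b=%.4g sigma=%.4g slope=%.4g n=%d converged=%s%s\n",
              x$bias, x$sigma, x$slope, x$n_trials, x$converged,
              if (x$capped) " (slope capped)" else ""))
  invisible(x)
}

#' Collective benefit ratio
#'
#' Ratio of a decision maker's psychometric slope to that of the more
#' sensitive dyad member: `s_test / max(s_member1, s_member2)`. A value
#' above 1 means the tested decision maker (the empirical dyad, or a model
#' acting for it) beats the dyad's better observer. Statistical tests on
#' cohorts should be applied to `log(CB)` to tame the heavy-tailed ratio
#' distribution.
#'
#' @param s_test Slope of the tested decision maker (> 0).
#' @param s_member1,s_member2 Slopes of the two dyad members (> 0).
#' @return The collective-benefit ratio.
#' @export
#' @examples
#' collective_benefit(1.2, 1.0, 0.8)  # 1.2
#' collective_benefit(0.9, 0.8, 1.0)  # 0.9: denominator is the steeper member
collective_benefit <- function(s_test, s_member1, s_member2) {
  s <- c(s_test, s_member1, s_member2)
  if (!is.numeric(s) || length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
    stop("all slopes must be finite and > 0", call. = FALSE)
  s_test / max(s_member1, s_member2)
}
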