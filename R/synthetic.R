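#' Observer parameters for the generative signal-detection model
#'
#' Describes one dyad member as an equal-variance Gaussian evidence observer.
#' On a trial with contrast difference `delta_c` the observer draws internal
#' evidence `x ~ N(delta_c - bias, sigma^2)` and chooses the second interval
#' iff `x > 0`, so its choice curve is exactly the cumulative Gaussian
#' `P(choose 2nd) = pnorm((delta_c - bias) / sigma)`. Confidence magnitude is
#' obtained by quantizing `|x|` against four ascending thresholds (giving the
#' empirical 5-step scale), and confidence escalation is modelled as a
#' geometric decay of those thresholds over trials: decayed thresholds raise
#' reported confidence without touching the choice rule, hence without
#' touching accuracy.
#'
#' @param sigma Evidence noise standard deviation, in contrast units
#'   (must be > 0).
#' @param bias Decision bias `b`, in contrast units. Default 0.
#' @param conf_thresholds Four strictly increasing positive cut-points on
#'   `|evidence|` mapping evidence strength to confidence magnitude 1-5.
#'   Default `sigma * c(0.5, 1, 1.5, 2)`, i.e. cuts at fixed multiples of the
#'   observer's own noise, which makes confidence approximately calibrated
#'   across observers with different `sigma`.
#' @param escalation_rate Per-trial multiplicative threshold decay rate in
#'   `[0, 1)`; on trial `t` (0-based) the thresholds are multiplied by
#'   `(1 - escalation_rate)^t`. 0 (default) means stationary confidence.
#' @return An object of class `observer_params`.
#' @seealso [simulate_observer_response()], [session_config()]
#' @export
#' @examples
#' observer_params(sigma = 0.07)
observer_params <- function(sigma, bias = 0, conf_thresholds = NULL,
                            escalation_rate = 0) {
  if (!is_number(sigma) || sigma <= 0)
    stop("`sigma` must be a single finite number > 0", call. = FALSE)
  if (!is_number(bias))
    stop("`bias` must be a single finite number", call. = FALSE)
  if (is.null(conf_thresholds)) conf_thresholds <- sigma * c(0.5, 1, 1.5, 2)
  if (!is.numeric(conf_thresholds) || length(conf_thresholds) != 4L ||
      any(!is.finite(conf_thresholds)) || any(conf_thresholds <= 0) ||
      any(diff(conf_thresholds) <= 0))
    stop("`conf_thresholds` must be 4 strictly increasing positive numbers",
         call. = FALSE)
  if (!is_number(escalation_rate) || escalation_rate < 0 || escalation_rate >= 1)
    stop("`escalation_rate` must be in [0, 1)", call. = FALSE)
  structure(list(sigma = sigma, bias = bias,
                 conf_thresholds = conf_thresholds,
                 escalation_rate = escalation_rate),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> sigma=%.4g bias=%.4g escalation_rate=%.4g\n",
              x$sigma, x$bias, x$escalation_rate))
  cat("  conf_thresholds:", paste(format(x$conf_thresholds, digits = 4),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Session configuration for a simulated dyad
#'
#' The default design mirrors a standard confidence-sharing 2IFC study:
#' 16 blocks of 16 trials (256 trials), four contrast-difference magnitudes
#' spanning very hard to very easy, and two observers.
#'
#' @param members List of two [observer_params()] objects.
#' @param seed Integer master seed for the session (mandatory: every random
#'   draw in the session is reproducible from it).
#' @param n_blocks,trials_per_block Session structure; defaults 16 and 16.
#' @param contrast_magnitudes Four distinct positive contrast-difference
#'   magnitudes. Published designs of this type rarely report exact values;
#'   the defaults
#'   `c(0.015, 0.035, 0.07, 0.15)` (unit-normalised contrast) are
#'   placeholders spanning ~58% to ~98% correct for a `sigma = 0.07`
#'   observer.
#' @return An object of class `session_config`.
#' @export
session_config <- function(members = list(observer_params(sigma = 0.06),
                                          observer_params(sigma = 0.09)),
                           seed,
                           n_blocks = 16, trials_per_block = 16,
                           contrast_magnitudes = c(0.015, 0.035, 0.07, 0.15)) {
  if (missing(seed) || !is_number(seed))
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  if (!is_count(n_blocks) || !is_count(trials_per_block))
    stop("`n_blocks` and `trials_per_block` must be positive integers",
         call. = FALSE)
  if (!is.numeric(contrast_magnitudes) || length(contrast_magnitudes) < 1L ||
      any(!is.finite(contrast_magnitudes)) || any(contrast_magnitudes <= 0) ||
      anyDuplicated(contrast_magnitudes))
    stop("`contrast_magnitudes` must be distinct positive numbers",
         call. = FALSE)
  if (!is.list(members) || length(members) != 2L ||
      !all(vapply(members, inherits, logical(1), "observer_params")))
    stop("`members` must be a list of two observer_params objects",
         call. = FALSE)
  structure(list(members = members, seed = as.integer(seed),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 contrast_magnitudes = as.numeric(contrast_magnitudes)),
            class = "session_config")
}

#' Simulate one observer's signed confidence response
#'
#' Draws internal evidence `x ~ N(delta_c - bias, sigma^2)` from the current
#' global RNG stream, chooses interval 2 iff `x > 0`, and reports confidence
#' magnitude `1 + #(decayed thresholds below |x|)` capped at 5, signed by the
#' chosen interval (negative = first, positive = second). Thresholds on trial
#' `t` are `conf_thresholds * (1 - escalation_rate)^t`, so escalation raises
#' confidence magnitudes over time while leaving choice accuracy untouched.
#'
#' Vectorized over `delta_c` and `trial_index` (recycled to a common length).
#'
#' @param delta_c Signed contrast difference(s); positive means the target is
#'   in the second interval.
#' @param params An [observer_params()] object.
#' @param trial_index 0-based trial index (or vector), used only for the
#'   escalation decay.
#' @return Integer vector of signed confidences in `{-5..-1, 1..5}`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_observer_response(c(-0.07, 0.07), observer_params(sigma = 0.07))
simulate_observer_response <- function(delta_c, params, trial_index = 0L) {
  if (!inherits(params, "observer_params"))
    stop("`params` must be an observer_params object", call. = FALSE)
  if (!is.numeric(delta_c) || any(!is.finite(delta_c)))
    stop("`delta_c` must be finite numeric", call. = FALSE)
  if (!is.numeric(trial_index) || any(trial_index < 0) ||
      any(trial_index != round(trial_index)))
    stop("`trial_index` must be non-negative integers", call. = FALSE)
  k <- max(length(delta_c), length(trial_index))
  delta_c <- rep_len(delta_c, k)
  trial_index <- rep_len(trial_index, k)
  x <- rnorm(k, mean = delta_c - params$bias, sd = params$sigma)
  decay <- (1 - params$escalation_rate)^trial_index
  # k x 4 matrix of decayed thresholds; magnitude = 1 + #(thresholds < |x|)
  thr <- outer(decay, params$conf_thresholds)
  mag <- pmin(1L + rowSums(thr < abs(x)), 5L)
  as.integer(ifelse(x > 0, 1L, -1L) * mag)
}

#' Default arbitration rule: the nominated member keeps their own choice
#'
#' On disagreement trials the joint decision is indicated by a randomly
#' nominated member; the generator's default policy is that this member
#' sticks with their individual choice. Alternative rules can be passed to
#' [simulate_session()]: any function of `(c1, c2, nominated)` over the
#' disagreement trials returning intervals in `{1, 2}`.
#'
#' @param c1,c2 Signed confidences of the two members on disagreement trials.
#' @param nominated Member (1 or 2) nominated to indicate the joint decision.
#' @return Integer vector of joint decisions (1 or 2).
#' @export
arbitrate_nominated <- function(c1, c2, nominated) {
  interval_of(ifelse(nominated == 1L, c1, c2))
}

#' Simulate a full dyad session
#'
#' Generates one trial record per trial: `|delta_c|` is drawn uniformly from
#' the configured magnitudes and the target interval (the sign of `delta_c`)
#' uniformly from `{1, 2}`; each member responds via
#' [simulate_observer_response()]; a responder is nominated uniformly at
#' random on every trial (meaningful on disagreement trials); the joint
#' decision is the common choice on agreement trials and the arbitration
#' rule's output on disagreement trials. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [session_config()] object.
#' @param arbitration Arbitration rule for disagreement trials; default
#'   [arbitrate_nominated()].
#' @return A `data.frame` with columns `trial_index` (0-based), `delta_c`,
#'   `c1`, `c2`, `correct_interval`, `nominated`, `dyad_decision` — the trial
#'   table schema used throughout the package.
#' @export
#' @examples
#' trials <- simulate_session(session_config(seed = 42))
#' nrow(trials)  # 256
simulate_session <- function(config, arbitration = arbitrate_nominated) {
  if (!inherits(config, "session_config"))
    stop("`config` must be a session_config object", call. = FALSE)
  if (!is.function(arbitration))
    stop("`arbitration` must be a function(c1, c2, nominated)", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_blocks * config$trials_per_block
  mag <- sample(config$contrast_magnitudes, n, replace = TRUE)
  correct_interval <- sample(c(1L, 2L), n, replace = TRUE)
  delta_c <- ifelse(correct_interval == 2L, mag, -mag)
  idx <- 0:(n - 1L)
  c1 <- simulate_observer_response(delta_c, config$members[[1L]], idx)
  c2 <- simulate_observer_response(delta_c, config$members[[2L]], idx)
  nominated <- sample(c(1L, 2L), n, replace = TRUE)
  choice1 <- interval_of(c1)
  choice2 <- interval_of(c2)
  agree <- choice1 == choice2
  dyad_decision <- choice1
  if (any(!agree)) {
    dec <- as.integer(arbitration(c1[!agree], c2[!agree], nominated[!agree]))
    if (length(dec) != sum(!agree) || any(!dec %in% c(1L, 2L)))
      stop("arbitration rule must return intervals in {1, 2}, one per disagreement trial",
           call. = FALSE)
    dyad_decision[!agree] <- dec
  }
  data.frame(trial_index = idx, delta_c = delta_c, c1 = c1, c2 = c2,
             correct_interval = correct_interval, nominated = nominated,
             dyad_decision = dyad_decision)
}

#' Cohort presets
#'
#' Escalation levels emulating the two communication conditions of a
#' confidence-sharing study: `"V"` (visual-only confidence sharing, mild
#' escalation), `"VV"` (visual plus verbal interaction, pronounced
#' escalation), and `"none"` (stationary confidence). Values are per-trial
#' geometric threshold decay rates; over 256 trials they shrink thresholds
#' to ~77% ("V") and ~36% ("VV") of their initial values.
#' @keywords internal
cohort_escalation_level <- function(preset) {
  switch(preset,
         none = 0,
         V    = 0.001,
         VV   = 0.004,
         stop(sprintf("unknown preset '%s'", preset), call. = FALSE))
}

#' Simulate a cohort of dyads with per-dyad parameter draws
#'
#' Draws observer parameters per dyad (noise SDs and, for escalating presets,
#' per-member escalation rates), gives each dyad an independent seed derived
#' from the master seed, and simulates each session. The returned manifest
#' records every drawn parameter so that parameter-recovery tests can refer
#' back to the generating truth.
#'
#' @param n_dyads Number of dyads (>= 1).
#' @param seed Master seed; per-dyad seeds and all parameter draws derive
#'   from it.
#' @param preset `"none"`, `"V"` or `"VV"` (see [cohort_escalation_level()]),
#'   or `"custom"` to use `escalation_level` directly.
#' @param sigma_range Range for the uniform per-member draw of `sigma`;
#'   default `c(0.05, 0.09)` gives realistically unequal dyad members
#'   (slope ratios mostly below ~1.8).
#' @param escalation_level Dyad-level escalation rate; per-member rates are
#'   jittered uniformly in `level * [1 - jitter, 1 + jitter]`. Ignored unless
#'   `preset = "custom"`.
#' @param escalation_jitter Relative jitter of per-member escalation rates
#'   around the dyad level; default 0.5.
#' @param n_blocks,trials_per_block,contrast_magnitudes Passed to
#'   [session_config()].
#' @return A list of class `dyad_cohort` with elements `sessions` (list of
#'   trial tables), `manifest` (data.frame: dyad_id, seed, sigma1, sigma2,
#'   bias1, bias2, escalation1, escalation2, preset) and `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(2, seed = 7, preset = "V")
#' coh$manifest
simulate_cohort <- function(n_dyads, seed, preset = c("none", "V", "VV", "custom"),
                            sigma_range = c(0.05, 0.09),
                            escalation_level = 0, escalation_jitter = 0.5,
                            n_blocks = 16, trials_per_block = 16,
                            contrast_magnitudes = c(0.015, 0.035, 0.07, 0.15)) {
  if (!is_count(n_dyads)) stop("`n_dyads` must be >= 1", call. = FALSE)
  if (!is_number(seed)) stop("`seed` must be a single integer", call. = FALSE)
  preset <- match.arg(preset)
  level <- if (preset == "custom") escalation_level else cohort_escalation_level(preset)
  if (!is_number(level) || level < 0) stop("invalid escalation level", call. = FALSE)

  set.seed(derive_seed(seed, 0))
  n <- as.integer(n_dyads)
  sigma1 <- runif(n, sigma_range[1L], sigma_range[2L])
  sigma2 <- runif(n, sigma_range[1L], sigma_range[2L])
  esc1 <- level * runif(n, 1 - escalation_jitter, 1 + escalation_jitter)
  esc2 <- level * runif(n, 1 - escalation_jitter, 1 + escalation_jitter)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))

  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- session_config(
      members = list(
        observer_params(sigma = sigma1[i], escalation_rate = esc1[i]),
        observer_params(sigma = sigma2[i], escalation_rate = esc2[i])),
      seed = seeds[i], n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      contrast_magnitudes = contrast_magnitudes)
    sessions[[i]] <- simulate_session(cfg)
  }
  manifest <- data.frame(dyad_id = seq_len(n), seed = seeds,
                         sigma1 = sigma1, sigma2 = sigma2,
                         bias1 = 0, bias2 = 0,
                         escalation1 = esc1, escalation2 = esc2,
                         preset = preset, stringsAsFactors = FALSE)
  structure(list(sessions = sessions, manifest = manifest,
                 seed = as.integer(seed)),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d dyads, preset '%s', master seed %d\n",
              nrow(x$manifest), x$manifest$preset[1L], x$seed))
  invisible(x)
}
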