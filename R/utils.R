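# Internal helpers: validation and deterministic seed derivation.

# Valid signed confidence alphabet: -5..-1, 1..5 (zero excluded).
confidence_alphabet <- function() c(-5:-1, 1:5)

# Number of confidence steps per direction on the raw reporting scale.
confidence_steps <- function() max(abs(confidence_alphabet()))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_confidence <- function(conf, what = "confidence") {
  bad <- !(conf %in% confidence_alphabet())
  if (any(bad)) {
    stop(sprintf("%s values must be integers in {-5..-1, 1..5} (zero excluded); offending value: %s",
                 what, format(conf[which(bad)[1L]])), call. = FALSE)
  }
  invisible(conf)
}

# Interval (1 or 2) encoded by the sign of a signed confidence.
interval_of <- function(conf) ifelse(conf > 0, 2L, 1L)

# Deterministic seed chaining on the Lehmer multiplier; every intermediate
# product stays below 2^53 so the arithmetic is exact in doubles, and the
# result is a valid 32-bit seed in [1, 2147483647].
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- abs(as.numeric(master)) %% m
  for (k in c(...)) {
    h <- (h * 48271) %% m
    h <- (h + (abs(as.numeric(k)) %% m) + 1) %% m
  }
  h <- (h * 48271) %% m
  as.integer(h %% (m - 1) + 1)
}
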