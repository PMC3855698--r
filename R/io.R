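# Trial-table schema shared by the simulator, the fitters and the CSV I/O.
trial_columns <- function() {
  c("trial_index", "delta_c", "c1", "c2",
    "correct_interval", "nominated", "dyad_decision")
}

#' Validate a trial table against the schema
#'
#' Checks the exact column set, finite `delta_c`, signed non-zero
#' confidences in `{-5..-1, 1..5}` and intervals in `{1, 2}`. Errors name
#' the first offending row and column.
#'
#' @param trials A data.frame candidate trial table.
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials))
    stop("trial table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols))
    stop(sprintf("trial table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  fail <- function(col, rows, why) {
    stop(sprintf("trial table validation failed at row %d, column '%s': %s",
                 rows[1L], col, why), call. = FALSE)
  }
  check <- function(col, ok, why) {
    if (any(!ok)) fail(col, which(!ok), why)
  }
  check("trial_index",
        is.finite(trials$trial_index) & trials$trial_index >= 0 &
          trials$trial_index == round(trials$trial_index),
        "must be a non-negative integer")
  check("delta_c", is.finite(trials$delta_c), "must be finite")
  for (col in c("c1", "c2"))
    check(col, trials[[col]] %in% confidence_alphabet(),
          "must be a signed non-zero confidence in {-5..-1, 1..5}")
  for (col in c("correct_interval", "nominated", "dyad_decision"))
    check(col, trials[[col]] %in% c(1L, 2L), "must be 1 or 2")
  agree <- interval_of(trials$c1) == interval_of(trials$c2)
  common <- interval_of(trials$c1)
  check("dyad_decision", !agree | trials$dyad_decision == common,
        "must equal the common choice on agreement trials")
  invisible(trials)
}

# Format a numeric column with enough digits for a bit-identical round trip;
# whole-number doubles keep a decimal point so they read back as doubles.
fmt_full <- function(x) {
  if (!is.double(x)) return(x)
  s <- sprintf("%.17g", x)
  plain <- !grepl("[.eE]", s)
  s[plain] <- paste0(s[plain], ".0")
  s
}

write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_full(out[[j]])
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write trial tables as CSV
#'
#' The on-disk dialect is RFC-4180 CSV, UTF-8, header row, columns exactly
#' `trial_index, delta_c, c1, c2, correct_interval, nominated,
#' dyad_decision`; confidences are signed integers with no zeros. Reading
#' applies [validate_trials()] and preserves row order; writing uses full
#' precision so `write_trials()` then `read_trials()` is the identity.
#' Confidence magnitudes 5 load unchanged — the collapse to 4 happens only
#' inside [transform_state()], as a modelling step.
#'
#' @param path File path.
#' @param trials Trial table to write.
#' @return `read_trials()`: the validated trial table. `write_trials()`:
#'   `path`, invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (!identical(names(df), trial_columns()))
    stop(sprintf("trial CSV must have columns exactly: %s (got: %s)",
                 paste(trial_columns(), collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  for (col in c("trial_index", "c1", "c2", "correct_interval", "nominated",
                "dyad_decision")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("trial table validation failed at column '%s': not numeric", col),
           call. = FALSE)
    df[[col]] <- as.integer(df[[col]])
  }
  validate_trials(df)
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write_csv_full(trials[trial_columns()], path)
}

#' Read and write cohort parameter manifests
#'
#' The manifest records every parameter drawn for a simulated cohort (see
#' [simulate_cohort()]). Numeric columns are written at full precision so
#' the round trip is bit-identical.
#'
#' @param manifest Manifest data.frame.
#' @param path File path.
#' @return `read_manifest()`: the manifest data.frame. `write_manifest()`:
#'   `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write_csv_full(manifest, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything a `reproduce` run needs: master seed, cohort preset
#' and size, fitting options and the output directory. Round-trips through
#' JSON losslessly.
#'
#' @param seed Master seed (mandatory).
#' @param preset Cohort preset: `"none"`, `"V"` or `"VV"`.
#' @param n_dyads Cohort size.
#' @param n_bins Learning-restart bins for the fitters.
#' @param alpha_grid Learning-rate grid.
#' @param objective `"max_accuracy"`, `"max_similarity"` or `"both"`.
#' @param update_on_agreement Ledger switch: update Q on agreement trials.
#' @param escalation_index_type `"relative"` or `"absolute"`.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, preset = "V", n_dyads = 14, n_bins = 3,
                       alpha_grid = seq(0, 1, by = 0.01),
                       objective = c("both", "max_accuracy", "max_similarity"),
                       update_on_agreement = TRUE,
                       escalation_index_type = c("relative", "absolute"),
                       out_dir = ".") {
  if (missing(seed) || !is_number(seed))
    stop("`seed` is mandatory", call. = FALSE)
  structure(list(seed = as.integer(seed), preset = preset,
                 n_dyads = as.integer(n_dyads), n_bins = as.integer(n_bins),
                 alpha_grid = as.numeric(alpha_grid),
                 objective = match.arg(objective),
                 update_on_agreement = isTRUE(update_on_agreement),
                 escalation_index_type = match.arg(escalation_index_type),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the JSON config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = x$seed, preset = x$preset, n_dyads = x$n_dyads,
             n_bins = x$n_bins, alpha_grid = x$alpha_grid,
             objective = x$objective,
             update_on_agreement = x$update_on_agreement,
             escalation_index_type = x$escalation_index_type,
             out_dir = x$out_dir)
}
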