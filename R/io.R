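# CSV reading/writing for the three tabular interfaces: choice trials,
# reconstruction trials, and CCEI-versus-retention-interval datasets.

.write_csv <- function(df, path) {
  # keep full double precision so budget identities survive round-trips
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a trials CSV
#'
#' One row per choice trial, schema [trials_schema()], doubles serialised
#' with 15 significant digits.
#'
#' @param trials Data frame of trials.
#' @param path File path.
#' @return `read_trials_csv` returns the validated data frame.
#' @export
write_trials_csv <- function(trials, path) {
  if (!all(trials_schema() %in% names(trials))) .stopf("trials schema mismatch")
  .write_csv(trials[trials_schema()], path)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trials_schema(), names(df))
  if (length(missing))
    .stopf("trials CSV missing columns: %s", paste(missing, collapse = ", "))
  df
}

.recon_cols <- function() c("participant_id", "presentation_time_s",
                            "retention_interval_s", "axis",
                            "exemplar_deg", "response_deg")

#' Write / read a reconstruction-task CSV
#'
#' @param trials Data frame of reconstruction trials.
#' @param path File path.
#' @export
write_recon_csv <- function(trials, path) {
  if (!all(.recon_cols() %in% names(trials))) .stopf("recon schema mismatch")
  .write_csv(trials[.recon_cols()], path)
  invisible(path)
}

#' @rdname write_recon_csv
#' @export
read_recon_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.recon_cols(), names(df))
  if (length(missing))
    .stopf("recon CSV missing columns: %s", paste(missing, collapse = ", "))
  df
}

#' Write / read a CCEI dataset CSV
#'
#' Columns `participant_id`, `retention_interval_s`, `ccei`.
#'
#' @param data CCEI dataset.
#' @param path File path.
#' @export
write_ccei_csv <- function(data, path) {
  cols <- c("participant_id", "retention_interval_s", "ccei")
  if (!all(cols %in% names(data))) .stopf("ccei schema mismatch")
  .write_csv(data[cols], path)
  invisible(path)
}

#' @rdname write_ccei_csv
#' @export
read_ccei_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_ccei_data(df)
  df
}
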