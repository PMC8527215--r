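# Reconstruction-task analysis: absolute (circular) reconstruction error,
# manipulation-check summaries over retention interval and presentation
# time, and the exploratory task-difficulty bootstrap.

#' Absolute reconstruction error (circular distance)
#'
#' Distance between two orientations on the circle, in degrees: 0 and 360
#' degrees are the same orientation, so the error between 90 and 360
#' degrees is 90, not 270. Bounded by 180.
#'
#' @param a_deg,b_deg Orientations in degrees (vectorised).
#' @return Error(s) in \[0, 180\].
#' @export
circular_error <- function(a_deg, b_deg) {
  if (any(!is.finite(a_deg)) || any(!is.finite(b_deg)))
    .stopf("orientations must be finite")
  d <- abs(a_deg - b_deg) %% 360
  pmin(d, 360 - d)
}

#' Literal printed absolute-error formula (audit variant)
#'
#' Evaluates `||a - b| - 180|` exactly as printed in the study's
#' statistical-analysis description. Kept for auditability only: it
#' returns 180 for identical orientations and disagrees with the worked
#' example (90 vs 360) that identifies the intended quantity as the
#' circular distance implemented by [circular_error()].
#'
#' @inheritParams circular_error
#' @return Numeric vector.
#' @export
circular_error_literal <- function(a_deg, b_deg) abs(abs(a_deg - b_deg) - 180)

#' Manipulation-check summary of reconstruction errors
#'
#' Cell means, standard errors and counts of the absolute reconstruction
#' error by retention interval and by presentation time, with a
#' monotone-trend flag across retention-interval levels. Cells with a
#' single trial get `NA` standard errors; empty levels are omitted with a
#' warning.
#'
#' @param trials Reconstruction trials (`retention_interval_s`,
#'   `presentation_time_s`, `exemplar_deg`, `response_deg`).
#' @return List with data frames `by_ri` and `by_pt` (columns `level`,
#'   `mean_error`, `se`, `n`) and logical `monotone_in_ri`.
#' @export
manipulation_summary <- function(trials) {
  req <- c("retention_interval_s", "presentation_time_s",
           "exemplar_deg", "response_deg")
  if (!all(req %in% names(trials))) .stopf("missing reconstruction columns")
  if (nrow(trials) == 0L) .stopf("no trials to summarise")
  err <- circular_error(trials$exemplar_deg, trials$response_deg)
  summarise_by <- function(f) {
    lv <- sort(unique(f))
    out <- do.call(rbind, lapply(lv, function(l) {
      e <- err[f == l]
      data.frame(level = l, mean_error = mean(e),
                 se = if (length(e) > 1) stats::sd(e) / sqrt(length(e)) else NA_real_,
                 n = length(e))
    }))
    out
  }
  by_ri <- summarise_by(trials$retention_interval_s)
  by_pt <- summarise_by(trials$presentation_time_s)
  list(by_ri = by_ri, by_pt = by_pt,
       monotone_in_ri = !is.unsorted(by_ri$mean_error, strictly = FALSE))
}

#' Orientation increment between adjacent choice-set options
#'
#' Adjacent options on the budget line differ by `(m / p) / 4` tokens on
#' an axis, i.e. `0.3 * (m / p) / 4` degrees of orientation — the
#' granularity a chooser must discriminate on that axis.
#'
#' @param price Axis price(s) (vectorised).
#' @param m Budget in tokens.
#' @return Increment(s) in degrees.
#' @export
increment_step <- function(price, m = 100) {
  if (any(price <= 0) || any(m <= 0)) .stopf("price and budget must be positive")
  0.3 * (m / price) / 4
}

#' Bootstrap comparison of reconstruction error and choice-set increments
#'
#' Percentile bootstrap of `mean(errors) - mean(increments)`, resampling
#' each list independently with replacement. A positive difference means
#' the typical reconstruction error exceeds the orientation step between
#' adjacent options, i.e. the discrimination the task requires is finer
#' than what memory supports.
#'
#' @param errors Absolute reconstruction errors (degrees).
#' @param increments Choice-set orientation increments (degrees).
#' @param n_boot Bootstrap resamples (10000 in the study).
#' @param seed Optional integer seed.
#' @return List with `mean_diff`, `ci95` (`lo`, `hi`), `n_boot`, `seed`
#'   and the bootstrap distribution `boot`.
#' @export
bootstrap_difficulty <- function(errors, increments, n_boot = 10000, seed = NULL) {
  if (length(errors) == 0L || length(increments) == 0L)
    .stopf("`errors` and `increments` must be non-empty")
  .seed_scope(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(errors, replace = TRUE)) -
      mean(sample(increments, replace = TRUE))
  }, numeric(1))
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  list(mean_diff = mean(errors) - mean(increments),
       ci95 = c(lo = ci[1], hi = ci[2]),
       n_boot = n_boot, seed = seed, boot = boot)
}
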