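# Construction of multi-attribute visual choice (MAVC) budget-line choice
# sets, and the mapping from similarity-token bundles to cube-orientation
# offsets.
#
# Each trial offers five visual objects lying on a budget line: at prices
# p = (p_x, p_y) and budget m, a bundle (x_x, x_y) of similarity tokens
# satisfies x_x * p_x + x_y * p_y = m. Tokens translate linearly into
# orientation: 0 tokens = 30 degrees away from the exemplar on that axis,
# 100 tokens = exact match, 0.3 degrees per token.

#' Permitted exemplar orientations (degrees)
#'
#' The six orientations used for exemplar cubes on each rotation axis.
#'
#' @return Numeric vector of length 6.
#' @export
exemplar_orientations <- function() c(10, 75, 120, 185, 250, 315)

#' Draw a random price pair for one trial
#'
#' One component is drawn uniformly from \[1, 3\] and the other from
#' \[1, 10\]; which axis receives which range is a fair coin flip.
#'
#' @param integer_prices If `TRUE`, prices are drawn uniformly from the
#'   integers of each range instead of the continuous interval.
#' @return Named numeric vector `c(x = p_x, y = p_y)`.
#' @export
draw_prices <- function(integer_prices = FALSE) {
  ranges <- list(c(1, 3), c(1, 10))
  if (stats::runif(1) < 0.5) ranges <- rev(ranges)
  draw1 <- function(r) {
    if (integer_prices) sample(seq(r[1], r[2]), 1L) else stats::runif(1, r[1], r[2])
  }
  c(x = draw1(ranges[[1]]), y = draw1(ranges[[2]]))
}

#' Build the five-option budget-line choice set
#'
#' Options are equidistant points on the budget line, placed at fractions
#' 0, 1/4, 1/2, 3/4 and 1 of the X-intercept `m / p_x`, so the extreme
#' bundles `(m/p_x, 0)` and `(0, m/p_y)` are always included and every
#' option exactly exhausts the budget.
#'
#' @param p_x,p_y Positive prices of similarity tokens on the X and Y axis.
#' @param m Budget in tokens (default 100).
#' @return A 5 x 2 matrix with columns `x`, `y`; row `k` is option `k`.
#' @export
make_choice_set <- function(p_x, p_y, m = 100) {
  if (!is.numeric(p_x) || !is.numeric(p_y) || p_x <= 0 || p_y <= 0)
    .stopf("prices must be positive")
  if (!is.numeric(m) || m <= 0) .stopf("budget must be positive")
  fx <- seq(0, 1, by = 0.25)
  x <- fx * m / p_x
  y <- (m - x * p_x) / p_y
  # fraction 1 must hit the axis exactly despite float division
  y[length(y)] <- 0
  cbind(x = x, y = y)
}

#' Map a token value to an option orientation
#'
#' `tokens = 0` places the option 30 degrees away from the exemplar on the
#' given axis; each token rotates it 0.3 degrees back toward the exemplar,
#' so `tokens = 100` matches the exemplar exactly.
#'
#' @param tokens Similarity tokens in \[0, 100\] (vectorised).
#' @param exemplar_deg Exemplar orientation in degrees.
#' @param side `+1` (clockwise of the exemplar) or `-1`; the consistency
#'   analysis is invariant to this choice.
#' @return Orientation in degrees, wrapped to \[0, 360).
#' @export
bundle_to_orientation <- function(tokens, exemplar_deg, side = 1) {
  if (any(!is.finite(tokens)) || any(tokens < -1e-9) || any(tokens > 100 + 1e-9))
    .stopf("`tokens` must lie in [0, 100]: more than 100 tokens would overshoot the exemplar")
  if (!all(side %in% c(-1, 1))) .stopf("`side` must be +1 or -1")
  .wrap360(exemplar_deg + side * (30 - 0.3 * tokens))
}

.trial_cols <- function() {
  c("participant_id", "block_role", "retention_interval_s", "trial_id",
    "price_x", "price_y", "budget", "exemplar_x_deg", "exemplar_y_deg",
    paste0("opt", 1:5, "_x"), paste0("opt", 1:5, "_y"), "choice_index")
}

#' Generate one block of choice trials
#'
#' Draws fresh prices and exemplar orientations for each trial and builds
#' the five-option choice set. `choice_index` is left `NA` until a chooser
#' model (or a participant) fills it.
#'
#' @param participant_id Identifier stored with each trial.
#' @param t Retention interval in seconds, in \[0, 30\].
#' @param n_trials Number of trials (20 in the study design).
#' @param block_role Label for the block (e.g. `"block1"`, later remapped
#'   to `"train"`/`"test"` by [split_train_test()]).
#' @param m Budget in tokens.
#' @param integer_prices Passed to [draw_prices()].
#' @param seed Optional integer seed; when supplied the block is a pure
#'   function of its arguments.
#' @return A data frame with one row per trial (see [trials_schema()]).
#' @export
generate_block <- function(participant_id, t, n_trials = 20, block_role = "block1",
                           m = 100, integer_prices = FALSE, seed = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 30)
    .stopf("retention interval `t` must lie in [0, 30] seconds")
  if (n_trials < 1) .stopf("`n_trials` must be >= 1")
  .seed_scope(seed)
  ex <- exemplar_orientations()
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    p <- draw_prices(integer_prices = integer_prices)
    opts <- make_choice_set(p[["x"]], p[["y"]], m)
    rows[[i]] <- data.frame(
      participant_id = participant_id, block_role = block_role,
      retention_interval_s = t, trial_id = i,
      price_x = p[["x"]], price_y = p[["y"]], budget = m,
      exemplar_x_deg = sample(ex, 1L), exemplar_y_deg = sample(ex, 1L),
      t(stats::setNames(opts[, "x"], paste0("opt", 1:5, "_x"))),
      t(stats::setNames(opts[, "y"], paste0("opt", 1:5, "_y"))),
      choice_index = NA_integer_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[.trial_cols()]
}

#' Generate a two-block session for one participant
#'
#' Each block receives an independent retention interval drawn uniformly
#' from \[0, 30\] seconds, matching the study design of two consecutive
#' blocks of 20 trials.
#'
#' @inheritParams generate_block
#' @return A data frame of `2 * n_trials` rows with `block_role` values
#'   `"block1"` and `"block2"`.
#' @export
generate_session <- function(participant_id, n_trials = 20, m = 100,
                             integer_prices = FALSE, seed = NULL) {
  .seed_scope(seed)
  t1 <- stats::runif(1, 0, 30)
  t2 <- stats::runif(1, 0, 30)
  rbind(
    generate_block(participant_id, t1, n_trials, "block1", m, integer_prices),
    generate_block(participant_id, t2, n_trials, "block2", m, integer_prices))
}

#' Column schema of the trials table
#'
#' @return Character vector of the column names used by the trials CSV.
#' @export
trials_schema <- function() .trial_cols()
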