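# Forgetting models for CCEI-versus-retention-interval data.
#
# Both candidate models state CCEI_t ~ Normal(mu_t, sigma) truncated to
# [0, 1]. The exponential model sets mu_t = a + (1 - a) * b * exp(-alpha * t)
# (asymptote a, t = 0 level a + (1 - a) * b, decay rate alpha); the null
# model sets mu_t = c. All parameters carry Beta(1, 1) priors on [0, 1].

#' Exponential forgetting mean
#'
#' `mu_t = a + (1 - a) * b * exp(-alpha * t)`: consistency starts at
#' `a + (1 - a) * b` for an immediate choice and decays at constant rate
#' `alpha` toward the asymptote `a`.
#'
#' @param t Retention interval(s) in seconds, `>= 0`.
#' @param a Asymptotic consistency level in \[0, 1\].
#' @param b Baseline level at `t = 0` in \[0, 1\].
#' @param alpha Decay rate in \[0, 1\].
#' @return Expected CCEI, same length as `t`.
#' @export
mu_exponential <- function(t, a, b, alpha) {
  .check_prob01(a, "a"); .check_prob01(b, "b"); .check_prob01(alpha, "alpha")
  if (any(t < 0)) .stopf("`t` must be >= 0")
  a + (1 - a) * b * exp(-alpha * t)
}

#' Truncated-normal log likelihood of a CCEI dataset
#'
#' Sum of log densities of `Normal(mu, sigma)` truncated to \[0, 1\],
#' evaluated at the observed CCEI values.
#'
#' @param ccei Observed CCEI values in \[0, 1\].
#' @param mu Mean(s), recycled against `ccei`.
#' @param sigma Noise standard deviation, `> 0`.
#' @return Log likelihood (scalar).
#' @export
truncnorm_loglik <- function(ccei, mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    .stopf("`sigma` must be a single number > 0")
  if (any(ccei < 0 | ccei > 1)) .stopf("`ccei` values must lie in [0, 1]")
  z <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
  sum(stats::dnorm(ccei, mu, sigma, log = TRUE) - log(z))
}

# model table: parameter names and log-likelihood functions on [0,1]^d
.model_def <- function(model) {
  switch(model,
    exponential = list(
      pars = c("a", "b", "alpha", "sigma"),
      loglik = function(theta, data) {
        if (theta[4] <= 0) return(-Inf)
        mu <- theta[1] + (1 - theta[1]) * theta[2] *
          exp(-theta[3] * data$retention_interval_s)
        truncnorm_loglik(data$ccei, mu, theta[4])
      }),
    null = list(
      pars = c("c", "sigma"),
      loglik = function(theta, data) {
        if (theta[2] <= 0) return(-Inf)
        truncnorm_loglik(data$ccei, theta[1], theta[2])
      }),
    .stopf("unknown model '%s'", model))
}

.check_ccei_data <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("retention_interval_s", "ccei") %in% names(data)))
    .stopf("`data` needs columns `retention_interval_s` and `ccei`")
  if (nrow(data) >= 1L &&
      (any(data$ccei < 0 | data$ccei > 1) ||
       any(data$retention_interval_s < 0)))
    .stopf("`ccei` must lie in [0, 1] and retention intervals must be >= 0")
  invisible(data)
}

#' Replication Bayes factor by evidence updating
#'
#' The evidence the held-out test data add on top of the training data:
#' the Bayes factor of the combined dataset divided by that of the
#' training set alone. Exact — no approximation beyond the two input BFs.
#'
#' @param bf_combined Bayes factor computed on training + test data.
#' @param bf_train Bayes factor computed on the training data alone.
#' @return `bf_combined / bf_train`.
#' @export
replication_bf <- function(bf_combined, bf_train) {
  if (!is.numeric(bf_combined) || !is.numeric(bf_train) ||
      bf_combined <= 0 || bf_train <= 0)
    .stopf("Bayes factors must be positive numbers")
  bf_combined / bf_train
}

#' Map a Bayes factor to the study's interpretation verdict
#'
#' `BF >= 10` counts as strong support for the hypothesis, `BF <= 0.1` as
#' strong support against it, anything between as inconclusive.
#'
#' @param bf10 A Bayes factor.
#' @return One of `"strong support"`, `"strong support against"`,
#'   `"inconclusive"`.
#' @export
bf_verdict <- function(bf10) {
  if (!is.numeric(bf10) || bf10 <= 0) .stopf("`bf10` must be positive")
  if (bf10 >= 10) "strong support"
  else if (bf10 <= 0.1) "strong support against"
  else "inconclusive"
}

#' Monitor a sequential Bayes-factor stopping rule
#'
#' Recomputes the exponential-versus-null Bayes factor on growing
#' prefixes of a dataset and reports when the conclusive thresholds
#' (`>= 10` or `<= 0.1`) are first crossed. A monitoring utility over
#' already-collected data, not a data-collection controller.
#'
#' @param data CCEI dataset (`retention_interval_s`, `ccei`).
#' @param step Number of observations added per monitoring point.
#' @param lower,upper Stopping thresholds.
#' @return Data frame with `n` and `bf10` per monitoring point, with
#'   attribute `stopped_at` (first conclusive `n`, or `NA`).
#' @export
bf_stopping_monitor <- function(data, step = 25, lower = 0.1, upper = 10) {
  .check_ccei_data(data)
  ns <- unique(c(seq(step, nrow(data), by = step), nrow(data)))
  bf <- vapply(ns, function(k) {
    bf_quadrature(data[seq_len(k), , drop = FALSE])$bf10
  }, numeric(1))
  hit <- which(bf >= upper | bf <= lower)
  out <- data.frame(n = ns, bf10 = bf)
  attr(out, "stopped_at") <- if (length(hit)) ns[hit[1]] else NA_integer_
  out
}
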