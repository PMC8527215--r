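# H1 inference: rank association between retention interval and CCEI,
# with a one-sided Savage-Dickey Bayes factor, plus test-retest
# reliability of the consistency indices.

#' Kendall's tau (tie-corrected)
#'
#' Tau-b rank correlation between two paired series; equals tau-a when
#' there are no ties. Computed via [stats::cor()].
#'
#' @param u,v Numeric vectors of equal length, `n >= 2`.
#' @return A number in \[-1, 1\].
#' @export
kendall_tau <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    .stopf("`u` and `v` must have equal length >= 2")
  if (any(!is.finite(u)) || any(!is.finite(v))) .stopf("values must be finite")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    .stopf("correlation undefined for a constant series")
  stats::cor(u, v, method = "kendall")
}

# standardized Kendall statistic T* whose asymptotic sampling distribution
# is Normal(1.5 * tau * sqrt(n), 1)
.kendall_zstat <- function(u, v) {
  n <- length(u)
  du <- sign(outer(u, u, "-")); dv <- sign(outer(v, v, "-"))
  S <- sum(du[upper.tri(du)] * dv[upper.tri(dv)])  # concordant - discordant
  3 * S / sqrt(n * (n - 1) * (2 * n + 5) / 2)
}

# prior density on tau induced by parametric yoking from a stretched
# Beta(1/kappa, 1/kappa) prior on Pearson's rho via tau = (2/pi) asin(rho)
.tau_prior <- function(tau, kappa = 1) {
  rho <- sin(pi * tau / 2)
  stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2 *
    (pi / 2) * cos(pi * tau / 2)
}

#' One-sided Bayes factor for Kendall's tau
#'
#' Savage-Dickey density-ratio test of `tau = 0` using the asymptotic
#' normal likelihood of the standardized Kendall statistic, with the
#' yoked symmetric prior on tau (width `kappa`; `kappa = 1` corresponds
#' to a uniform prior on the underlying Pearson correlation). For the
#' directional hypotheses the prior mass is restricted to the
#' corresponding sign.
#'
#' @param u,v Paired series (e.g. retention interval and CCEI).
#' @param alternative `"negative"` (default; an inverse relationship),
#'   `"positive"`, or `"two.sided"`.
#' @param kappa Prior width parameter.
#' @param n_grid Grid size of the numerical prior/posterior evaluation.
#' @return List of class `mavc_bf` with `bf10`, `method`
#'   (`"savage-dickey"`), the observed `tau`, and diagnostics.
#' @export
bf_kendall_onesided <- function(u, v, alternative = c("negative", "positive", "two.sided"),
                                kappa = 1, n_grid = 4001) {
  alternative <- match.arg(alternative)
  tau_hat <- kendall_tau(u, v)  # validates input
  n <- length(u)
  z <- .kendall_zstat(u, v)
  tau <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  prior <- .tau_prior(tau, kappa)
  lik <- stats::dnorm(z, 1.5 * tau * sqrt(n), 1)
  post_un <- prior * lik
  norm_tr <- function(dens, keep) {
    d2 <- dens * keep
    d2 / (sum(d2) * diff(tau[1:2]))
  }
  keep <- switch(alternative,
                 negative = tau <= 0, positive = tau >= 0,
                 two.sided = rep(TRUE, n_grid))
  # one-sided priors double the density at 0 relative to the symmetric one
  prior_n <- norm_tr(prior, keep)
  post_n <- norm_tr(post_un, keep)
  at0 <- which.min(abs(tau))
  bf10 <- prior_n[at0] / post_n[at0]
  structure(list(bf10 = bf10, log_bf10 = log(bf10), mc_error = 0,
                 method = "savage-dickey", tau = tau_hat,
                 diagnostics = list(alternative = alternative, n = n,
                                    z_stat = z, kappa = kappa)),
            class = "mavc_bf")
}

#' Test-retest reliability of a consistency index
#'
#' Pearson correlation of a consistency index between the training and
#' test blocks of matched participants.
#'
#' @param train,test Data frames of per-block consistency results (as
#'   returned by [consistency_report()] rows), containing
#'   `participant_id` and the index column.
#' @param index_name Column to correlate (default `"ccei"`).
#' @return Pearson correlation coefficient.
#' @export
test_retest <- function(train, test, index_name = "ccei") {
  if (!index_name %in% names(train) || !index_name %in% names(test))
    .stopf("index `%s` missing from inputs", index_name)
  m <- merge(train[c("participant_id", index_name)],
             test[c("participant_id", index_name)],
             by = "participant_id", suffixes = c("_train", "_test"))
  if (nrow(m) < 3L) .stopf("need at least 3 matched participants")
  stats::cor(m[[paste0(index_name, "_train")]],
             m[[paste0(index_name, "_test")]])
}
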