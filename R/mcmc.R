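# Posterior sampling and Bayes-factor machinery for the forgetting models.
#
# All parameters live on [0, 1] with flat Beta(1, 1) priors, so the
# posterior is proportional to the likelihood and the marginal likelihood
# is the integral of the likelihood over the unit hypercube. Sampling uses
# componentwise random-walk Metropolis with boundary reflection (a
# symmetric proposal on the interval); model comparison uses the product
# space method with moment-matched Beta pseudo-priors, cross-checked by
# adaptive tensor quadrature.

# reflect a proposal into [0, 1] (preserves proposal symmetry)
.reflect01 <- function(z) {
  while (any(z < 0 | z > 1)) {
    z <- ifelse(z < 0, -z, z)
    z <- ifelse(z > 1, 2 - z, z)
  }
  z
}

# split-Rhat of one parameter given an iterations x chains matrix
.split_rhat <- function(draws) {
  ni <- nrow(draws)
  half <- ni %/% 2L
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(ni - half + 1L):ni, , drop = FALSE])
  mns <- colMeans(segs)
  vars <- apply(segs, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Default MCMC configuration
#'
#' @param n_chains Number of chains.
#' @param n_iter Post-warmup iterations per chain.
#' @param n_warmup Warmup (adaptation) iterations per chain.
#' @return Named list of settings.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 10000, n_warmup = 2000) {
  if (n_chains < 2 || n_iter < 100 || n_warmup < 100)
    .stopf("need >= 2 chains and reasonable iteration counts")
  list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup)
}

#' Sample a forgetting-model posterior
#'
#' Adaptive componentwise random-walk Metropolis within \[0, 1\]^d
#' (reflection at the boundaries, per-component step sizes tuned during
#' warmup toward 44% acceptance). Flat priors mean the target is the
#' truncated-normal likelihood itself.
#'
#' @param data CCEI dataset with columns `retention_interval_s`, `ccei`.
#' @param model `"exponential"` or `"null"`.
#' @param config A [mcmc_config()].
#' @param seed Optional integer seed.
#' @return List with `draws` (matrix, one column per parameter), `chain`
#'   (chain index per draw), `acceptance` (per-parameter rates), `rhat`
#'   (split-Rhat per parameter), `model`, `pars`. Warns if any split-Rhat
#'   exceeds 1.01.
#' @export
sample_posterior <- function(data, model = c("exponential", "null"),
                             config = mcmc_config(), seed = NULL) {
  model <- match.arg(model)
  .check_ccei_data(data)
  if (nrow(data) == 0L) .stopf("`data` must contain at least one observation")
  .seed_scope(seed)
  def <- .model_def(model)
  d <- length(def$pars)
  nc <- config$n_chains; ni <- config$n_iter; nw <- config$n_warmup
  draws <- array(NA_real_, c(ni, nc, d))
  acc_post <- matrix(0, nc, d)
  for (ch in seq_len(nc)) {
    theta <- stats::runif(d, 0.05, 0.95)
    ll <- def$loglik(theta, data)
    while (!is.finite(ll)) { theta <- stats::runif(d, 0.05, 0.95); ll <- def$loglik(theta, data) }
    lsc <- rep(log(0.1), d)
    acc_batch <- rep(0, d)
    for (it in seq_len(nw + ni)) {
      for (k in seq_len(d)) {
        prop <- theta
        prop[k] <- .reflect01(theta[k] + exp(lsc[k]) * stats::rnorm(1))
        llp <- def$loglik(prop, data)
        if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
          theta <- prop; ll <- llp
          acc_batch[k] <- acc_batch[k] + 1
          if (it > nw) acc_post[ch, k] <- acc_post[ch, k] + 1
        }
      }
      if (it <= nw && it %% 50L == 0L) {
        lsc <- lsc + (acc_batch / 50 - 0.44)
        acc_batch[] <- 0
      }
      if (it > nw) draws[it - nw, ch, ] <- theta
    }
  }
  rhat <- vapply(seq_len(d), function(k) .split_rhat(draws[, , k]), numeric(1))
  if (any(rhat > 1.01))
    warning(sprintf("split-Rhat above 1.01 for: %s",
                    paste(def$pars[rhat > 1.01], collapse = ", ")),
            call. = FALSE)
  flat <- matrix(aperm(draws, c(1, 2, 3)), nc * ni, d)
  colnames(flat) <- def$pars
  list(draws = flat, chain = rep(seq_len(nc), each = ni),
       acceptance = acc_post / ni, rhat = stats::setNames(rhat, def$pars),
       model = model, pars = def$pars)
}

# moment-matched Beta pseudo-prior parameters from posterior draws
.beta_match <- function(draws) {
  fit1 <- function(m, v) {
    v <- max(v, 1e-6)
    # cap the concentration, not the shapes, so the matched mean survives
    kappa <- min(max(m * (1 - m) / v - 1, 0.2), 1e4)
    c(shape1 = max(m * kappa, 0.5), shape2 = max((1 - m) * kappa, 0.5))
  }
  t(vapply(seq_len(ncol(draws)),
           function(k) fit1(mean(draws[, k]), stats::var(draws[, k])),
           numeric(2)))
}

# pseudo-priors are defensive mixtures, 90% moment-matched Beta plus 10%
# uniform: the uniform floor keeps the density bounded below so a poor
# Beta fit (e.g. on a ridge-shaped posterior) cannot trap the model
# indicator
.PSEUDO_DEF <- 0.1

.dpseudo <- function(theta, ab, log = TRUE) {
  d <- (1 - .PSEUDO_DEF) * stats::dbeta(theta, ab[, 1], ab[, 2]) + .PSEUDO_DEF
  s <- sum(log(d))
  if (log) s else exp(s)
}

.rpseudo <- function(ab) {
  k <- nrow(ab)
  use_beta <- stats::runif(k) > .PSEUDO_DEF
  ifelse(use_beta, stats::rbeta(k, ab[, 1], ab[, 2]), stats::runif(k))
}

# importance-sampling pilot estimate of the log marginal likelihood using
# the pseudo-prior as proposal (flat prior cancels); used only to tune the
# sampler's internal prior model odds
.lml_is <- function(data, def, ab, n_is = 4000) {
  k <- nrow(ab)
  th <- matrix(stats::rbeta(n_is * k, rep(ab[, 1], each = n_is),
                            rep(ab[, 2], each = n_is)), n_is, k)
  unif <- matrix(stats::runif(n_is * k) < .PSEUDO_DEF, n_is, k)
  th[unif] <- stats::runif(sum(unif))
  lw <- vapply(seq_len(n_is), function(j) {
    def$loglik(th[j, ], data) - .dpseudo(th[j, ], ab)
  }, numeric(1))
  .logsumexp(lw) - log(n_is)
}

#' Bayes factor by the product space method
#'
#' Runs a transdimensional Gibbs/Metropolis sampler over the joint space
#' of a model indicator and both models' parameters. Inactive parameters
#' are drawn from Beta pseudo-priors moment-matched to single-model pilot
#' posteriors. The sampler internally tunes its prior model odds (from an
#' importance-sampling pilot) so both models are visited even for very
#' decisive data, and corrects the reported Bayes factor back to the equal
#' prior model probabilities of the analysis plan, `p(M1) = p(M2) = 0.5`.
#'
#' @param data CCEI dataset (`retention_interval_s`, `ccei`).
#' @param config A [mcmc_config()] for the product-space chain; pilot runs
#'   use a quarter of its iterations.
#' @param seed Optional integer seed.
#' @return List of class `mavc_bf`: `bf10` (exponential over null),
#'   `log_bf10`, `mc_error` (relative Monte-Carlo error), `method`,
#'   `diagnostics` (model visit counts per chain, pilot Rhats, tuning
#'   odds).
#' @export
bf_product_space <- function(data, config = mcmc_config(), seed = NULL) {
  .check_ccei_data(data)
  if (nrow(data) == 0L)
    return(structure(list(bf10 = 1, log_bf10 = 0, mc_error = 0,
                          method = "product-space",
                          diagnostics = list(note = "empty data: prior odds")),
                     class = "mavc_bf"))
  .seed_scope(seed)
  def1 <- .model_def("exponential")
  def2 <- .model_def("null")
  pilot_cfg <- mcmc_config(2, max(500, config$n_iter %/% 4), max(250, config$n_warmup %/% 2))
  # short pilots only shape the pseudo-priors; their Rhat need not be tight
  pilot1 <- suppressWarnings(sample_posterior(data, "exponential", pilot_cfg))
  pilot2 <- suppressWarnings(sample_posterior(data, "null", pilot_cfg))
  ab1 <- .beta_match(pilot1$draws)
  ab2 <- .beta_match(pilot2$draws)
  # initial internal prior odds log(p_int(M2)/p_int(M1)): give the null
  # extra prior weight when the exponential marginal likelihood dominates
  # (and vice versa), so the indicator keeps moving even for decisive data
  lpo <- max(min(.lml_is(data, def1, ab1) - .lml_is(data, def2, ab2), 500), -500)
  sc1 <- pmax(apply(pilot1$draws, 2, stats::sd), 1e-3)
  sc2 <- pmax(apply(pilot2$draws, 2, stats::sd), 1e-3)
  nc <- config$n_chains; ni <- config$n_iter; nw <- config$n_warmup
  run_chain <- function(lpo, n_burn, n_keep, adapt = FALSE) {
    th1 <- colMeans(pilot1$draws); ll1 <- def1$loglik(th1, data)
    th2 <- colMeans(pilot2$draws); ll2 <- def2$loglik(th2, data)
    M <- 1L
    keep <- integer(n_keep)
    win <- c(0L, 0L)
    for (it in seq_len(n_burn + n_keep)) {
      if (M == 1L) {  # update active exponential parameters, refresh null
        for (k in 1:4) {
          prop <- th1; prop[k] <- .reflect01(th1[k] + 2.4 * sc1[k] * stats::rnorm(1))
          llp <- def1$loglik(prop, data)
          if (is.finite(llp) && log(stats::runif(1)) < llp - ll1) { th1 <- prop; ll1 <- llp }
        }
        th2 <- .rpseudo(ab2); ll2 <- def2$loglik(th2, data)
      } else {
        for (k in 1:2) {
          prop <- th2; prop[k] <- .reflect01(th2[k] + 2.4 * sc2[k] * stats::rnorm(1))
          llp <- def2$loglik(prop, data)
          if (is.finite(llp) && log(stats::runif(1)) < llp - ll2) { th2 <- prop; ll2 <- llp }
        }
        th1 <- .rpseudo(ab1); ll1 <- def1$loglik(th1, data)
      }
      lp1 <- ll1 + .dpseudo(th2, ab2)            # + log p_int(M1), folded into lpo
      lp2 <- lpo + ll2 + .dpseudo(th1, ab1)
      M <- if (log(stats::runif(1)) < lp1 - .logsumexp(c(lp1, lp2))) 1L else 2L
      if (adapt && it <= n_burn) {
        win[M] <- win[M] + 1L
        if (it %% 100L == 0L) {
          lpo <- lpo + log((win[1] + 1) / (win[2] + 1))  # push toward balance
          win <- c(0L, 0L)
        }
      }
      if (it > n_burn) keep[it - n_burn] <- M
    }
    list(ind = keep, lpo = lpo)
  }
  # warmup phase: refine the tuning odds on a preliminary chain, then
  # freeze them for the counting chains
  lpo <- run_chain(lpo, n_burn = 2L * nw, n_keep = 0L, adapt = TRUE)$lpo
  ind <- vapply(seq_len(nc), function(ch) run_chain(lpo, nw, ni)$ind,
                integer(ni))
  n1 <- sum(ind == 1L); n2 <- sum(ind == 2L)
  if (n1 == 0L || n2 == 0L)
    .stopf(paste("product-space chain never visited model %s;",
                 "retune pseudo-priors or increase iterations"),
           if (n1 == 0L) "1 (exponential)" else "2 (null)")
  log_bf <- log(n1) - log(n2) + lpo
  # relative MC error from batch means of the model indicator
  nb <- 10L
  bsize <- ni %/% nb
  p_batch <- as.vector(vapply(seq_len(nb), function(b) {
    colMeans(ind[((b - 1) * bsize + 1):(b * bsize), , drop = FALSE] == 1L)
  }, numeric(nc)))
  p_hat <- n1 / (n1 + n2)
  se_p <- stats::sd(p_batch) / sqrt(length(p_batch))
  mc_error <- se_p / max(p_hat * (1 - p_hat), 1e-12)
  structure(list(
    bf10 = exp(log_bf), log_bf10 = log_bf, mc_error = mc_error,
    method = "product-space",
    diagnostics = list(
      visits = c(exponential = n1, null = n2),
      visits_by_chain = colSums(ind == 1L),
      tuning_log_prior_odds = lpo,
      pilot_rhat = list(exponential = pilot1$rhat, null = pilot2$rhat))),
    class = "mavc_bf")
}

#' @export
print.mavc_bf <- function(x, ...) {
  cat(sprintf("Bayes factor (BF10): %.4g  [log BF10 = %.3f]\n",
              x$bf10, x$log_bf10))
  cat(sprintf("method: %s; relative MC error: %.3g\n", x$method, x$mc_error))
  invisible(x)
}

# vectorised log likelihood over a G x d grid of parameter vectors
.loglik_grid <- function(theta, model, data, chunk = 20000L) {
  n <- nrow(data)
  G <- nrow(theta)
  x <- data$ccei
  t_ri <- data$retention_interval_s
  out <- numeric(G)
  for (s in seq(1L, G, by = chunk)) {
    idx <- s:min(s + chunk - 1L, G)
    th <- theta[idx, , drop = FALSE]
    if (model == "exponential") {
      mu <- th[, 1] + (1 - th[, 1]) * th[, 2] * exp(-outer(th[, 3], t_ri))
      sg <- th[, 4]
    } else {
      mu <- matrix(th[, 1], length(idx), n)
      sg <- th[, 2]
    }
    xm <- matrix(x, length(idx), n, byrow = TRUE)
    # sd recycles down columns, i.e. per grid row, because nrow(mu) = |idx|
    ld <- stats::dnorm(xm, mu, sg, log = TRUE) -
      log(stats::pnorm((1 - mu) / sg) - stats::pnorm(-mu / sg))
    out[idx] <- rowSums(ld)
  }
  out
}

#' Marginal likelihood by adaptive tensor quadrature
#'
#' Integrates the likelihood over the unit hypercube (flat priors) with a
#' tensor Gauss-Legendre rule on a box centred on the posterior mode
#' (found by bounded optimisation) and spanning 10 mode-curvature
#' standard deviations per dimension, clipped to \[0, 1\]. Two node
#' counts are compared; the rule is refined if they disagree by more than
#' `rel_tol` on the log scale. Serves as the independent oracle for
#' [bf_product_space()].
#'
#' @param data CCEI dataset (`retention_interval_s`, `ccei`).
#' @param model `"exponential"` or `"null"`.
#' @param rel_tol Relative tolerance of the refinement check.
#' @param log Return the log marginal likelihood (recommended for large
#'   datasets, where the raw value overflows).
#' @return Marginal likelihood (or its log). With zero rows of data the
#'   empty product gives 1.
#' @export
marginal_likelihood_quadrature <- function(data, model = c("exponential", "null"),
                                           rel_tol = 0.01, log = FALSE) {
  model <- match.arg(model)
  .check_ccei_data(data)
  if (nrow(data) == 0L) return(if (log) 0 else 1)
  def <- .model_def(model)
  d <- length(def$pars)
  eps <- 1e-5
  # small datasets have broad (for n = 1 even mode-free: the sigma -> 0
  # spike is integrable but unbounded) likelihoods: integrate the full
  # unit box; larger datasets concentrate and get a mode-centred box
  use_full_box <- nrow(data) < 20
  lo <- rep(0, d); hi <- rep(1, d)
  if (!use_full_box) {
    nll <- function(th) -def$loglik(th, data)
    starts <- list(rep(0.5, d))
    if (model == "exponential") {
      starts <- c(starts, list(c(0.4, 0.9, 0.3, max(min(stats::sd(data$ccei), 0.9), 0.02)),
                               c(mean(data$ccei), 0.5, 0.05,
                                 max(min(stats::sd(data$ccei), 0.9), 0.02))))
    } else {
      starts <- c(starts, list(c(max(min(mean(data$ccei), 1 - eps), eps),
                                 max(min(stats::sd(data$ccei), 0.9), 0.02))))
    }
    fits <- lapply(starts, function(s0) {
      tryCatch(stats::optim(s0, nll, method = "L-BFGS-B",
                            lower = rep(eps, d), upper = rep(1 - eps, d),
                            hessian = TRUE),
               error = function(e) NULL)
    })
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
    if (length(fits) == 0L) {
      use_full_box <- TRUE
    } else {
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      # per-dimension curvature widths; ridge-flat dimensions fall back
      # to a wide box on their own without widening the sharp ones
      hs <- suppressWarnings(
        tryCatch(sqrt(diag(solve(fit$hessian))),
                 error = function(e) rep(NA_real_, d)))
      sds <- ifelse(is.finite(hs) & hs > 0, pmin(pmax(hs, 1e-4), 0.5), 0.3)
      lo <- pmax(0, fit$par - 10 * sds)
      hi <- pmin(1, fit$par + 10 * sds)
    }
  }
  quad <- function(k) {
    gl <- lapply(seq_len(d), function(j) pracma::gaussLegendre(k, lo[j], hi[j]))
    grid <- as.matrix(expand.grid(lapply(gl, `[[`, "x")))
    lw <- rowSums(as.matrix(expand.grid(lapply(gl, function(g) log(g$w)))))
    .logsumexp(.loglik_grid(grid, model, data) + lw)
  }
  ks <- if (use_full_box && d <= 2) c(64, 96)
        else if (d <= 2) c(48, 64) else c(16, 24)
  l1 <- quad(ks[1]); l2 <- quad(ks[2])
  if (abs(l1 - l2) > rel_tol) l2 <- quad(if (d <= 2) 128 else 32)
  if (log) l2 else exp(l2)
}

#' Bayes factor by quadrature
#'
#' Ratio of the two models' marginal likelihoods computed by
#' [marginal_likelihood_quadrature()]; deterministic companion to the
#' product-space estimate.
#'
#' @inheritParams bf_product_space
#' @return List of class `mavc_bf` with `bf10`, `log_bf10`, `method`.
#' @export
bf_quadrature <- function(data) {
  l1 <- marginal_likelihood_quadrature(data, "exponential", log = TRUE)
  l2 <- marginal_likelihood_quadrature(data, "null", log = TRUE)
  structure(list(bf10 = exp(l1 - l2), log_bf10 = l1 - l2, mc_error = 0,
                 method = "quadrature",
                 diagnostics = list(log_ml = c(exponential = l1, null = l2))),
            class = "mavc_bf")
}
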