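# Independent oracles and fixture builders used across the test files.

# the canonical two-observation crossing fixture: each chosen bundle is
# strictly cheaper at the other observation's prices, giving a mutual
# strict preference cycle with breakpoint 1/3
two_obs_fixture <- function() {
  observation_set(x = rbind(c(0, 100 / 3), c(100 / 3, 0)),
                  p = rbind(c(1, 3), c(3, 1)))
}

# a random observation set built from genuine budget-line choice sets
random_obs <- function(n = 8) {
  b <- generate_block("oracle", t = 0, n_trials = n)
  b$choice_index <- sample.int(5L, n, replace = TRUE)
  block_observations(b)
}

# brute-force Houtman-Maks: try every subset of observations
hmi_brute_force <- function(obs) {
  n <- obs$n
  for (k in 0:(n - 1)) {
    subsets <- if (k == 0) matrix(integer(0), 0, 1) else utils::combn(n, k)
    for (s in seq_len(ncol(subsets))) {
      keep <- setdiff(seq_len(n), subsets[, s])
      sub <- observation_set(obs$x[keep, , drop = FALSE],
                             obs$p[keep, , drop = FALSE], obs$m[keep])
      if (nrow(garp_violations(sub)) == 0L) return(k)
    }
  }
  n
}

# brute-force tau-b from explicit pair counts
tau_b_brute_force <- function(u, v) {
  n <- length(u)
  conc <- disc <- tie_u <- tie_v <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    du <- u[i] - u[j]; dv <- v[i] - v[j]
    if (du == 0 && dv == 0) { tie_u <- tie_u + 1; tie_v <- tie_v + 1 }
    else if (du == 0) tie_u <- tie_u + 1
    else if (dv == 0) tie_v <- tie_v + 1
    else if (sign(du) == sign(dv)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_u) * (n0 - tie_v))
}

# truncated-normal density on [0, 1] for quadrature checks
dtnorm01 <- function(x, mu, sigma) {
  stats::dnorm(x, mu, sigma) /
    (stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma))
}
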