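# Synthetic participants and datasets: uniform-random choosers for the
# task-sensitivity simulation, utility-based choosers with logit noise for
# property tests, forgetting-curve CCEI datasets, and reconstruction-task
# data with the study's qualitative error structure.

#' Simulate uniform-random virtual participants
#'
#' Each virtual participant receives one freshly generated block of choice
#' sets and picks uniformly at random among the five options — the
#' task-sensitivity benchmark of the study design.
#'
#' @param n Number of virtual participants (1000 in the study).
#' @param n_trials Choice sets per participant (20 in the study).
#' @param seed Optional integer seed.
#' @return Data frame of trials (schema [trials_schema()]) with
#'   `choice_index` filled and `block_role = "sim"`.
#' @export
simulate_random_participants <- function(n = 1000, n_trials = 20, seed = NULL) {
  .seed_scope(seed)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    b <- generate_block(paste0("sim", i), t = stats::runif(1, 0, 30),
                        n_trials = n_trials, block_role = "sim")
    b$choice_index <- sample.int(5L, n_trials, replace = TRUE)
    blocks[[i]] <- b
  }
  do.call(rbind, blocks)
}

#' Chooser specification for simulated blocks
#'
#' @param kind `"random"`, `"linear-utility"` or `"noisy-utility"`.
#' @param w Weight on X-axis similarity tokens, in \[0, 1\].
#' @param noise_sd Scale of Gumbel (logit) utility noise, `>= 0`;
#'   `noise_sd = 0` reduces noisy-utility to the deterministic maximiser.
#' @return A `chooser_spec` list.
#' @export
chooser_spec <- function(kind = c("linear-utility", "noisy-utility", "random"),
                         w = 0.5, noise_sd = 0) {
  kind <- match.arg(kind)
  .check_prob01(w, "w")
  if (noise_sd < 0) .stopf("`noise_sd` must be >= 0")
  structure(list(kind = kind, w = w, noise_sd = noise_sd),
            class = "chooser_spec")
}

#' Simulate one block chosen by a utility-based (or random) chooser
#'
#' The noisy-utility chooser picks the option maximising
#' `w * x_x + (1 - w) * x_y + noise_sd * Gumbel`; ties break to the lowest
#' option index. A noiseless monotone maximiser is GARP-consistent by
#' construction (Afriat direction), which the test suite exploits.
#'
#' @param spec A [chooser_spec()].
#' @param t Retention interval in seconds.
#' @param participant_id,n_trials,seed Passed to [generate_block()].
#' @return A block data frame with `choice_index` filled.
#' @export
simulate_chooser_block <- function(spec, t = 0, participant_id = "chooser",
                                   n_trials = 20, seed = NULL) {
  stopifnot(inherits(spec, "chooser_spec"))
  .seed_scope(seed)
  b <- generate_block(participant_id, t, n_trials)
  if (spec$kind == "random") {
    b$choice_index <- sample.int(5L, n_trials, replace = TRUE)
    return(b)
  }
  xs <- as.matrix(b[paste0("opt", 1:5, "_x")])
  ys <- as.matrix(b[paste0("opt", 1:5, "_y")])
  u <- spec$w * xs + (1 - spec$w) * ys
  if (spec$kind == "noisy-utility" && spec$noise_sd > 0)
    u <- u + spec$noise_sd * (-log(-log(stats::runif(length(u)))))
  b$choice_index <- apply(u, 1L, which.max)
  b
}

# inverse-CDF sampler for Normal(mu, sd) truncated to [0, 1]
.rtruncnorm01 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(1, mu, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sd)
}

#' Simulate a CCEI-versus-retention-interval dataset
#'
#' Retention intervals are uniform on \[0, 30\] s and CCEI observations
#' follow a \[0, 1\]-truncated normal around the exponential forgetting
#' mean [mu_exponential()]. Defaults are the illustration parameters of
#' the study design (`a = 0.4`, `b = 0.9`, `alpha = 0.3`, `sigma = 0.1`,
#' `n = 300`).
#'
#' @param a,b,alpha Exponential forgetting parameters, each in \[0, 1\].
#' @param sigma Observation noise sd, in (0, 1\].
#' @param n Number of simulated participants/blocks.
#' @param seed Optional integer seed.
#' @return Data frame: `participant_id`, `retention_interval_s`, `ccei`.
#' @export
simulate_ccei_dataset <- function(a = 0.4, b = 0.9, alpha = 0.3, sigma = 0.1,
                                  n = 300, seed = NULL) {
  for (nm in c("a", "b", "alpha", "sigma")) .check_prob01(get(nm), nm)
  if (sigma <= 0) .stopf("`sigma` must be > 0")
  .seed_scope(seed)
  t <- stats::runif(n, 0, 30)
  mu <- mu_exponential(t, a, b, alpha)
  data.frame(participant_id = paste0("p", seq_len(n)),
             retention_interval_s = t,
             ccei = .rtruncnorm01(n, mu, sigma))
}

#' Reconstruction-task generator specification
#'
#' Defaults are calibrated so that at the main-task presentation time of
#' 5 s the expected share of perfect responses, averaged over retention
#' intervals 1, 5, 10 and 30 s, is 42%; the error magnitude grows with the
#' retention interval and shrinks with presentation time, giving the
#' strongly right-skewed error distribution the task produces.
#'
#' @param p_perfect Function `(t, pt) ->` probability of an exact
#'   response.
#' @param error_scale Function `(t, pt) ->` half-normal scale in degrees
#'   for non-perfect responses.
#' @return A `recon_spec` list.
#' @export
recon_spec <- function(
    p_perfect = function(t, pt) stats::plogis(0.698 + 0.6 * log(pt / 5) - 0.5 * log1p(t)),
    error_scale = function(t, pt) 12 * (1 + 0.35 * log1p(t)) / (1 + 0.4 * log1p(pt / 5))) {
  structure(list(p_perfect = p_perfect, error_scale = error_scale),
            class = "recon_spec")
}

#' Simulate reconstruction-task trials
#'
#' For every factorial cell of retention interval x presentation time,
#' draws trials whose response either matches the exemplar exactly (with
#' probability `p_perfect(t, pt)`) or deviates by a signed half-normal
#' error of scale `error_scale(t, pt)` degrees, wrapped to \[0, 360).
#'
#' @param spec A [recon_spec()].
#' @param n_per_cell Trials per factorial cell (10 in the pilot design).
#' @param RIs,PTs Retention intervals and presentation times in seconds.
#' @param participant_id Identifier stored with the trials.
#' @param seed Optional integer seed.
#' @return Data frame: `participant_id`, `presentation_time_s`,
#'   `retention_interval_s`, `axis`, `exemplar_deg`, `response_deg`.
#' @export
simulate_reconstruction <- function(spec = recon_spec(), n_per_cell = 10,
                                    RIs = c(1, 5, 10, 30), PTs = c(1, 5, 10, 30),
                                    participant_id = "sim", seed = NULL) {
  stopifnot(inherits(spec, "recon_spec"))
  .seed_scope(seed)
  cells <- expand.grid(t = RIs, pt = PTs)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    t <- cells$t[k]; pt <- cells$pt[k]
    ex <- sample(exemplar_orientations(), n_per_cell, replace = TRUE)
    perfect <- stats::runif(n_per_cell) < spec$p_perfect(t, pt)
    err <- abs(stats::rnorm(n_per_cell, 0, spec$error_scale(t, pt))) *
      sample(c(-1, 1), n_per_cell, replace = TRUE)
    err[perfect] <- 0
    out[[k]] <- data.frame(
      participant_id = participant_id, presentation_time_s = pt,
      retention_interval_s = t,
      axis = sample(c("X", "Y"), n_per_cell, replace = TRUE),
      exemplar_deg = ex, response_deg = .wrap360(ex + err))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
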