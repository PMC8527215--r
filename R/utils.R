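# internal helpers shared across modules

#' @keywords internal
.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# wrap angles to [0, 360)
.wrap360 <- function(deg) ((deg %% 360) + 360) %% 360

# set the RNG for the calling function's scope when a seed is supplied
.seed_scope <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      .stopf("`seed` must be a single finite number")
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# numerically safe log-sum-exp
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.check_prob01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    .stopf("`%s` must be a single number in [0, 1]", name)
  invisible(x)
}
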