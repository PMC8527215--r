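# Revealed-preference relations, GARP testing and the critical cost
# efficiency index (CCEI) for blocks of MAVC observations.
#
# An observation i is a chosen bundle x_i at prices p_i with budget m_i
# (the chooser spends the whole budget, x_i . p_i = m_i). Bundle x_i is
# directly revealed preferred to x_j (x_i R_D x_j) when x_j was affordable
# at i's prices (x_j . p_i <= m_i) and the bundles differ; strictly so
# (x_i P_D x_j) when x_j was strictly cheaper. R is the transitive closure
# of R_D. GARP requires that x_i R x_j never co-occurs with x_j P_D x_i.
#
# The CCEI is the largest uniform budget deflation e under which the
# relaxed relations (affordability compared against e * m_i) satisfy GARP.

# affordability tolerance: absorbs float noise from the budget-line
# construction; knife-edge equality counts as affordable, not cheaper
.AFF_TOL <- 1e-9

#' Assemble an observation set
#'
#' @param x n x 2 matrix of chosen bundles (token values).
#' @param p n x 2 matrix of prices faced at each observation.
#' @param m Numeric vector of budgets (default `rowSums(x * p)`).
#' @return An object of class `mavc_obs` (list with `x`, `p`, `m`, `n`).
#' @export
observation_set <- function(x, p, m = NULL) {
  x <- rbind(x); p <- rbind(p)
  if (!is.numeric(x) || !is.numeric(p) || ncol(x) != 2L || ncol(p) != 2L ||
      nrow(x) != nrow(p) || nrow(x) < 1L)
    .stopf("`x` and `p` must be numeric n x 2 matrices with n >= 1")
  if (any(x < -1e-9) || any(p <= 0)) .stopf("bundles must be >= 0 and prices > 0")
  spent <- rowSums(x * p)
  if (is.null(m)) m <- spent
  if (length(m) != nrow(x) || any(abs(spent - m) > 1e-6 * pmax(1, m)))
    .stopf("every chosen bundle must exhaust its budget (x_i . p_i = m_i)")
  structure(list(x = unname(x), p = unname(p), m = as.numeric(m), n = nrow(x)),
            class = "mavc_obs")
}

#' Extract the observation set of chosen bundles from a block of trials
#'
#' @param block Data frame of trials (one block) with `choice_index` set.
#' @return An `mavc_obs` object.
#' @export
block_observations <- function(block) {
  ci <- block$choice_index
  if (any(is.na(ci))) .stopf("all trials need a `choice_index` before scoring")
  if (any(ci < 1 | ci > 5)) .stopf("`choice_index` must be in 1..5")
  idx <- cbind(seq_len(nrow(block)), ci)
  xs <- as.matrix(block[paste0("opt", 1:5, "_x")])[idx]
  ys <- as.matrix(block[paste0("opt", 1:5, "_y")])[idx]
  observation_set(cbind(xs, ys), cbind(block$price_x, block$price_y),
                  block$budget)
}

#' Cross-evaluation cost matrix
#'
#' `C[i, j] = x_j . p_i`: what bundle j would have cost at observation i's
#' prices. The diagonal equals the budgets.
#'
#' @param obs An `mavc_obs` object.
#' @return n x n numeric matrix.
#' @export
cost_matrix <- function(obs) {
  stopifnot(inherits(obs, "mavc_obs"))
  obs$p %*% t(obs$x)
}

# boolean transitive closure by repeated squaring
.closure <- function(A) {
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# which pairs of observations chose numerically identical bundles
.same_bundle <- function(obs) as.matrix(stats::dist(obs$x)) < 1e-12

#' Revealed-preference relations at a budget efficiency level
#'
#' At efficiency `e`, bundle j is (weakly) related from i when
#' `C[i, j] <= e * m_i` and the bundles differ, and strictly when
#' `C[i, j] < e * m_i`. With `literal = TRUE` the weak relation is kept at
#' `e = 1` and only the strict comparison is relaxed, reproducing the
#' printed relaxation formula of the study's preprocessing section; the
#' default relaxes both sides (Varian's canonical CCEI construction).
#'
#' @param obs An `mavc_obs` object.
#' @param e Efficiency level in \[0, 1\].
#' @param literal Use the literal single-sided relaxation variant.
#' @return List with logical matrices `RD`, `PD`, `R` and the level `e`.
#' @export
relations_at_efficiency <- function(obs, e = 1, literal = FALSE) {
  stopifnot(inherits(obs, "mavc_obs"))
  .check_prob01(e, "e")
  C <- cost_matrix(obs)
  same <- .same_bundle(obs)
  e_weak <- if (literal) 1 else e
  RD <- sweep(C, 1, e_weak * obs$m + .AFF_TOL, "<=") & !same
  PD <- sweep(C, 1, e * obs$m - .AFF_TOL, "<")
  diag(RD) <- FALSE
  diag(PD) <- FALSE
  list(RD = RD, PD = PD, R = .closure(RD), e = e)
}

#' GARP violations at an efficiency level
#'
#' @inheritParams relations_at_efficiency
#' @return Integer matrix with columns `i`, `j`, one row per ordered pair
#'   such that `x_i R x_j` and `x_j P_D x_i`; zero rows when GARP holds.
#' @export
garp_violations <- function(obs, e = 1, literal = FALSE) {
  rel <- relations_at_efficiency(obs, e, literal)
  v <- which(rel$R & t(rel$PD), arr.ind = TRUE)
  colnames(v) <- c("i", "j")
  v
}

# fast internal GARP check used inside searches (avoids rebuilding lists)
.garp_holds <- function(C, m, same, e, literal = FALSE) {
  e_weak <- if (literal) 1 else e
  RD <- sweep(C, 1, e_weak * m + .AFF_TOL, "<=") & !same
  PD <- sweep(C, 1, e * m - .AFF_TOL, "<")
  diag(RD) <- FALSE
  diag(PD) <- FALSE
  !any(.closure(RD) & t(PD))
}

#' Critical cost efficiency index (CCEI)
#'
#' The supremum of efficiency levels `e` in \[0, 1\] at which the data
#' satisfy (relaxed) GARP, located by bisection. 1 means perfectly
#' consistent; values near 0 mean budgets must be deflated almost entirely
#' to rationalise the choices.
#'
#' @inheritParams relations_at_efficiency
#' @param tol Bisection tolerance.
#' @return A number in \[0, 1\].
#' @export
ccei <- function(obs, tol = 1e-6, literal = FALSE) {
  stopifnot(inherits(obs, "mavc_obs"))
  C <- cost_matrix(obs)
  same <- .same_bundle(obs)
  if (.garp_holds(C, obs$m, same, 1, literal)) return(1)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.garp_holds(C, obs$m, same, mid, literal)) lo <- mid else hi <- mid
  }
  lo
}

#' Exact CCEI by breakpoint enumeration
#'
#' The violation pattern can only change at the cost ratios
#' `C[i, j] / m_i`, so the exact CCEI is the largest such candidate at
#' which GARP holds. Serves as the independent oracle for [ccei()].
#'
#' @inheritParams relations_at_efficiency
#' @return A number in \[0, 1\].
#' @export
ccei_breakpoint <- function(obs, literal = FALSE) {
  stopifnot(inherits(obs, "mavc_obs"))
  C <- cost_matrix(obs)
  same <- .same_bundle(obs)
  m <- obs$m
  if (.garp_holds(C, m, same, 1, literal)) return(1)
  cand <- sweep(C, 1, m, "/")
  diag(cand) <- NA
  cand <- sort(unique(c(cand[is.finite(cand) & cand > 0 & cand <= 1], 1)))
  # monotone: find the first failing breakpoint by binary search
  lo <- 1L; hi <- length(cand); first_fail <- length(cand)
  best <- 0
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (.garp_holds(C, m, same, cand[mid], literal)) {
      best <- cand[mid]; lo <- mid + 1L
    } else {
      first_fail <- mid; hi <- mid - 1L
    }
  }
  # the supremum is the first failing candidate when the violation only
  # arises exactly at that level (an arriving weak edge), and the last
  # holding candidate when it already fails just above the latter
  between <- (best + cand[first_fail]) / 2
  if (.garp_holds(C, m, same, between, literal)) cand[first_fail] else best
}

#' Count choices involved in GARP violations
#'
#' @inheritParams relations_at_efficiency
#' @param count `"observations"` (default): distinct observations appearing
#'   in at least one violating ordered pair; `"pairs"`: number of violating
#'   ordered pairs.
#' @return Integer count.
#' @export
count_inconsistent_choices <- function(obs, literal = FALSE,
                                       count = c("observations", "pairs")) {
  count <- match.arg(count)
  v <- garp_violations(obs, 1, literal)
  if (count == "pairs") nrow(v) else length(unique(as.vector(v)))
}
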