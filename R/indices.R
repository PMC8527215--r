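# Alternative consistency indices: Houtman-Maks, money pump, minimum cost.
# All operate on the e = 1 revealed-preference relations.

.obs_subset <- function(obs, keep) {
  observation_set(obs$x[keep, , drop = FALSE], obs$p[keep, , drop = FALSE],
                  obs$m[keep])
}

# vertices lying on a directed cycle of RD; any minimal removal set that
# restores GARP is a subset of these (an acyclic vertex is on no violating
# cycle, so deleting it cannot clear one)
.cycle_vertices <- function(R) {
  both <- R & t(R)
  diag(both) <- FALSE
  which(rowSums(both) > 0)
}

#' Houtman-Maks index
#'
#' Minimal number of observations whose removal leaves the remainder
#' GARP-consistent. Searched exactly by iterative deepening over subsets
#' of the observations lying on revealed-preference cycles; beyond
#' `node_budget` candidate subsets a greedy most-violations-first removal
#' is used and flagged with `exact = FALSE`.
#'
#' @param obs An `mavc_obs` object.
#' @param node_budget Maximum number of candidate subsets to test exactly.
#' @return List with `removed` (integer), `fraction` (`removed / n`) and
#'   `exact` (logical).
#' @export
houtman_maks <- function(obs, node_budget = 2e5) {
  stopifnot(inherits(obs, "mavc_obs"))
  v <- garp_violations(obs)
  if (nrow(v) == 0L) return(list(removed = 0L, fraction = 0, exact = TRUE))
  rel <- relations_at_efficiency(obs, 1)
  cand <- .cycle_vertices(rel$R)
  tested <- 0
  for (k in seq_along(cand)) {
    n_sub <- choose(length(cand), k)
    if (tested + n_sub > node_budget) break
    tested <- tested + n_sub
    subs <- utils::combn(cand, k)
    for (s in seq_len(ncol(subs))) {
      keep <- setdiff(seq_len(obs$n), subs[, s])
      if (length(keep) == 0L ||
          nrow(garp_violations(.obs_subset(obs, keep))) == 0L)
        return(list(removed = k, fraction = k / obs$n, exact = TRUE))
    }
  }
  # greedy fallback: repeatedly drop the observation in most violating pairs
  removed <- integer(0)
  keep <- seq_len(obs$n)
  repeat {
    sub <- .obs_subset(obs, keep)
    vv <- garp_violations(sub)
    if (nrow(vv) == 0L) break
    counts <- table(factor(as.vector(vv), levels = seq_along(keep)))
    drop_local <- which.max(counts)
    removed <- c(removed, keep[drop_local])
    keep <- keep[-drop_local]
  }
  list(removed = length(removed), fraction = length(removed) / obs$n,
       exact = FALSE)
}

# enumerate directed simple cycles of length 2..max_len in adjacency A,
# each cycle once (canonical form: starts at its smallest vertex)
.simple_cycles <- function(A, max_len) {
  n <- nrow(A)
  out <- list()
  path <- integer(max_len)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    if (depth >= 2L && A[v, start]) out[[length(out) + 1L]] <<- path[seq_len(depth)]
    if (depth == max_len) return(invisible(NULL))
    nxt <- which(A[v, ])
    for (w in nxt) if (w > start && !(w %in% path[seq_len(depth)])) dfs(start, w, depth + 1L)
    invisible(NULL)
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  out
}

#' Money pump index
#'
#' Enumerates simple GARP-violating cycles (cycles of the direct relation
#' containing at least one strict edge) up to `max_cycle_len` and averages
#' the money-pump cost of each: the fraction of the cycle's total
#' expenditure an arbitrager could extract,
#' `sum_k (x_k p_k - x_{k+1} p_k) / sum_k x_k p_k` with cyclic successor.
#'
#' @param obs An `mavc_obs` object.
#' @param max_cycle_len Maximum cycle length enumerated (default 3).
#' @return Mean money-pump cost in \[0, 1\]; 0 when no violating cycle.
#' @export
money_pump_index <- function(obs, max_cycle_len = 3) {
  stopifnot(inherits(obs, "mavc_obs"))
  if (max_cycle_len < 2) .stopf("`max_cycle_len` must be >= 2")
  rel <- relations_at_efficiency(obs, 1)
  C <- cost_matrix(obs)
  cycles <- .simple_cycles(rel$RD, min(max_cycle_len, obs$n))
  costs <- vapply(cycles, function(cy) {
    succ <- c(cy[-1], cy[1])
    if (!any(rel$PD[cbind(cy, succ)])) return(NA_real_)  # not violating
    sum(obs$m[cy] - C[cbind(cy, succ)]) / sum(obs$m[cy])
  }, numeric(1))
  costs <- costs[!is.na(costs)]
  if (length(costs) == 0L) 0 else mean(costs)
}

# edges of RD lying on a directed cycle, with their normalised slack weights
.cycle_edges <- function(rel, C, m) {
  on_cycle <- rel$RD & t(rel$R)
  idx <- which(on_cycle, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  w <- (m[idx[, 1]] - C[idx]) / m[idx[, 1]]
  list(idx = idx, w = w)
}

.garp_holds_matrices <- function(RD, PD) !any(.closure(RD) & t(PD))

#' Minimum cost index
#'
#' Weights each direct revealed-preference relation by its normalised
#' slack `(m_i - x_j p_i) / m_i` and finds the cheapest set of relations
#' whose deletion leaves no GARP-violating cycle, divided by the number of
#' observations. Exact by subset enumeration over cycle edges when there
#' are at most `max_exact_edges` of them; otherwise greedy cheapest-edge
#' cycle breaking, flagged with `exact = FALSE`.
#'
#' @param obs An `mavc_obs` object.
#' @param max_exact_edges Cap on cycle-edge count for exact enumeration.
#' @return List with `mci` in \[0, 1\] and `exact` (logical).
#' @export
minimum_cost_index <- function(obs, max_exact_edges = 15) {
  stopifnot(inherits(obs, "mavc_obs"))
  rel <- relations_at_efficiency(obs, 1)
  if (!any(rel$R & t(rel$PD))) return(list(mci = 0, exact = TRUE))
  C <- cost_matrix(obs)
  ce <- .cycle_edges(rel, C, obs$m)
  ne <- nrow(ce$idx)
  if (ne <= max_exact_edges) {
    best <- Inf
    for (mask in seq_len(2^ne) - 1L) {
      sel <- bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0
      cost <- sum(ce$w[sel])
      if (cost >= best) next
      RD2 <- rel$RD; PD2 <- rel$PD
      rm_idx <- ce$idx[sel, , drop = FALSE]
      RD2[rm_idx] <- FALSE
      PD2[rm_idx] <- FALSE
      if (.garp_holds_matrices(RD2, PD2)) best <- cost
    }
    return(list(mci = best / obs$n, exact = TRUE))
  }
  # greedy: remove the cheapest edge still on a cycle until GARP holds
  RD2 <- rel$RD; PD2 <- rel$PD
  total <- 0
  repeat {
    R2 <- .closure(RD2)
    if (!any(R2 & t(PD2))) break
    ce2 <- .cycle_edges(list(RD = RD2, R = R2), C, obs$m)
    if (is.null(ce2)) break
    k <- which.min(ce2$w)
    e_rm <- ce2$idx[k, , drop = FALSE]
    total <- total + ce2$w[k]
    RD2[e_rm] <- FALSE
    PD2[e_rm] <- FALSE
  }
  list(mci = total / obs$n, exact = FALSE)
}

#' Full consistency report for one block
#'
#' Runs every consistency index on the chosen bundles of a block.
#'
#' @param block Data frame of trials for one block, `choice_index` set.
#' @param literal Use the literal single-sided CCEI relaxation.
#' @param mpi_cycle_len Maximum money-pump cycle length.
#' @return One-row data frame: `ccei`, `n_violating_pairs`,
#'   `n_inconsistent_choices`, `hmi_removed`, `hmi_fraction`, `mpi`,
#'   `mci`, `hmi_exact`, `mci_exact`.
#' @export
consistency_report <- function(block, literal = FALSE, mpi_cycle_len = 3) {
  obs <- block_observations(block)
  v <- garp_violations(obs, literal = literal)
  hm <- houtman_maks(obs)
  mc <- minimum_cost_index(obs)
  data.frame(
    participant_id = block$participant_id[1],
    block_role = block$block_role[1],
    retention_interval_s = block$retention_interval_s[1],
    ccei = ccei(obs, literal = literal),
    n_violating_pairs = nrow(v),
    n_inconsistent_choices = length(unique(as.vector(v))),
    hmi_removed = hm$removed, hmi_fraction = hm$fraction,
    mpi = money_pump_index(obs, mpi_cycle_len),
    mci = mc$mci, hmi_exact = hm$exact, mci_exact = mc$exact)
}
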