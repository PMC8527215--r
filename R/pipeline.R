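# End-to-end orchestration: the task-sensitivity simulation, the
# train/test split, and the full preregistered analysis sequence with its
# quality controls.

#' Task-sensitivity simulation with uniform-random choosers
#'
#' Simulates `n` virtual participants choosing uniformly at random from
#' freshly constructed choice sets and summarises how sensitively the
#' design detects their inconsistency: share with at least one GARP
#' violation, median CCEI, shares below 0.90 and 0.80, median number of
#' inconsistent choices, and share of perfectly consistent participants.
#'
#' @param n Number of virtual participants (1000 in the study).
#' @param n_trials Choice sets per participant (20 in the study).
#' @param seed Optional integer seed.
#' @param literal Use the literal single-sided CCEI relaxation.
#' @return List with `summary` (named numeric vector; percentages on the
#'   0-100 scale) and `per_participant` (data frame with `ccei`,
#'   `n_violating_pairs`, `n_inconsistent_choices`).
#' @export
run_sensitivity <- function(n = 1000, n_trials = 20, seed = NULL,
                            literal = FALSE) {
  .seed_scope(seed)
  trials <- simulate_random_participants(n, n_trials)
  ids <- unique(trials$participant_id)
  res <- do.call(rbind, lapply(ids, function(id) {
    obs <- block_observations(trials[trials$participant_id == id, ])
    v <- garp_violations(obs, literal = literal)
    data.frame(participant_id = id,
               ccei = ccei(obs, literal = literal),
               n_violating_pairs = nrow(v),
               n_inconsistent_choices = length(unique(as.vector(v))))
  }))
  summary <- c(
    pct_with_violation = 100 * mean(res$n_violating_pairs > 0),
    median_ccei = stats::median(res$ccei),
    pct_ccei_below_090 = 100 * mean(res$ccei < 0.90),
    pct_ccei_below_080 = 100 * mean(res$ccei < 0.80),
    median_inconsistent_choices = stats::median(res$n_inconsistent_choices),
    pct_ccei_equal_1 = 100 * mean(res$ccei >= 1))
  list(summary = summary, per_participant = res)
}

#' Randomly split each participant's two blocks into train and test
#'
#' Per participant a fair coin assigns one block to the training set and
#' the other to the test set. Participants without exactly two blocks are
#' excluded with a warning. The assignment is recorded in the
#' `"assignment"` attribute.
#'
#' @param trials Data frame of trials with two blocks per participant.
#' @param seed Optional integer seed.
#' @return The trials with `block_role` remapped to `"train"`/`"test"`.
#' @export
split_train_test <- function(trials, seed = NULL) {
  .seed_scope(seed)
  out <- NULL
  log <- NULL
  for (id in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == id, ]
    roles <- unique(tr$block_role)
    if (length(roles) != 2L) {
      warning(sprintf("participant %s has %d block(s), expected 2; excluded",
                      id, length(roles)), call. = FALSE)
      next
    }
    train_role <- if (stats::runif(1) < 0.5) roles[1] else roles[2]
    tr$block_role <- ifelse(tr$block_role == train_role, "train", "test")
    out <- rbind(out, tr)
    log <- rbind(log, data.frame(participant_id = id, train_block = train_role))
  }
  if (is.null(out)) .stopf("no participant had exactly two blocks")
  attr(out, "assignment") <- log
  out
}

.consistency_by_block <- function(trials, role, literal, hmi_node_budget) {
  sub <- trials[trials$block_role == role, ]
  do.call(rbind, lapply(unique(sub$participant_id), function(id) {
    block <- sub[sub$participant_id == id, ]
    obs <- block_observations(block)
    v <- garp_violations(obs, literal = literal)
    hm <- houtman_maks(obs, node_budget = hmi_node_budget)
    mc <- minimum_cost_index(obs)
    data.frame(participant_id = id, block_role = role,
               retention_interval_s = block$retention_interval_s[1],
               ccei = ccei(obs, literal = literal),
               n_violating_pairs = nrow(v),
               n_inconsistent_choices = length(unique(as.vector(v))),
               hmi_removed = hm$removed, hmi_fraction = hm$fraction,
               mpi = money_pump_index(obs), mci = mc$mci,
               hmi_exact = hm$exact, mci_exact = mc$exact)
  }))
}

#' Run the full preregistered analysis sequence on a dataset
#'
#' Splits blocks into training and test sets, scores every consistency
#' index per block, tests H1 (one-sided Kendall's tau Bayes factor of
#' retention interval against CCEI in the training set), and — only if H1
#' finds strong support, per the interpretative plan — H2 (exponential
#' versus null forgetting model by the product space method) and H3 (the
#' replication Bayes factor on the held-out test set). Quality controls
#' always run: a classical rank-sum comparison of empirical CCEI against
#' an equal-sized sample of simulated random choosers (floor-effect
#' check), test-retest reliability of all four indices, the
#' manipulation-check summary of the reconstruction task, and the
#' task-difficulty bootstrap.
#'
#' @param trials Choice trials (two blocks per participant).
#' @param recon Reconstruction-task trials.
#' @param seed Integer seed controlling the split, the random-chooser
#'   control sample, the bootstrap and the MCMC.
#' @param config Optional list overriding defaults: `mcmc`
#'   ([mcmc_config()]), `n_boot`, `literal`, `hmi_node_budget`,
#'   `force_models` (run H2/H3 regardless of the H1 verdict).
#' @param out Optional path; when given the report is written as JSON.
#' @return Report list with elements `h1`, `h2`, `h3`, `consistency`,
#'   `quality`, `config`.
#' @export
run_full_analysis <- function(trials, recon, seed = 20210308, config = list(),
                              out = NULL) {
  cfg <- utils::modifyList(
    list(mcmc = mcmc_config(), n_boot = 10000, literal = FALSE,
         hmi_node_budget = 5000, force_models = FALSE), config)
  if (!all(trials_schema() %in% names(trials))) .stopf("trials schema mismatch")
  if (!all(.recon_cols() %in% names(recon))) .stopf("recon schema mismatch")
  split <- split_train_test(trials, seed = seed)
  train <- .consistency_by_block(split, "train", cfg$literal, cfg$hmi_node_budget)
  test <- .consistency_by_block(split, "test", cfg$literal, cfg$hmi_node_budget)

  h1_bf <- bf_kendall_onesided(train$retention_interval_s, train$ccei,
                               alternative = "negative")
  h1 <- list(tau = h1_bf$tau, bf10 = h1_bf$bf10, verdict = bf_verdict(h1_bf$bf10))

  h2 <- h3 <- NULL
  if (identical(h1$verdict, "strong support") || isTRUE(cfg$force_models)) {
    dtrain <- data.frame(participant_id = train$participant_id,
                         retention_interval_s = train$retention_interval_s,
                         ccei = train$ccei)
    dtest <- data.frame(participant_id = test$participant_id,
                        retention_interval_s = test$retention_interval_s,
                        ccei = test$ccei)
    bf_train <- bf_product_space(dtrain, cfg$mcmc, seed = seed + 1L)
    bf_comb <- bf_product_space(rbind(dtrain, dtest), cfg$mcmc, seed = seed + 2L)
    h2 <- list(bf10 = bf_train$bf10, mc_error = bf_train$mc_error,
               verdict = bf_verdict(bf_train$bf10))
    h3 <- list(bf_replication = replication_bf(bf_comb$bf10, bf_train$bf10),
               bf_combined = bf_comb$bf10,
               verdict = bf_verdict(replication_bf(bf_comb$bf10, bf_train$bf10)))
  }

  # floor-effect control: are participants more consistent than chance?
  rnd <- run_sensitivity(n = nrow(train), n_trials = 20, seed = seed + 3L,
                         literal = cfg$literal)
  wt <- stats::wilcox.test(train$ccei, rnd$per_participant$ccei,
                           alternative = "greater", exact = FALSE)
  reliability <- vapply(c("ccei", "hmi_fraction", "mpi", "mci"),
                        function(ix) test_retest(train, test, ix), numeric(1))
  errors <- circular_error(recon$exemplar_deg, recon$response_deg)
  increments <- c(increment_step(split$price_x, split$budget),
                  increment_step(split$price_y, split$budget))
  diff_boot <- bootstrap_difficulty(errors, increments, cfg$n_boot,
                                    seed = seed + 4L)
  quality <- list(
    floor_check = list(
      W = unname(wt$statistic), p_value = wt$p.value,
      median_empirical = stats::median(train$ccei),
      median_random = stats::median(rnd$per_participant$ccei),
      discernible_from_random = wt$p.value < 0.05),
    test_retest = as.list(reliability),
    manipulation = manipulation_summary(recon),
    difficulty = diff_boot[c("mean_diff", "ci95", "n_boot")])

  report <- list(
    seed = seed, n_participants = nrow(train),
    h1 = h1, h2 = h2, h3 = h3,
    consistency = list(train = train, test = test),
    quality = quality,
    config = cfg[c("n_boot", "literal", "hmi_node_budget", "force_models")])
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}
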