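test_that("risk groups take the top and bottom fractions with stable ties", {
  pi10 <- c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10)
  g <- assign_risk_groups(pi10, 0.40)
  expect_equal(sum(g == "high"), 4)
  expect_equal(sum(g == "low"), 4)
  expect_equal(sum(g == "unassigned"), 2)
  expect_true(all(pi10[g == "high"] > pi10[g == "unassigned"]))
  expect_true(all(pi10[g == "unassigned"] > pi10[g == "low"]))
  # all tied: groups filled in stable sample order, counts unchanged
  g_tied <- assign_risk_groups(rep(1, 10), 0.40)
  expect_equal(g_tied, rep(c("high", "unassigned", "low"), c(4, 2, 4)))
  # fraction 0.5 with n = 4: no unassigned middle
  expect_equal(sort(table(assign_risk_groups(c(4, 3, 2, 1), 0.5))),
               sort(table(c("high", "high", "low", "low"))), ignore_attr = TRUE)
  expect_error(assign_risk_groups(c(1, 2), 0.6), "fraction")
  expect_error(assign_risk_groups(1, 0.4), "too few")
})

test_that("Kaplan-Meier curve matches the product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.50, 0.25, 0))
  expect_equal(km$at_risk, c(4, 3, 2, 1))
  # all censored: no event times; step function constant at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0)
  expect_equal(km_survival_at(km0, c(0.5, 2.5)), c(1, 1))
  # censoring between events: (1, 2+, 3) -> 2/3 then 2/3 * (1 - 1/1) = 0
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("log-rank statistic matches the hand-worked 6-patient example", {
  # group A: events at 1, 2, censored at 3; group B: events at 4, 5,
  # censored at 6
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- c(0, 0, 0, 1, 1, 1)
  # step-by-step observed-minus-expected in group A and hypergeometric
  # variance, written out independently of the package
  oe <- 0; v <- 0
  for (t in unique(time[event == 1])) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n_tot <- sum(at_risk); n_a <- sum(at_risk & group == 0)
    oe <- oe + sum(time == t & event == 1 & group == 0) - d * n_a / n_tot
    if (n_tot > 1)
      v <- v + d * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  expected_chi2 <- oe^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi2, expected_chi2)
  expect_equal(lr$p, pchisq(expected_chi2, 1, lower.tail = FALSE))
  # two identical groups: no difference
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2), rep(0:1, each = 3))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)
  # symmetry in the group labels
  lr_sw <- logrank_test(time, event, 1 - group)
  expect_equal(lr_sw$chi2, lr$chi2)
  # invariance under monotone relabelling of time
  lr_mono <- logrank_test(log(time), event, group)
  expect_equal(lr_mono$chi2, lr$chi2)
})

test_that("log-rank p-value agrees with a permutation null", {
  set.seed(77)
  time <- c(rexp(25, 0.5), rexp(25, 0.8))
  event <- rbinom(50, 1, 0.8); event[1] <- 1L
  group <- rep(0:1, each = 25)
  obs <- logrank_test(time, event, group)$chi2
  n_perm <- 10000
  null <- vapply(seq_len(n_perm), function(i)
    logrank_test(time, event, sample(group))$chi2, numeric(1))
  p_perm <- mean(null >= obs)
  p_chi <- logrank_test(time, event, group)$p
  # within Monte-Carlo error plus a small allowance for the chi-square
  # reference being asymptotic (the permutation null is exact at finite n)
  mc_sd <- sqrt(max(p_perm * (1 - p_perm), 1e-4) / n_perm)
  expect_lt(abs(p_perm - p_chi), 3 * mc_sd + 0.02)
})

test_that("time-dependent AUC equals pair counting without censoring", {
  set.seed(55)
  n <- 40
  pi <- rnorm(n)
  time <- rexp(n, exp(pi))      # informative index
  event <- rep(1L, n)
  for (t in quantile(time, c(0.3, 0.5, 0.7))) {
    roc <- time_dependent_roc(pi, time, event, t)
    cases <- pi[time <= t]; ctrls <- pi[time > t]
    expect_equal(roc$auc, pair_count_auc(cases, ctrls), tolerance = 1e-10)
  }
  # perfect ordering: AUC 1 at every horizon with both classes present
  pi_perf <- -time
  roc_perf <- time_dependent_roc(pi_perf, time, event, median(time))
  expect_equal(roc_perf$auc, 1)
  # constant index: AUC 1/2 by the tie convention
  roc_const <- time_dependent_roc(rep(0, n), time, event, median(time))
  expect_equal(roc_const$auc, 0.5)
  # reversing the index flips the AUC
  roc_f <- time_dependent_roc(pi, time, event, median(time))
  roc_r <- time_dependent_roc(-pi, time, event, median(time))
  expect_equal(roc_r$auc, 1 - roc_f$auc, tolerance = 1e-10)
  expect_error(time_dependent_roc(pi, time, event, max(time) + 1), "follow-up")
  expect_error(time_dependent_roc(pi, time, event, min(time) / 2), "no events")
})

test_that("the KM and IPCW estimators are close under random censoring", {
  set.seed(56)
  n <- 200
  pi <- rnorm(n)
  t_ev <- rexp(n, exp(pi)); t_c <- rexp(n, 0.5)
  time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)
  t0 <- quantile(time[event == 1], 0.5)
  a_km <- time_dependent_roc(pi, time, event, t0, method = "km")$auc
  a_ipcw <- time_dependent_roc(pi, time, event, t0, method = "ipcw")$auc
  expect_lt(abs(a_km - a_ipcw), 0.05)
  expect_gt(a_km, 0.5)
})

test_that("auc_over_time applies the ROC estimator elementwise", {
  set.seed(57)
  n <- 30
  pi <- rnorm(n); time <- rexp(n, exp(pi)); event <- rep(1L, n)
  grid <- unname(quantile(time, c(0.3, 0.6)))
  res <- auc_over_time(pi, time, event, grid)
  expect_equal(res$auc, vapply(grid, function(t)
    time_dependent_roc(pi, time, event, t)$auc, numeric(1)))
})

test_that("gene ranking orders by coefficient magnitude, keeping signs", {
  rg <- rank_genes(c(g1 = 0.5, g2 = -2, g3 = 0.1))
  expect_equal(rg$gene, c("g2", "g1", "g3"))
  expect_equal(rg$beta, c(-2, 0.5, 0.1))
  expect_true(all(diff(rg$abs_beta) <= 0))
  # all-zero coefficients: stable gene order
  rg0 <- rank_genes(c(a = 0, b = 0, c = 0))
  expect_equal(rg0$gene, c("a", "b", "c"))
})

test_that("extreme-ranked genes carry the largest likelihood contributions", {
  sim <- make_dataset(sim_config(p = 40, n = 120, n_modules = 4,
                                 module_size = 10, seed = 81))
  fit <- netcox_fit(sim$dataset, penalty_matrix(sim$network, 0.1), 0.1)
  rg <- rank_genes(fit)
  # per-gene contribution: drop in partial likelihood when the gene's
  # coefficient is zeroed
  contrib <- vapply(sim$dataset$gene_ids, function(g) {
    b <- fit$beta; b[g] <- 0
    abs(partial_log_likelihood(fit$beta, sim$dataset) -
          partial_log_likelihood(b, sim$dataset))
  }, numeric(1))
  top <- utils::head(rg$gene, 10); bottom <- utils::tail(rg$gene, 10)
  expect_gt(mean(contrib[top]), mean(contrib[bottom]))
})

test_that("consensus ranking uses the best rank with documented tie-breaks", {
  mk <- function(genes) {
    structure(data.frame(rank = seq_along(genes), gene = genes,
                         beta = 0, abs_beta = 0, stringsAsFactors = FALSE),
              class = c("ranked_genes", "data.frame"))
  }
  # gene ranks (7, 2, 40) -> consensus score 2
  u <- paste0("g", 1:40)
  l1 <- mk(c(u[2:7], u[1], u[8:40]))         # g1 at rank 7
  l2 <- mk(c(u[5], u[1], u[2:4], u[6:40]))   # g1 at rank 2
  l3 <- mk(c(u[2:40], u[1]))                 # g1 at rank 40
  cons <- consensus_rank(list(l1, l2, l3))
  expect_equal(cons$score[cons$gene == "g1"], 2)
  # identical lists: output equals input order
  same <- consensus_rank(list(l1, l1))
  expect_equal(same$gene, l1$gene)
  # tie on the best rank: next-smallest rank decides
  a <- mk(c("x", "y", "z", "w")); b <- mk(c("y", "x", "w", "z"))
  # x: ranks (1, 2); y: ranks (2, 1) -> both best 1, both second 2 -> by id
  cons2 <- consensus_rank(list(a, b))
  expect_equal(cons2$gene[1:2], c("x", "y"))
  ties <- consensus_rank(list(mk(c("q", "r", "s")), mk(c("r", "s", "q"))))
  # q: (1, 3), r: (1, 2) -> r wins on the second-best rank
  expect_equal(ties$gene[1], "r")
  expect_error(consensus_rank(list(a, mk(c("x", "y", "z", "v")))), "universes")
})

test_that("overlap curves count the common top-k genes", {
  mk <- function(genes) {
    structure(data.frame(rank = seq_along(genes), gene = genes,
                         beta = 0, abs_beta = 0, stringsAsFactors = FALSE),
              class = c("ranked_genes", "data.frame"))
  }
  A <- mk(c("g1", "g2", "g3")); B <- mk(c("g2", "g3", "g4"))
  C <- mk(c("g3", "g2", "g5"))
  oc <- overlap_curve(list(A, B, C), k_max = 3)
  expect_equal(oc$fraction[3], 2 / 3)
  expect_equal(overlap_curve(list(A, A), k_max = 3)$fraction, rep(1, 3))
  D <- mk(c("g4", "g5", "g6"))
  expect_equal(overlap_curve(list(A, D), k_max = 3)$fraction, rep(0, 3))
  expect_error(overlap_curve(list(A, B), k_max = 10), "exceeds")
})

test_that("randomization assessment ignores the network at alpha = 1", {
  sim <- make_dataset(sim_config(p = 30, n = 50, n_modules = 3,
                                 module_size = 10, seed = 82))
  ra <- randomization_assessment(sim$dataset, sim$network, lambda = 0.1,
                                 alpha = 1, statistic = "loglik",
                                 n_random = 3, seed = 9)
  r <- ra$results[[1]]
  expect_equal(length(r$null), 3)
  expect_true(all(r$null == r$observed))
  # determinism
  ra2 <- randomization_assessment(sim$dataset, sim$network, lambda = 0.1,
                                  alpha = 1, statistic = "loglik",
                                  n_random = 3, seed = 9)
  expect_identical(ra2$results[[1]]$null, r$null)
})

test_that("true-network CVPL beats shuffled networks on smooth signal", {
  sim <- make_dataset(sim_config(p = 60, n = 80, n_modules = 6,
                                 module_size = 10, seed = 83))
  ra <- randomization_assessment(sim$dataset, sim$network, lambda = 0.1,
                                 alpha = 0.1, statistic = "cvpl",
                                 n_random = 8, seed = 10)
  r <- ra$results[[1]]
  expect_gt(r$observed, mean(r$null))
})

test_that("pooled KM curve lies between the two risk-group curves", {
  sim <- make_dataset(sim_config(p = 40, n = 120, n_modules = 4,
                                 module_size = 10, seed = 84))
  fit <- netcox_fit(sim$dataset, penalty_matrix(sim$network, 0.1), 0.1)
  pi <- prognostic_index(fit, sim$dataset$X)
  g <- assign_risk_groups(pi)
  km_all <- kaplan_meier(sim$dataset$time, sim$dataset$event)
  hi <- g == "high"; lo <- g == "low"
  km_hi <- kaplan_meier(sim$dataset$time[hi], sim$dataset$event[hi])
  km_lo <- kaplan_meier(sim$dataset$time[lo], sim$dataset$event[lo])
  tt <- km_all$time
  s_all <- km_survival_at(km_all, tt)
  s_hi <- km_survival_at(km_hi, tt)
  s_lo <- km_survival_at(km_lo, tt)
  # sanity, not exactness: allow small violations from discreteness
  expect_true(mean(s_hi <= s_all + 0.05) > 0.9)
  expect_true(mean(s_lo >= s_all - 0.05) > 0.9)
})
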