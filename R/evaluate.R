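#' Assign high/low risk groups from a prognostic index
#'
#' Labels the top `fraction` of patients by prognostic index as `"high"`
#' risk and the bottom `fraction` as `"low"` (default 40% each); the middle
#' remains `"unassigned"`. Group sizes are `floor(fraction * n)`. Ties in the
#' index are broken by stable sample order (first come, first placed), so the
#' split is deterministic.
#'
#' @param pi numeric prognostic index vector.
#' @param fraction group fraction in (0, 0.5].
#' @return Character vector of labels `"high"`, `"low"`, `"unassigned"`.
#' @export
assign_risk_groups <- function(pi, fraction = 0.40) {
  if (fraction <= 0 || fraction > 0.5) stop("`fraction` must be in (0, 0.5]")
  n <- length(pi)
  n_g <- floor(fraction * n)
  if (n_g < 1L) stop("too few samples for the requested group fraction")
  ord <- order(-pi, seq_len(n))  # descending PI, ties by stable sample order
  labels <- rep("unassigned", n)
  labels[ord[seq_len(n_g)]] <- "high"
  labels[ord[seq.int(n - n_g + 1L, n)]] <- "low"
  labels
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate (via `survival::survfit`), reported at the distinct
#' event times with at-risk counts. The curve is 1 before the first event;
#' `km_survival_at()` evaluates the step function at arbitrary times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return An object of class `surv_curve`: data frame with columns `time`,
#'   `survival`, `at_risk`, `n_event`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop("empty input")
  if (length(event) != length(time)) stop("`time`/`event` length mismatch")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  out <- data.frame(time = sf$time[keep], survival = sf$surv[keep],
                    at_risk = sf$n.risk[keep], n_event = sf$n.event[keep])
  structure(out, class = c("surv_curve", "data.frame"))
}

#' @rdname kaplan_meier
#' @param curve a `surv_curve`.
#' @param t times at which to evaluate the step function.
#' @export
km_survival_at <- function(curve, t) {
  c(1, curve$survival)[findInterval(t, curve$time) + 1L]
}

#' Two-group log-rank test
#'
#' Mantel log-rank statistic comparing the survival curves of two groups
#' (via `survival::survdiff`), with the p-value from a chi-square
#' distribution with one degree of freedom.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-level group labels (0/1 or any two values).
#' @return List with `chi2`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("`group` must have exactly two levels")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

km_subgroup_survival <- function(time, event, keep, t) {
  # KM survival at t within a subgroup; 1 when the subgroup is empty
  if (!any(keep)) return(1)
  km_survival_at(kaplan_meier(time[keep], event[keep]), t)
}

#' Time-dependent ROC curve for censored outcomes
#'
#' Cumulative/dynamic ROC at horizon `t`: cases are subjects with an event by
#' time t, controls are subjects event-free at t. Censoring is handled by the
#' Kaplan-Meier/Bayes-rule estimator: with M the prognostic index and S the
#' KM survival,
#' `sens(c, t) = (1 - S(t | M > c)) P(M > c) / (1 - S(t))` and
#' `spec(c, t) = S(t | M <= c) P(M <= c) / S(t)`,
#' where the conditional survival functions are KM estimates within the
#' threshold subgroups. Estimates are clipped to `[0, 1]`. A simpler
#' inverse-probability-of-censoring-weighted (IPCW) estimator is available
#' with `method = "ipcw"`. AUC(t) is the trapezoidal area under the ROC
#' curve over all observed cutoffs; with no censoring it equals the
#' empirical two-sample AUC (ties counted 1/2).
#'
#' @param pi prognostic index.
#' @param time,event survival data.
#' @param t evaluation horizon, within the observed follow-up.
#' @param method `"km"` (default) or `"ipcw"`.
#' @return An object of class `td_roc`: list with `t`, `cutoffs`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
time_dependent_roc <- function(pi, time, event, t, method = c("km", "ipcw")) {
  method <- match.arg(method)
  n <- length(pi)
  if (length(time) != n || length(event) != n) stop("length mismatch")
  if (t > max(time)) stop("`t` exceeds the observed follow-up")
  if (!any(time <= t & event == 1)) stop("no events by time t")
  cutoffs <- sort(unique(pi))
  if (method == "km") {
    St <- km_survival_at(kaplan_meier(time, event), t)
    if (St <= 0) stop("all samples have failed by time t; no controls")
    sens <- spec <- numeric(length(cutoffs))
    for (i in seq_along(cutoffs)) {
      cc <- cutoffs[i]
      hi <- pi > cc; lo <- !hi
      p_hi <- mean(hi)
      S_hi <- km_subgroup_survival(time, event, hi, t)
      S_lo <- km_subgroup_survival(time, event, lo, t)
      sens[i] <- (1 - S_hi) * p_hi / (1 - St)
      spec[i] <- S_lo * (1 - p_hi) / St
    }
  } else {
    # IPCW: weight events by 1/G(t_i^-), controls by 1/G(t); G = censoring KM
    Gfit <- kaplan_meier(time, 1 - event)
    G_at <- function(u) pmax(km_survival_at(Gfit, u), 1e-10)
    case <- time <= t & event == 1
    ctrl <- time > t
    w <- numeric(n)
    w[case] <- 1 / G_at(time[case] - 1e-12)
    w[ctrl] <- 1 / G_at(t)
    sens <- vapply(cutoffs, function(cc)
      sum(w[case & pi > cc]) / sum(w[case]), numeric(1))
    spec <- vapply(cutoffs, function(cc)
      sum(w[ctrl & pi <= cc]) / sum(w[ctrl]), numeric(1))
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # ROC polygon: (FPR, TPR) over cutoffs plus the (0,0) and (1,1) anchors;
  # rounding kills floating-point fuzz that would scramble the vertex order
  fpr <- round(c(1, 1 - spec, 0), 12)
  tpr <- round(c(1, sens, 0), 12)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(t = t, cutoffs = cutoffs, sensitivity = sens,
                 specificity = spec, auc = auc), class = "td_roc")
}

#' AUC(t) over a time grid
#'
#' Applies [time_dependent_roc] at each time in `t_grid` and collects the
#' areas under the curves.
#'
#' @inheritParams time_dependent_roc
#' @param t_grid evaluation horizons.
#' @return Data frame with columns `t` and `auc`.
#' @export
auc_over_time <- function(pi, time, event, t_grid, method = c("km", "ipcw")) {
  method <- match.arg(method)
  data.frame(t = t_grid, auc = vapply(t_grid, function(tt)
    time_dependent_roc(pi, time, event, tt, method = method)$auc, numeric(1)))
}

#' Rank genes by coefficient magnitude
#'
#' Orders genes by decreasing `|beta|`, keeping the signed coefficient so
#' hazard-increasing genes (beta > 0, over-expression indicating higher
#' hazard) remain identifiable. Magnitude ties are broken by stable gene
#' order.
#'
#' @param fit a `netcox_fit`, or a named coefficient vector.
#' @param gene_ids gene identifiers when `fit` is an unnamed vector.
#' @return An object of class `ranked_genes`: data frame with columns
#'   `rank`, `gene`, `beta`, `abs_beta`.
#' @export
rank_genes <- function(fit, gene_ids = NULL) {
  beta <- if (inherits(fit, "netcox_fit")) fit$beta else fit
  if (is.null(gene_ids)) gene_ids <- names(beta)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(beta))
  stopifnot_finite(beta, "beta")
  ord <- order(-abs(beta), seq_along(beta))
  out <- data.frame(rank = seq_along(beta), gene = gene_ids[ord],
                    beta = unname(beta[ord]), abs_beta = abs(unname(beta[ord])),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_genes", "data.frame"))
}

ranked_gene_positions <- function(rg) {
  stats::setNames(rg$rank, rg$gene)
}

#' Consensus gene ranking across datasets
#'
#' Re-ranks a shared gene universe by the best (lowest) rank each gene
#' attains across two or more per-dataset rankings. Ties on the best rank are
#' broken by the next-smallest rank, and finally by gene identifier.
#'
#' @param lists list of two or more `ranked_genes` over the same gene
#'   universe.
#' @return A `ranked_genes` data frame with columns `rank`, `gene`, `score`
#'   (the minimum per-dataset rank).
#' @export
consensus_rank <- function(lists) {
  if (length(lists) < 2L) stop("need at least two rankings")
  universe <- sort(lists[[1]]$gene)
  for (l in lists)
    if (!identical(sort(l$gene), universe)) stop("gene universes differ")
  ranks <- vapply(lists, function(l) ranked_gene_positions(l)[universe],
                  numeric(length(universe)))
  sorted <- t(apply(ranks, 1, sort))       # per-gene ranks, ascending
  ord <- do.call(order, c(lapply(seq_len(ncol(sorted)), function(j) sorted[, j]),
                          list(universe)))
  out <- data.frame(rank = seq_along(universe), gene = universe[ord],
                    score = sorted[ord, 1], stringsAsFactors = FALSE)
  structure(out, class = c("ranked_genes", "data.frame"))
}

#' Top-k overlap curve across rankings
#'
#' For each k up to `k_max`, the number of genes common to the top-k sets of
#' every ranking, as a fraction (and percentage) of k.
#'
#' @param lists list of `ranked_genes` over a shared universe.
#' @param k_max largest list size considered (default 300).
#' @return Data frame with columns `k`, `n_common`, `fraction`, `percent`.
#' @export
overlap_curve <- function(lists, k_max = 300L) {
  if (length(lists) < 2L) stop("need at least two rankings")
  p <- nrow(lists[[1]])
  if (k_max > p) stop("`k_max` exceeds the ranking length")
  tops <- lapply(lists, function(l) l$gene)
  n_common <- vapply(seq_len(k_max), function(k)
    length(Reduce(intersect, lapply(tops, utils::head, k))), numeric(1))
  data.frame(k = seq_len(k_max), n_common = n_common,
             fraction = n_common / seq_len(k_max),
             percent = 100 * n_common / seq_len(k_max))
}

top_k_overlap <- function(lists, k = 100L) {
  length(Reduce(intersect, lapply(lists, function(l) utils::head(l$gene, k)))) / k
}

#' Network-randomization significance assessment
#'
#' Compares a statistic computed with the true gene network against its null
#' distribution over networks whose edges have been shuffled
#' ([shuffle_edges]). Supported statistics: `"cvpl"` (cross-validated partial
#' likelihood, default 20 random networks), `"loglik"` (partial
#' log-likelihood of the full-data fit, default 50), and `"overlap"`
#' (top-`top_k` gene overlap across two or more datasets, default 50). At
#' `alpha = 1` the network is ignored and every null value equals the
#' observed one.
#'
#' @param ds a [survival_dataset], or a list of datasets for
#'   `statistic = "overlap"`.
#' @param network the true [gene_network].
#' @param lambda penalty weight.
#' @param alpha network mixing values; may be a vector (one assessment per
#'   value).
#' @param statistic one of `"cvpl"`, `"loglik"`, `"overlap"`.
#' @param n_random number of shuffled networks; defaults per statistic.
#' @param k CV folds for the CVPL statistic.
#' @param top_k list size for the overlap statistic.
#' @param seed master seed controlling folds and shuffles.
#' @return An object of class `netcox_randomization`: list with one element
#'   per alpha, each holding `observed`, `null` (length `n_random`) and
#'   `exceedance` (share of null values below the observed).
#' @export
randomization_assessment <- function(ds, network, lambda,
                                     alpha = netcox_alpha_random_set(),
                                     statistic = c("cvpl", "loglik", "overlap"),
                                     n_random = NULL, k = 5L, top_k = 100L,
                                     seed = 1L) {
  statistic <- match.arg(statistic)
  n_random <- as.integer(n_random %||%
                           switch(statistic, cvpl = 20L, loglik = 50L, overlap = 50L))
  if (n_random < 1L) stop("`n_random` must be >= 1")
  ds_list <- if (inherits(ds, "survival_dataset")) list(ds) else ds
  if (statistic == "overlap" && length(ds_list) < 2L)
    stop("the overlap statistic needs two or more datasets")
  seeds <- derive_seeds(seed, n_random)
  folds <- if (statistic == "cvpl")
    make_folds(nrow(ds_list[[1]]$X), k, seed = seed, event = ds_list[[1]]$event)
  stat_fun <- function(net, a) {
    switch(statistic,
      cvpl = cvpl(ds_list[[1]], net, lambda, a, folds),
      loglik = {
        fit <- netcox_fit(ds_list[[1]], penalty_matrix(net, a), lambda)
        partial_log_likelihood(fit$beta, ds_list[[1]])
      },
      overlap = {
        rgs <- lapply(ds_list, function(d)
          rank_genes(netcox_fit(d, penalty_matrix(net, a), lambda)))
        top_k_overlap(rgs, top_k)
      })
  }
  out <- lapply(alpha, function(a) {
    observed <- stat_fun(network, a)
    null <- vapply(seq_len(n_random), function(b)
      stat_fun(shuffle_edges(network, seed = seeds[b]), a), numeric(1))
    list(alpha = a, observed = observed, null = null,
         exceedance = mean(observed > null))
  })
  names(out) <- paste0("alpha_", alpha)
  structure(list(results = out, statistic = statistic, lambda = lambda,
                 n_random = n_random, seed = seed),
            class = "netcox_randomization")
}

#' @export
print.netcox_randomization <- function(x, ...) {
  cat(sprintf("netcox_randomization: statistic = %s, lambda = %g, %d shuffles\n",
              x$statistic, x$lambda, x$n_random))
  for (r in x$results)
    cat(sprintf("  alpha = %-5g observed %.4f | null mean %.4f sd %.4f | exceedance %.2f\n",
                r$alpha, r$observed, mean(r$null), stats::sd(r$null),
                r$exceedance))
  invisible(x)
}
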