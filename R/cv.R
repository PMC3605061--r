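#' Default parameter grids
#'
#' The default penalty-weight ladder is
#' `{1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1}` (larger values no longer change the
#' coefficient ranking) and the default network-mixing grid is
#' `{0.01, 0.1, 0.5, 0.95, 1}`, whose `alpha = 1` entry is the ridge model
#' that ignores the network. The randomization studies use the alpha subset
#' `{0.01, 0.1, 0.5, 0.95}`.
#'
#' @return Numeric vectors.
#' @export
netcox_lambda_grid <- function() c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1)

#' @rdname netcox_lambda_grid
#' @export
netcox_alpha_grid <- function() c(0.01, 0.1, 0.5, 0.95, 1.0)

#' @rdname netcox_lambda_grid
#' @export
netcox_alpha_random_set <- function() c(0.01, 0.1, 0.5, 0.95)

#' Cross-validation fold assignment
#'
#' Partitions `n` samples into `k` near-equal folds, stratified by the event
#' indicator when supplied so every training set retains events. Deterministic
#' given `seed`.
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed integer seed or `NULL` for the current RNG stream.
#' @param event optional 0/1 vector for stratified assignment.
#' @return Integer vector of fold labels in `1..k`, length `n`.
#' @export
make_folds <- function(n, k = 5L, seed = NULL, event = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  if (k > n) stop("`k` cannot exceed the number of samples")
  if (!is.null(event) && length(event) != n) stop("`event` length must equal n")
  with_seed(seed, {
    folds <- integer(n)
    strata <- if (is.null(event)) list(seq_len(n)) else split(seq_len(n), event)
    offset <- 0L
    for (idx in strata) {
      shuffled <- idx[sample.int(length(idx))]
      # round-robin with a rotating offset keeps overall fold sizes balanced
      folds[shuffled] <- ((seq_along(shuffled) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
    folds
  })
}

#' Cross-validated partial likelihood (CVPL)
#'
#' Evaluates the model-selection criterion
#' \eqn{\sum_k [\,l(\hat\beta_{(-k)}) - l_{(-k)}(\hat\beta_{(-k)})\,]}
#' where \eqn{\hat\beta_{(-k)}} is the network-penalized Cox fit on the data
#' excluding fold k, \eqn{l} is the partial log-likelihood on all samples and
#' \eqn{l_{(-k)}} on the training samples only. Larger is better.
#'
#' @param ds a [survival_dataset].
#' @param network a [gene_network] or `normalized_adjacency`; `NULL` uses a
#'   pure ridge penalty (equivalent to `alpha = 1`).
#' @param lambda penalty weight > 0.
#' @param alpha network mixing in (0, 1].
#' @param folds fold labels from [make_folds].
#' @param engine solver choice passed to [netcox_fit].
#' @return A single number.
#' @export
cvpl <- function(ds, network, lambda, alpha, folds,
                 engine = c("auto", "primal", "dual")) {
  engine <- match.arg(engine)
  if (length(folds) != nrow(ds$X)) stop("`folds` length must equal sample count")
  if (is.null(network) && alpha != 1)
    stop("a network is required when alpha < 1")
  gamma <- if (is.null(network))
    penalty_matrix(matrix(0, ncol(ds$X), ncol(ds$X)), alpha = 1)
  else penalty_matrix(network, alpha)
  total <- 0
  for (kk in sort(unique(folds))) {
    train <- folds != kk
    ds_train <- subset_samples(ds, train)
    if (sum(ds_train$event) < 1L)
      stop(sprintf("training set for fold %d has no events", kk))
    fit <- netcox_fit(ds_train, gamma, lambda, engine = engine)
    total <- total + partial_log_likelihood(fit$beta, ds) -
      partial_log_likelihood(fit$beta, ds_train)
  }
  if (!is.finite(total)) stop("non-finite CVPL")
  total
}

#' Grid search over (lambda, alpha) by repeated cross-validation
#'
#' Evaluates the mean CVPL over `repeats` repeated `k`-fold splits for every
#' (lambda, alpha) pair and reports the maximizing pair. The `alpha = 1`
#' entries correspond to the ridge model that ignores the network.
#'
#' @inheritParams cvpl
#' @param lambda_grid,alpha_grid numeric grids; defaults
#'   [netcox_lambda_grid()] and [netcox_alpha_grid()].
#' @param k folds per split (default 5).
#' @param repeats number of repeated splits (default 5); repeat r uses seed
#'   `seed + r`.
#' @param seed master seed for the fold assignments.
#' @return An object of class `netcox_cv`: list with `entries` (data frame
#'   with columns lambda, alpha, rep, cvpl), `summary` (mean CVPL per pair),
#'   `best` (lambda, alpha, mean cvpl), `folds`, `repeats`, `seed`.
#' @export
grid_search <- function(ds, network, lambda_grid = netcox_lambda_grid(),
                        alpha_grid = netcox_alpha_grid(), k = 5L,
                        repeats = 5L, seed = 1L,
                        engine = c("auto", "primal", "dual")) {
  engine <- match.arg(engine)
  if (length(lambda_grid) == 0L || length(alpha_grid) == 0L)
    stop("parameter grids must be non-empty")
  fold_list <- lapply(seq_len(repeats), function(r)
    make_folds(nrow(ds$X), k, seed = seed + r, event = ds$event))
  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid,
                      rep = seq_len(repeats), KEEP.OUT.ATTRS = FALSE)
  grid$cvpl <- mapply(function(l, a, r)
    cvpl(ds, network, l, a, fold_list[[r]], engine = engine),
    grid$lambda, grid$alpha, grid$rep)
  agg <- stats::aggregate(cvpl ~ lambda + alpha, data = grid, FUN = mean)
  names(agg)[names(agg) == "cvpl"] <- "mean_cvpl"
  best <- agg[which.max(agg$mean_cvpl), , drop = FALSE]
  structure(list(entries = grid, summary = agg,
                 best = list(lambda = best$lambda, alpha = best$alpha,
                             mean_cvpl = best$mean_cvpl),
                 folds = k, repeats = repeats, seed = seed),
            class = "netcox_cv")
}

#' @export
print.netcox_cv <- function(x, ...) {
  cat(sprintf("netcox_cv: %d (lambda, alpha) pairs x %d repeats of %d-fold CV\n",
              nrow(x$summary), x$repeats, x$folds))
  cat(sprintf("  best: lambda = %g, alpha = %g (mean CVPL %.4f)\n",
              x$best$lambda, x$best$alpha, x$best$mean_cvpl))
  invisible(x)
}
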