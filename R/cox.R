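#' Survival dataset container
#'
#' Bundles an expression matrix with right-censored follow-up data: positive
#' follow-up times and 0/1 event indicators (1 = event observed, 0 = censored).
#'
#' @param X n x p numeric expression matrix (samples in rows).
#' @param time positive follow-up times (time units are the caller's; months
#'   in typical microarray survival cohorts).
#' @param event 0/1 event indicators.
#' @param gene_ids,sample_ids identifiers; default to dimnames of `X` or
#'   generated labels.
#' @return An object of class `survival_dataset` with elements `X`,
#'   `gene_ids`, `sample_ids`, `time`, `event`.
#' @export
survival_dataset <- function(X, time, event, gene_ids = colnames(X),
                             sample_ids = rownames(X)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p || length(sample_ids) != n)
    stop("identifier lengths inconsistent with `X`")
  if (anyDuplicated(gene_ids)) stop("`gene_ids` must be unique")
  if (anyDuplicated(sample_ids)) stop("`sample_ids` must be unique")
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != n || length(event) != n)
    stop("`time`/`event` lengths must equal nrow(X)")
  stopifnot_finite(X, "expression matrix"); stopifnot_finite(time, "time")
  if (any(time <= 0)) stop("all follow-up times must be > 0")
  if (!all(event %in% c(0, 1))) stop("`event` must contain only 0 and 1")
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(X = X, gene_ids = gene_ids, sample_ids = sample_ids,
                 time = time, event = as.integer(event)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d samples x %d genes, %d events (%.0f%% censored)\n",
              nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

subset_samples <- function(ds, keep) {
  survival_dataset(ds$X[keep, , drop = FALSE], ds$time[keep], ds$event[keep],
                   ds$gene_ids, ds$sample_ids[keep])
}

check_beta <- function(beta, ds) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(ds$X)) stop("`beta` length must equal the gene count")
  stopifnot_finite(beta, "beta")
  beta
}

# Per-sample log sum_{j in R(t_i)} exp(eta_j) over closed risk sets
# R(t) = {j : t_j >= t}, accumulated as a streaming log-sum-exp from the
# largest time downward so extreme linear predictors neither overflow nor
# underflow to log(0).
log_risk_sums <- function(time, eta) {
  n <- length(time)
  ord <- order(time)
  eta_s <- eta[ord]
  cum <- numeric(n)
  lse <- -Inf
  for (j in n:1) {
    a <- lse; b <- eta_s[j]
    lse <- if (a == -Inf) b else max(a, b) + log1p(exp(-abs(a - b)))
    cum[j] <- lse
  }
  ts <- time[ord]
  # ties share the risk sum of the first index in their tie group
  first_of_tie <- match(ts, ts)
  out <- numeric(n)
  out[ord] <- cum[first_of_tie]
  out
}

#' Cox partial log-likelihood
#'
#' Evaluates the Cox log-partial likelihood
#' \eqn{\sum_{i: \delta_i = 1} [\beta' x_i - \log \sum_{j \in R(t_i)} e^{\beta' x_j}]}
#' with closed risk sets \eqn{R(t) = \{j : t_j \ge t\}} and the Breslow
#' convention for tied event times. Computations are max-shifted so large
#' linear predictors do not overflow.
#'
#' @param beta coefficient vector (length p).
#' @param ds a [survival_dataset].
#' @return A single number (0 when there are no events).
#' @export
partial_log_likelihood <- function(beta, ds) {
  beta <- check_beta(beta, ds)
  ev <- ds$event == 1
  if (!any(ev)) return(0)
  eta <- drop(ds$X %*% beta)
  lrs <- log_risk_sums(ds$time, eta)
  val <- sum(eta[ev] - lrs[ev])
  if (!is.finite(val)) stop("non-finite partial log-likelihood")
  val
}

#' Breslow baseline hazard estimator
#'
#' Nonparametric maximum-likelihood baseline hazard increments given `beta`:
#' at each distinct event time t the increment is
#' (number of events at t) / \eqn{\sum_{j \in R(t)} e^{\beta' x_j}}.
#' At `beta = 0` the cumulative hazard is the Nelson-Aalen estimator.
#'
#' @inheritParams partial_log_likelihood
#' @return An object of class `baseline_hazard`: list with `event_times`
#'   (sorted distinct times carrying >= 1 event), `increments`, `cumulative`.
#' @export
breslow_baseline <- function(beta, ds) {
  beta <- check_beta(beta, ds)
  breslow_baseline_eta(drop(ds$X %*% beta), ds)
}

# H0(t) evaluated at arbitrary times (right-continuous step function).
cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$event_times)
  c(0, baseline$cumulative)[idx + 1L]
}

# log h0 at exact event times; error when a time is missing from the support.
log_increment_at <- function(baseline, t) {
  idx <- match(t, baseline$event_times)
  if (anyNA(idx))
    stop("event time absent from baseline hazard support")
  log(baseline$increments[idx])
}

#' Total log-likelihood of the Cox model
#'
#' Evaluates the full (beta, baseline) log-likelihood
#' \eqn{\sum_i [\delta_i (\log h_0(t_i) + \beta' x_i) - H_0(t_i) e^{\beta' x_i}]},
#' whose profile over the baseline hazard recovers the partial likelihood and
#' the Breslow estimator.
#'
#' @inheritParams partial_log_likelihood
#' @param baseline a `baseline_hazard` defined on the dataset's event times.
#' @return A single number.
#' @export
total_log_likelihood <- function(beta, baseline, ds) {
  beta <- check_beta(beta, ds)
  eta <- drop(ds$X %*% beta)
  total_log_likelihood_eta(eta, baseline, ds)
}

total_log_likelihood_eta <- function(eta, baseline, ds) {
  ev <- ds$event == 1
  H0 <- cumhaz_at(baseline, ds$time)
  val <- -sum(H0 * exp(eta))
  if (any(ev)) val <- val + sum(log_increment_at(baseline, ds$time[ev]) + eta[ev])
  val
}

#' Gradient of the penalized total log-likelihood
#'
#' At a fixed baseline hazard, the gradient in beta of
#' `total_log_likelihood - lambda * t(beta) Gamma beta` is
#' `t(X) (delta - mu) - 2 lambda Gamma beta` with
#' `mu_i = H0(t_i) exp(beta' x_i)`.
#'
#' @inheritParams total_log_likelihood
#' @param lambda penalty weight >= 0.
#' @param gamma a [penalty_matrix] (or plain matrix); `NULL` means the
#'   identity (pure ridge).
#' @return Length-p numeric vector.
#' @export
penalized_gradient <- function(beta, baseline, ds, lambda, gamma = NULL) {
  beta <- check_beta(beta, ds)
  G <- as_gamma_matrix(gamma, ncol(ds$X))
  if (nrow(G) != length(beta)) stop("penalty matrix dimension mismatch")
  eta <- drop(ds$X %*% beta)
  mu <- cumhaz_at(baseline, ds$time) * exp(eta)
  unname(drop(crossprod(ds$X, ds$event - mu)) - 2 * lambda * drop(G %*% beta))
}

#' Hessian of the penalized total log-likelihood
#'
#' `-t(X) diag(mu) X - 2 lambda Gamma`; symmetric, and negative definite for
#' `lambda > 0`.
#'
#' @inheritParams penalized_gradient
#' @return p x p numeric matrix.
#' @export
penalized_hessian <- function(beta, baseline, ds, lambda, gamma = NULL) {
  beta <- check_beta(beta, ds)
  G <- as_gamma_matrix(gamma, ncol(ds$X))
  if (nrow(G) != length(beta)) stop("penalty matrix dimension mismatch")
  eta <- drop(ds$X %*% beta)
  mu <- cumhaz_at(baseline, ds$time) * exp(eta)
  -crossprod(ds$X, ds$X * mu) - 2 * lambda * G
}

penalized_objective <- function(eta, baseline, ds, lambda, quad) {
  total_log_likelihood_eta(eta, baseline, ds) - lambda * quad
}

# Partial log-likelihood from a linear predictor (Breslow ties).
partial_log_likelihood_eta <- function(eta, ds) {
  ev <- ds$event == 1
  if (!any(ev)) return(0)
  lrs <- log_risk_sums(ds$time, eta)
  sum(eta[ev] - lrs[ev])
}

# Risk-set quantities at the self-consistent (Breslow) baseline: per-sample
# expected event counts mu_i = H0(t_i) e^{eta_i}, the n x K matrix P of
# risk-set membership probabilities pi_ki = e^{eta_i} 1(t_i >= t_k) / S_k
# (one column per distinct event time), and the event counts d. These give
# the exact curvature of the profiled partial likelihood:
#   d^2 pl / d eta^2 = -(diag(mu) - P diag(d) P').
risk_profile <- function(ds, eta) {
  ev <- ds$event == 1
  evt <- sort(unique(ds$time[ev]))
  d <- vapply(evt, function(t) sum(ds$time == t & ev), numeric(1))
  lrs_at <- log_risk_sums(ds$time, eta)[match(evt, ds$time)]
  # pi_ki = exp(eta_i - log S_k); exponent <= 0 for i in R(t_k)
  E <- outer(eta, lrs_at, "-")
  E[!outer(ds$time, evt, ">=")] <- -Inf
  P <- exp(E)
  mu <- drop(P %*% d)
  list(mu = mu, P = P, d = d, event_times = evt)
}

new_netcox_fit <- function(beta, baseline, lambda, alpha, trace, converged,
                           n_iter, engine, gene_ids) {
  names(beta) <- gene_ids
  structure(list(beta = beta, baseline = baseline, lambda = lambda,
                 alpha = alpha, objective_trace = trace, converged = converged,
                 n_iter = n_iter, engine = engine),
            class = "netcox_fit")
}

#' @export
print.netcox_fit <- function(x, ...) {
  cat(sprintf("netcox_fit (%s): %d genes, lambda = %g, alpha = %s\n",
              x$engine, length(x$beta), x$lambda,
              ifelse(is.na(x$alpha), "NA", format(x$alpha))))
  cat(sprintf("  converged: %s after %d outer iterations, objective %.6f\n",
              x$converged, x$n_iter, utils::tail(x$objective_trace, 1)))
  cat(sprintf("  %d nonzero |beta| > 1e-8, max |beta| = %.4g\n",
              sum(abs(x$beta) > 1e-8), max(abs(x$beta))))
  invisible(x)
}

#' Fit the network-penalized Cox model (primal solver)
#'
#' Maximizes the penalized total log-likelihood
#' `l(beta, h0) - lambda * t(beta) Gamma beta` by alternating Breslow updates
#' of the baseline hazard with safeguarded Newton-Raphson updates of beta.
#' With the baseline profiled out at each step, the beta update is an exact
#' Newton step on the penalized partial likelihood (the fixed-baseline
#' curvature of [penalized_hessian] plus the risk-set mean-correction term),
#' giving quadratic convergence. Newton steps that fail to improve the
#' objective are halved (up to 30 times), so the recorded objective trace is
#' nondecreasing.
#'
#' @param ds a [survival_dataset] with at least one event.
#' @param gamma a [penalty_matrix]; `NULL` means identity (ridge penalty).
#' @param lambda penalty weight >= 0. `lambda = 0` is refused when p >= n
#'   (non-identifiable).
#' @param init_beta starting coefficients (default 0, which makes the first
#'   baseline the Nelson-Aalen-type estimator).
#' @param tol relative objective-change tolerance for the outer loop.
#' @param beta_tol maximum absolute coefficient change required at
#'   convergence.
#' @param max_iter maximum outer iterations.
#' @return An object of class `netcox_fit` with elements `beta`, `baseline`,
#'   `lambda`, `alpha`, `objective_trace`, `converged`, `n_iter`, `engine`.
#' @export
fit_primal <- function(ds, gamma = NULL, lambda = 0, init_beta = NULL,
                       tol = 1e-9, beta_tol = 1e-7, max_iter = 200L) {
  if (!inherits(ds, "survival_dataset")) stop("`ds` must be a survival_dataset")
  if (lambda < 0) stop("`lambda` must be >= 0")
  n <- nrow(ds$X); p <- ncol(ds$X)
  if (sum(ds$event) < 1L) stop("dataset has no events")
  if (lambda == 0 && p >= n)
    stop("lambda = 0 with p >= n is non-identifiable; use lambda > 0")
  G <- as_gamma_matrix(gamma, p)
  alpha <- if (inherits(gamma, "penalty_matrix")) gamma$alpha else NA_real_
  beta <- if (is.null(init_beta)) numeric(p) else check_beta(init_beta, ds)
  eta <- drop(ds$X %*% beta)
  quad <- drop(crossprod(beta, G %*% beta))
  # penalized profiled objective (partial likelihood); differs from the
  # penalized total log-likelihood at the Breslow baseline by a constant
  pl_pen <- function(eta, quad) partial_log_likelihood_eta(eta, ds) - lambda * quad
  obj <- pl_pen(eta, quad)
  baseline <- breslow_baseline_eta(eta, ds)
  trace <- penalized_objective(eta, baseline, ds, lambda, quad)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    beta_prev <- beta
    # (b) Breslow baseline at the current beta; mu is then self-consistent
    rp <- risk_profile(ds, eta)
    g <- drop(crossprod(ds$X, ds$event - rp$mu)) - 2 * lambda * drop(G %*% beta)
    if (max(abs(g)) < 1e-9) { converged <- TRUE; break }
    # (a) Newton step on beta; curvature of the profiled likelihood is the
    # fixed-baseline Hessian plus the risk-set mean-correction term
    XtP <- crossprod(ds$X, rp$P)
    H <- -(crossprod(ds$X, ds$X * rp$mu) - XtP %*% (rp$d * t(XtP))) -
      2 * lambda * G
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) stop("singular Hessian in Newton step")
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      eta_c <- drop(ds$X %*% cand)
      quad_c <- drop(crossprod(cand, G %*% cand))
      f_new <- pl_pen(eta_c, quad_c)
      if (is.finite(f_new) && f_new >= obj) {
        beta <- cand; eta <- eta_c; quad <- quad_c; obj_new <- f_new
        ok <- TRUE; break
      }
    }
    if (!ok) { converged <- TRUE; break }  # no improving step: at the optimum
    baseline <- breslow_baseline_eta(eta, ds)
    trace <- c(trace, penalized_objective(eta, baseline, ds, lambda, quad))
    done <- abs(obj_new - obj) / (1 + abs(obj_new)) < tol &&
      max(abs(beta - beta_prev)) < beta_tol
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  baseline <- breslow_baseline_eta(eta, ds)
  new_netcox_fit(beta, baseline, lambda, alpha, trace, converged,
                 length(trace) - 1L, "primal", ds$gene_ids)
}

#' Fit the network-penalized Cox model (dual solver)
#'
#' Solves the same objective as [fit_primal] in the n-dimensional dual space:
#' the optimum satisfies `beta = solve(Gamma, t(X) %*% gam)` for an n-vector
#' `gam`, so with `K = X solve(Gamma) t(X)` the optimization runs over `gam`
#' with n x n linear algebra. Intended for p >> n; one p x n triangular solve
#' against the Cholesky factor of Gamma is the only p-sized operation.
#' Results agree with the primal path within solver tolerance.
#'
#' @inheritParams fit_primal
#' @param lambda penalty weight, strictly positive.
#' @return A `netcox_fit` (engine `"dual"`).
#' @export
fit_dual <- function(ds, gamma = NULL, lambda, tol = 1e-9, beta_tol = 1e-7,
                     max_iter = 200L) {
  if (!inherits(ds, "survival_dataset")) stop("`ds` must be a survival_dataset")
  if (lambda <= 0) stop("the dual solver requires lambda > 0")
  n <- nrow(ds$X); p <- ncol(ds$X)
  if (sum(ds$event) < 1L) stop("dataset has no events")
  G <- as_gamma_matrix(gamma, p)
  alpha <- if (inherits(gamma, "penalty_matrix")) gamma$alpha else NA_real_
  R <- tryCatch(chol(G), error = function(e)
    stop("penalty matrix is not positive definite"))
  GiXt <- backsolve(R, forwardsolve(t(R), t(ds$X)))   # solve(Gamma, t(X))
  K <- ds$X %*% GiXt                                   # n x n kernel
  K <- (K + t(K)) / 2
  gam <- numeric(n)
  eta <- numeric(n)
  quad <- 0                                # t(beta) G beta = gam' K gam
  pl_pen <- function(eta, quad) partial_log_likelihood_eta(eta, ds) - lambda * quad
  obj <- pl_pen(eta, quad)
  baseline <- breslow_baseline_eta(eta, ds)
  trace <- penalized_objective(eta, baseline, ds, lambda, quad)
  converged <- FALSE
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    beta_prev <- beta
    rp <- risk_profile(ds, eta)
    gtil <- (ds$event - rp$mu) - 2 * lambda * gam      # gradient = K %*% gtil
    if (max(abs(K %*% gtil)) < 1e-9) { converged <- TRUE; break }
    # Newton direction solves (D K + 2 lambda I) d = gtil with D the exact
    # profiled curvature diag(mu) - P diag(d) P', since
    # K (D K + 2 lambda I) d = K gtil recovers the Newton system in gam
    DK <- rp$mu * K - rp$P %*% (rp$d * crossprod(rp$P, K))
    d <- tryCatch(solve(DK + 2 * lambda * diag(n), gtil),
                  error = function(e) NULL)
    if (is.null(d)) stop("singular system in dual Newton step")
    ok <- FALSE
    for (h in 0:30) {
      cand <- gam + d / 2^h
      eta_c <- drop(K %*% cand)
      f_new <- pl_pen(eta_c, drop(crossprod(cand, K %*% cand)))
      if (is.finite(f_new) && f_new >= obj) {
        gam <- cand; eta <- eta_c; obj_new <- f_new; ok <- TRUE; break
      }
    }
    if (!ok) { converged <- TRUE; break }
    quad <- drop(crossprod(gam, K %*% gam))
    baseline <- breslow_baseline_eta(eta, ds)
    trace <- c(trace, penalized_objective(eta, baseline, ds, lambda, quad))
    beta <- drop(GiXt %*% gam)
    done <- abs(obj_new - obj) / (1 + abs(obj_new)) < tol &&
      max(abs(beta - beta_prev)) < beta_tol
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  beta <- drop(GiXt %*% gam)
  baseline <- breslow_baseline_eta(eta, ds)
  new_netcox_fit(beta, baseline, lambda, alpha, trace, converged,
                 length(trace) - 1L, "dual", ds$gene_ids)
}

# Breslow baseline from a precomputed linear predictor.
breslow_baseline_eta <- function(eta, ds) {
  ev <- ds$event == 1
  if (!any(ev)) stop("dataset has no events; baseline hazard undefined")
  lrs <- log_risk_sums(ds$time, eta)
  evt <- sort(unique(ds$time[ev]))
  d <- vapply(evt, function(t) sum(ds$time == t & ev), numeric(1))
  lrs_at <- lrs[match(evt, ds$time)]
  inc <- d * exp(-lrs_at)
  structure(list(event_times = evt, increments = inc, cumulative = cumsum(inc)),
            class = "baseline_hazard")
}

#' Fit the network-penalized Cox model
#'
#' Front end choosing the solver: the dual path when `p > n` (and
#' `lambda > 0`), the primal Newton path otherwise.
#'
#' @inheritParams fit_primal
#' @param engine `"auto"` (default), `"primal"`, or `"dual"`.
#' @return A `netcox_fit`.
#' @export
netcox_fit <- function(ds, gamma = NULL, lambda = 0,
                       engine = c("auto", "primal", "dual"), ...) {
  engine <- match.arg(engine)
  if (engine == "auto")
    engine <- if (ncol(ds$X) > nrow(ds$X) && lambda > 0) "dual" else "primal"
  switch(engine,
         primal = fit_primal(ds, gamma, lambda, ...),
         dual   = fit_dual(ds, gamma, lambda, ...))
}

#' Prognostic index
#'
#' Linear risk score `PI_i = beta' x_i` used to rank patients and split them
#' into risk groups.
#'
#' @param beta coefficient vector or a `netcox_fit`.
#' @param X n x p expression matrix.
#' @return Length-n numeric vector.
#' @export
prognostic_index <- function(beta, X) {
  if (inherits(beta, "netcox_fit")) beta <- beta$beta
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("dimension mismatch between `beta` and `X`")
  drop(X %*% beta)
}
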