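# Shared fixtures and independent oracles, built in code at test time.

# Small random survival dataset (no network structure).
toy_dataset <- function(n, p, seed = 1, event_prob = 0.7, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  time <- rexp(n, rate = 0.1 * exp(eta))
  event <- rbinom(n, 1, event_prob)
  if (sum(event) == 0) event[1] <- 1L
  survival_dataset(X, time, event)
}

# Random sparse symmetric weighted network.
toy_network <- function(p, n_edges = 3 * p, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ij <- cbind(sample(p, n_edges, replace = TRUE),
              sample(p, n_edges, replace = TRUE))
  ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  W[ij] <- runif(nrow(ij))
  W <- pmax(W, t(W))
  gene_network(W, paste0("g", seq_len(p)))
}

# Independent generic-optimizer oracle: maximize `fn` over p coefficients.
optim_oracle <- function(fn, p, start = rep(0, p)) {
  fit <- optim(start, fn, method = "BFGS",
               control = list(fnscale = -1, maxit = 2000, reltol = 1e-14))
  fit2 <- optim(fit$par, fn, method = "BFGS",
                control = list(fnscale = -1, maxit = 2000, reltol = 1e-14))
  fit2$par
}

# Independent risk-set-counting evaluation of the partial log-likelihood at
# beta = 0: sum over events of -log |R(t_i)| (Breslow ties).
lpl0_by_counting <- function(time, event) {
  s <- 0
  for (i in which(event == 1)) s <- s - log(sum(time >= time[i]))
  s
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Brute-force two-sample AUC by pair counting (ties count 1/2).
pair_count_auc <- function(pi_case, pi_ctrl) {
  tot <- 0
  for (a in pi_case) for (b in pi_ctrl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pi_case) * length(pi_ctrl))
}
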