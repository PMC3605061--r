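#' Simulation configuration
#'
#' Parameters of the synthetic-data generator, which emulates the structure
#' the network-penalized Cox model assumes: a modular weighted gene network,
#' regression coefficients that are smooth over that network (constant within
#' active modules up to jitter), block-correlated expression, and
#' right-censored proportional-hazards event times with an exponential
#' baseline.
#'
#' Defaults describe a desk-scale cohort: 200 genes in ten modules of 20,
#' dense within-module connectivity (`p_in = 0.8`) with strong weights and
#' sparse weak between-module edges, two signal-carrying modules with effect
#' size 0.5, within-module expression correlation 0.6, and 30% censoring over
#' 150 samples.
#'
#' @param p,n gene and sample counts.
#' @param n_modules,module_size network block structure
#'   (`n_modules * module_size <= p`; leftover genes belong to no module).
#' @param p_in,p_out within/between-module edge probabilities.
#' @param w_in,w_out length-2 weight ranges (uniform) for within/between
#'   edges.
#' @param active_modules indices of modules carrying survival signal.
#' @param effect coefficient magnitude on active-module genes.
#' @param coef_noise_sd Gaussian jitter of the active coefficients.
#' @param rho_in within-module expression correlation in [0, 1).
#' @param baseline_rate exponential baseline hazard rate.
#' @param censor_target desired censoring fraction in [0, 1).
#' @param seed master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = 200L, n = 150L, n_modules = 10L, module_size = 20L,
                       p_in = 0.8, p_out = 0.02, w_in = c(0.5, 1),
                       w_out = c(0.05, 0.2), active_modules = c(1L, 2L),
                       effect = 0.5, coef_noise_sd = 0.05, rho_in = 0.6,
                       baseline_rate = 0.05, censor_target = 0.3, seed = 1L) {
  cfg <- list(p = as.integer(p), n = as.integer(n),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              p_in = p_in, p_out = p_out, w_in = w_in, w_out = w_out,
              active_modules = as.integer(active_modules), effect = effect,
              coef_noise_sd = coef_noise_sd, rho_in = rho_in,
              baseline_rate = baseline_rate, censor_target = censor_target,
              seed = as.integer(seed))
  if (cfg$n_modules * cfg$module_size > cfg$p)
    stop("module structure exceeds the gene count")
  for (pr in c(cfg$p_in, cfg$p_out))
    if (pr < 0 || pr > 1) stop("edge probabilities must lie in [0, 1]")
  if (cfg$censor_target < 0 || cfg$censor_target >= 1)
    stop("`censor_target` must lie in [0, 1)")
  if (cfg$rho_in < 0 || cfg$rho_in >= 1)
    stop("`rho_in` must lie in [0, 1)")
  if (cfg$baseline_rate <= 0) stop("`baseline_rate` must be > 0")
  if (length(cfg$active_modules) &&
      (min(cfg$active_modules) < 1 || max(cfg$active_modules) > cfg$n_modules))
    stop("`active_modules` out of range")
  structure(cfg, class = "sim_config")
}

# module index per gene; 0 = no module
module_of <- function(cfg) {
  m <- integer(cfg$p)
  m[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  m
}

sim_gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$p))

#' Simulate a modular gene network
#'
#' Block-structured weighted network: within-module gene pairs carry an edge
#' with probability `p_in` and a weight uniform in `w_in`; between-module
#' pairs with probability `p_out` and weight in `w_out`.
#'
#' @param cfg a [sim_config].
#' @param seed seed (defaults to `cfg$seed`); `NULL` uses the current stream.
#' @return A [gene_network].
#' @export
simulate_network <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    p <- cfg$p
    mod <- module_of(cfg)
    ut <- which(upper.tri(matrix(0, p, p)))
    ij <- arrayInd(ut, c(p, p))
    same <- mod[ij[, 1]] == mod[ij[, 2]] & mod[ij[, 1]] > 0L
    prob <- ifelse(same, cfg$p_in, cfg$p_out)
    has_edge <- stats::runif(length(ut)) < prob
    w <- numeric(length(ut))
    w[has_edge & same] <- stats::runif(sum(has_edge & same),
                                       cfg$w_in[1], cfg$w_in[2])
    w[has_edge & !same] <- stats::runif(sum(has_edge & !same),
                                        cfg$w_out[1], cfg$w_out[2])
    W <- matrix(0, p, p)
    W[ut] <- w
    W <- W + t(W)
    gene_network(W, sim_gene_ids(cfg))
  })
}

#' Simulate network-smooth coefficients
#'
#' Coefficients equal `effect` on genes of the active modules, plus Gaussian
#' jitter of standard deviation `coef_noise_sd`, and 0 elsewhere — smooth
#' over the modular network by construction.
#'
#' @param net the [gene_network] the coefficients live on (used for its gene
#'   ids).
#' @inheritParams simulate_network
#' @return Named numeric vector of length p.
#' @export
simulate_coefficients <- function(net, cfg, seed = cfg$seed) {
  with_seed(seed, {
    mod <- module_of(cfg)
    beta <- numeric(cfg$p)
    active <- mod %in% cfg$active_modules
    beta[active] <- cfg$effect +
      stats::rnorm(sum(active), 0, cfg$coef_noise_sd)
    stats::setNames(beta, net$gene_ids)
  })
}

#' Simulate block-correlated expression
#'
#' Zero-mean unit-variance Gaussian expression with exchangeable correlation
#' `rho_in` within each module and independence between modules
#' (one latent factor per module).
#'
#' @inheritParams simulate_network
#' @param net unused except for gene ids; may be `NULL`.
#' @return n x p numeric matrix.
#' @export
simulate_expression <- function(cfg, net = NULL, seed = cfg$seed) {
  with_seed(seed, {
    mod <- module_of(cfg)
    X <- matrix(stats::rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
    if (cfg$rho_in > 0) {
      for (m in seq_len(cfg$n_modules)) {
        cols <- which(mod == m)
        z <- stats::rnorm(cfg$n)
        X[, cols] <- sqrt(cfg$rho_in) * z +
          sqrt(1 - cfg$rho_in) * X[, cols]
      }
    }
    colnames(X) <- if (!is.null(net)) net$gene_ids else sim_gene_ids(cfg)
    rownames(X) <- sprintf("s%04d", seq_len(cfg$n))
    X
  })
}

# censoring rate c with E[c / (c + r_i)] = target for exponential censoring
calibrate_censoring_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + rates)) - target
  lo <- log(min(rates)) - 25; hi <- log(max(rates)) + 25
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate right-censored proportional-hazards event times
#'
#' Latent event times are exponential with rate
#' `baseline_rate * exp(beta' x_i)` (inverse-CDF sampling). Censoring times
#' are independently exponential with a rate calibrated numerically so the
#' expected censoring fraction matches `censor_target` under the simulated
#' risk-score distribution; `censor_target = 0` disables censoring. Observed
#' time is the minimum, event = 1 when the event came first.
#'
#' @param X n x p expression matrix.
#' @param beta true coefficients.
#' @inheritParams simulate_network
#' @return List with `time` and `event`.
#' @export
simulate_survival <- function(X, beta, cfg, seed = cfg$seed) {
  if (ncol(X) != length(beta)) stop("dimension mismatch between `X` and `beta`")
  with_seed(seed, {
    rates <- cfg$baseline_rate * exp(drop(X %*% beta))
    t_event <- -log(stats::runif(nrow(X))) / rates
    if (cfg$censor_target > 0) {
      c_rate <- calibrate_censoring_rate(rates, cfg$censor_target)
      t_cens <- -log(stats::runif(nrow(X))) / c_rate
    } else {
      t_cens <- rep(Inf, nrow(X))
    }
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  })
}

#' Generate a full synthetic dataset
#'
#' Composes the network, coefficient, expression, and survival generators and
#' returns the ground truth alongside the data, for recovery experiments.
#'
#' @param cfg a [sim_config].
#' @return List with elements `dataset` (a [survival_dataset]), `network`
#'   (the true [gene_network]), `beta_true`, and `config`.
#' @export
make_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    net <- simulate_network(cfg, seed = NULL)
    beta <- simulate_coefficients(net, cfg, seed = NULL)
    X <- simulate_expression(cfg, net, seed = NULL)
    surv <- simulate_survival(X, beta, cfg, seed = NULL)
    ds <- survival_dataset(X, surv$time, surv$event,
                           gene_ids = net$gene_ids,
                           sample_ids = rownames(X))
    list(dataset = ds, network = net, beta_true = beta, config = cfg)
  })
}
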