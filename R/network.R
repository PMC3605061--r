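#' Weighted gene relation network
#'
#' Container for an undirected, positively weighted gene network: a symmetric
#' adjacency matrix with zero diagonal over a set of unique gene identifiers.
#'
#' @param weights p x p numeric matrix, symmetric, zero diagonal, entries >= 0.
#' @param gene_ids character vector of p unique gene identifiers. Defaults to
#'   the row names of `weights`.
#' @return An object of class `gene_network`: a list with elements `gene_ids`
#'   and `weights` (with dimnames set to the gene ids).
#' @export
gene_network <- function(weights, gene_ids = rownames(weights)) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (ncol(weights) != p) stop("`weights` must be square")
  if (length(gene_ids) != p) stop("`gene_ids` length must match matrix dimension")
  if (anyDuplicated(gene_ids)) stop("`gene_ids` must be unique")
  stopifnot_finite(weights, "network weights")
  if (any(weights < 0)) stop("network weights must be non-negative")
  if (!isSymmetric(unname(weights), tol = 1e-10)) stop("`weights` must be symmetric")
  diag(weights) <- 0
  dimnames(weights) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, weights = weights), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("gene_network: %d genes, %d weighted edges\n", length(x$gene_ids), m))
  invisible(x)
}

n_edges <- function(net) sum(net$weights[upper.tri(net$weights)] > 0)

#' Mutual-rank co-expression network
#'
#' Builds a weighted gene co-expression network from an expression matrix
#' using a reliability score over correlation ranks: for genes i and j,
#' `W_ij = 1 / sqrt(r_i(j) * r_j(i))`, where `r_i(j)` is the rank (1 = highest)
#' of gene j when all other genes are sorted by decreasing absolute Pearson
#' correlation with gene i. Weights lie in (0, 1]; mutual nearest neighbours
#' get weight 1.
#'
#' Ties in absolute correlation receive average ranks. Constant expression
#' columns are assigned correlation 0 with every other gene (worst ranks)
#' rather than being dropped.
#'
#' @param X n x p expression matrix (samples in rows, genes in columns), n >= 3.
#' @param gene_ids gene identifiers; defaults to `colnames(X)`.
#' @param top_k optional sparsification: keep `W_ij` only when j is among the
#'   `top_k` strongest neighbours of i or vice versa (union, preserving
#'   symmetry). Default `NULL` keeps the dense network.
#' @return A [gene_network].
#' @export
build_coexpression_network <- function(X, gene_ids = colnames(X), top_k = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least 2 genes")
  if (n < 3L) stop("need at least 3 samples to estimate correlations")
  stopifnot_finite(X, "expression matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  C <- abs(suppressWarnings(stats::cor(X)))
  C[!is.finite(C)] <- 0  # constant columns: correlation defined as 0
  diag(C) <- NA
  # r[i, j]: rank of j among genes != i, sorted by decreasing |corr| with i
  R <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    R[i, -i] <- rank(-C[i, -i], ties.method = "average")
  }
  W <- 1 / sqrt(R * t(R))
  diag(W) <- 0
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k < 1L || top_k >= p) stop("`top_k` must be in [1, p - 1)")
    keep <- R <= top_k            # j within i's top_k
    keep <- keep | t(keep)        # union keeps symmetry
    W[!keep] <- 0
  }
  gene_network(W, gene_ids)
}

#' Symmetric degree normalization of a network
#'
#' Computes `S_ij = W_ij / sqrt(d_i * d_j)` where `d_i` is the i-th row sum
#' (equal to the column sum for a symmetric W). Rows and columns of isolated
#' genes (degree 0) are set to zero. All eigenvalues of S lie in `[-1, 1]`.
#'
#' @param net a [gene_network].
#' @return An object of class `normalized_adjacency`: list with `S` and
#'   `gene_ids`.
#' @export
normalize_adjacency <- function(net) {
  if (!inherits(net, "gene_network")) net <- gene_network(net)
  W <- net$weights
  d <- rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- W * (inv_sqrt %o% inv_sqrt)
  dimnames(S) <- dimnames(W)
  structure(list(S = S, gene_ids = net$gene_ids), class = "normalized_adjacency")
}

as_S_matrix <- function(S) {
  if (inherits(S, "normalized_adjacency")) S$S
  else if (inherits(S, "gene_network")) normalize_adjacency(S)$S
  else as.matrix(S)
}

#' Network penalty matrix
#'
#' Builds `Gamma = alpha * I + (1 - alpha) * (I - S)`, the quadratic-form
#' matrix of the network constraint. Since the eigenvalues of `I - S` lie in
#' `[0, 2]`, Gamma is symmetric positive definite with minimum eigenvalue
#' at least `alpha`. At `alpha = 1` the network is ignored and Gamma is the
#' identity, reducing the model to ridge-penalized Cox regression.
#'
#' @param S a `normalized_adjacency` (or a [gene_network], normalized first,
#'   or a plain matrix).
#' @param alpha network mixing parameter in (0, 1]; smaller values put more
#'   weight on the network smoothness term.
#' @return An object of class `penalty_matrix`: list with `gamma`, `alpha`,
#'   `gene_ids`.
#' @export
penalty_matrix <- function(S, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must be a single value in (0, 1]")
  gene_ids <- if (is.list(S)) S$gene_ids else rownames(S)
  Sm <- as_S_matrix(S)
  p <- nrow(Sm)
  gamma <- diag(p) - (1 - alpha) * Sm
  if (!is.null(gene_ids)) dimnames(gamma) <- list(gene_ids, gene_ids)
  structure(list(gamma = gamma, alpha = alpha, gene_ids = gene_ids),
            class = "penalty_matrix")
}

as_gamma_matrix <- function(gamma, p = NULL) {
  if (is.null(gamma)) {
    if (is.null(p)) stop("need dimension for identity penalty")
    diag(p)
  } else if (inherits(gamma, "penalty_matrix")) gamma$gamma
  else as.matrix(gamma)
}

#' Network smoothness cost
#'
#' Evaluates the graph-Laplacian quadratic form `t(beta) (I - S) beta`,
#' the cost that penalizes differences between coefficients of connected
#' genes. Always >= 0 for a valid normalized adjacency.
#'
#' @param beta coefficient vector of length p.
#' @param S a `normalized_adjacency` (or matrix).
#' @return A single number.
#' @export
laplacian_quadratic <- function(beta, S) {
  Sm <- as_S_matrix(S)
  if (length(beta) != nrow(Sm)) stop("dimension mismatch between `beta` and `S`")
  sum(beta^2) - drop(crossprod(beta, Sm %*% beta))
}

#' Shuffle network edges
#'
#' Randomizes a network by reassigning its edges to uniformly random distinct
#' unordered gene pairs (no self-loops, no duplicate pairs), preserving the
#' edge count and the multiset of edge weights. Used to build null networks
#' for significance assessment. With `preserve_degree = TRUE`, a
#' double-edge-swap rewiring is used instead, preserving each gene's degree
#' sequence as well.
#'
#' @param net a [gene_network] with at least one edge.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @param preserve_degree use degree-preserving double-edge swaps.
#' @param n_swaps number of attempted swaps when `preserve_degree = TRUE`
#'   (default 10 per edge).
#' @return A [gene_network] on the same genes.
#' @export
shuffle_edges <- function(net, seed = NULL, preserve_degree = FALSE, n_swaps = NULL) {
  if (!inherits(net, "gene_network")) net <- gene_network(net)
  p <- length(net$gene_ids)
  ut <- upper.tri(net$weights)
  idx <- which(ut & net$weights > 0)
  m <- length(idx)
  if (m < 1L) stop("network has no edges to shuffle")
  w <- net$weights[idx]
  n_pairs <- p * (p - 1) / 2
  if (m > n_pairs) stop("too few genes to place all edges without duplication")
  with_seed(seed, {
    Wnew <- matrix(0, p, p)
    if (!preserve_degree) {
      pos <- which(ut)                       # all unordered pairs
      chosen <- pos[sample.int(n_pairs, m)]  # distinct pairs, uniform
      Wnew[chosen] <- sample(w)              # weights permuted over new pairs
    } else {
      ij <- arrayInd(idx, c(p, p))           # current edge endpoints
      a <- ij[, 1]; b <- ij[, 2]
      key <- function(x, y) pmin(x, y) + p * pmax(x, y)
      present <- new.env(hash = TRUE)
      for (k in seq_len(m)) assign(as.character(key(a[k], b[k])), TRUE, present)
      n_swaps <- n_swaps %||% (10L * m)
      for (s in seq_len(n_swaps)) {
        e <- sample.int(m, 2L)
        i1 <- a[e[1]]; j1 <- b[e[1]]; i2 <- a[e[2]]; j2 <- b[e[2]]
        # propose (i1, j2) and (i2, j1)
        if (i1 == j2 || i2 == j1) next
        k1 <- as.character(key(i1, j2)); k2 <- as.character(key(i2, j1))
        if (exists(k1, present, inherits = FALSE) ||
            exists(k2, present, inherits = FALSE) || k1 == k2) next
        rm(list = c(as.character(key(i1, j1)), as.character(key(i2, j2))),
           envir = present)
        assign(k1, TRUE, present); assign(k2, TRUE, present)
        b[e[1]] <- j2; b[e[2]] <- j1
      }
      Wnew[cbind(pmin(a, b), pmax(a, b))] <- w
    }
    Wnew <- Wnew + t(Wnew)
    gene_network(Wnew, net$gene_ids)
  })
}
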