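#' Read an expression matrix
#'
#' Reads tab-separated expression text with genes as rows, samples as
#' columns, and a single header row of sample ids; the first column holds
#' gene symbols. Rows sharing a gene symbol are merged by their mean (as is
#' done when collapsing array probes to genes), with a message reporting the
#' count. The matrix is returned transposed to samples x genes.
#'
#' @param path file path.
#' @return List with `X` (samples x genes), `gene_ids`, `sample_ids`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed expression file")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  sample_ids <- colnames(mat)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header")
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[, -1, drop = FALSE], is.numeric, logical(1)))
    stop(sprintf("non-numeric expression values in column '%s'",
                 sample_ids[bad[1]]))
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 genes[idx[1]], sample_ids[idx[2]]))
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    mat <- rowsum(mat, group = genes) / as.vector(table(genes)[unique(sort(genes))])
    # rowsum orders by group; restore first-appearance order
    mat <- mat[unique(genes), , drop = FALSE]
    genes <- unique(genes)
    message(sprintf("merged %d duplicated gene row(s) by mean", n_dup))
  }
  X <- t(mat)
  dimnames(X) <- list(sample_ids, genes)
  list(X = X, gene_ids = genes, sample_ids = sample_ids)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression]: genes as rows, samples as columns,
#' tab-separated.
#'
#' @param X samples x genes matrix.
#' @param path output path.
#' @param gene_ids,sample_ids identifiers; default to dimnames.
#' @export
write_expression <- function(X, path, gene_ids = colnames(X),
                             sample_ids = rownames(X)) {
  df <- data.frame(gene = gene_ids, t(X), check.names = FALSE)
  colnames(df) <- c("gene", sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a clinical survival table
#'
#' Tab-separated columns `sample_id`, `time`, `event` (0/1), one header row.
#'
#' @param path file path.
#' @return Data frame with those three columns, validated.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical file must have columns sample_id, time, event")
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical file")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop("`time` must be positive and finite")
  if (!all(df$event %in% c(0, 1))) stop("`event` must be 0 or 1")
  df
}

#' Write a clinical survival table
#' @param ds a [survival_dataset] (or data frame with the three columns).
#' @param path output path.
#' @export
write_clinical <- function(ds, path) {
  df <- if (inherits(ds, "survival_dataset"))
    data.frame(sample_id = ds$sample_ids, time = ds$time, event = ds$event)
  else ds
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Combine expression and clinical tables into a survival dataset
#'
#' Samples present in only one of the two sources are dropped with a message
#' reporting the count; the clinical rows are aligned to the expression
#' sample order.
#'
#' @param expr result of [read_expression].
#' @param clinical result of [read_clinical].
#' @return A [survival_dataset].
#' @export
combine_expression_clinical <- function(expr, clinical) {
  common <- intersect(expr$sample_ids, clinical$sample_id)
  if (length(common) == 0L) stop("no overlapping samples")
  dropped <- (length(expr$sample_ids) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0)
    message(sprintf("dropped %d sample(s) absent from one of the two files", dropped))
  keep <- expr$sample_ids %in% common
  cl <- clinical[match(expr$sample_ids[keep], clinical$sample_id), ]
  survival_dataset(expr$X[keep, , drop = FALSE], cl$time, cl$event,
                   gene_ids = expr$gene_ids, sample_ids = expr$sample_ids[keep])
}

#' Read a weighted network edge list
#'
#' Tab-separated `geneA<TAB>geneB<TAB>weight` with a header row, undirected,
#' weights >= 0. Duplicate unordered pairs are rejected; edges touching genes
#' outside `gene_ids` are dropped with a message reporting the count.
#'
#' @param path file path.
#' @param gene_ids the gene universe (e.g. the expression matrix genes).
#' @return A [gene_network] over `gene_ids`.
#' @export
read_network_edges <- function(path, gene_ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list must have 3 columns: geneA, geneB, weight")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  w <- as.numeric(df[[3]])
  if (any(!is.finite(w)) || any(w < 0)) stop("edge weights must be finite and >= 0")
  if (any(a == b)) stop("self-loops are not allowed")
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) stop("duplicate gene pairs in edge list")
  known <- a %in% gene_ids & b %in% gene_ids
  if (any(!known))
    message(sprintf("dropped %d edge(s) with genes outside the expression matrix",
                    sum(!known)))
  W <- matrix(0, length(gene_ids), length(gene_ids),
              dimnames = list(gene_ids, gene_ids))
  if (any(known)) {
    W[cbind(a[known], b[known])] <- w[known]
    W[cbind(b[known], a[known])] <- w[known]
  }
  gene_network(W, gene_ids)
}

#' Write a network as an edge list
#' @param net a [gene_network].
#' @param path output path.
#' @export
write_network_edges <- function(net, path) {
  ut <- which(upper.tri(net$weights) & net$weights > 0)
  ij <- arrayInd(ut, dim(net$weights))
  df <- data.frame(geneA = net$gene_ids[ij[, 1]],
                   geneB = net$gene_ids[ij[, 2]],
                   weight = net$weights[ut])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Round-trip a labelled matrix through tab-separated text
#'
#' Used for the normalized adjacency S and the penalty matrix Gamma.
#'
#' @param mat matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a ranked-genes table
#' @param rg a `ranked_genes` data frame.
#' @param path output path.
#' @export
write_ranked_genes <- function(rg, path) {
  utils::write.table(rg, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
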