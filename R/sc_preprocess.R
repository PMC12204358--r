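## Single-cell preprocessing: the CellMatrix container, QC filtering with
## the strict-inequality thresholds, library-size log-normalization,
## binned-dispersion variable-gene selection, and a PCA + k-means clustering
## stand-in producing per-cell labels.

#' Construct a CellMatrix
#'
#' A raw genes x cells count matrix with per-cell metadata. The per-cell QC
#' metrics (nFeature = genes detected, nCount = total counts, mito_fraction
#' = share of counts from mitochondrial genes) are always recomputed from
#' the counts.
#'
#' @param counts genes x cells matrix of non-negative integers (dense or
#'   `Matrix` sparse); rownames are gene names, colnames cell ids.
#' @param meta data.frame with one row per cell, including at least `cell`;
#'   `sample` and `pathology` are carried when present.
#' @param mito_pattern regex identifying mitochondrial genes by name.
#' @return object of class `CellMatrix`: list(counts, meta).
#' @export
cell_matrix <- function(counts, meta = NULL, mito_pattern = "^MT-") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stopf("duplicate gene names: %s", paste(head(dup, 5), collapse = ", "))
  }
  if (!inherits(counts, "Matrix")) {
    counts <- as(as(as.matrix(counts), "CsparseMatrix"), "dMatrix")
  }
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (is.null(meta)) {
    meta <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(meta) == ncol(counts))
  meta <- meta[match(colnames(counts), meta$cell), , drop = FALSE]
  rownames(meta) <- meta$cell
  mito <- grepl(mito_pattern, rownames(counts))
  ncount <- Matrix::colSums(counts)
  meta$nFeature <- Matrix::colSums(counts > 0)
  meta$nCount <- ncount
  meta$mito_fraction <- ifelse(
    ncount > 0,
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(ncount, 1),
    0
  )
  structure(list(counts = counts, meta = meta, mito_pattern = mito_pattern),
            class = "CellMatrix")
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("pathology" %in% names(x$meta)) {
    print(table(x$meta$pathology))
  }
  invisible(x)
}

#' Quality-control thresholds
#'
#' Cells are removed when nFeature < min_genes or > max_genes, nCount <
#' min_counts or > max_counts, or the mitochondrial fraction is higher than
#' max_mito. All violations are strict inequalities, so boundary values are
#' retained.
#'
#' @param min_genes,max_genes detected-gene bounds.
#' @param min_counts,max_counts total-count bounds.
#' @param max_mito maximum mitochondrial fraction (a cell is removed only
#'   when its fraction is strictly greater).
#' @export
qc_thresholds <- function(min_genes = 300, max_genes = 7500,
                          min_counts = 500, max_counts = 50000,
                          max_mito = 0.70) {
  stopifnot(min_genes < max_genes, min_counts < max_counts,
            max_mito > 0, max_mito <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito = max_mito),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Retains exactly the cells with min_genes <= nFeature <= max_genes,
#' min_counts <= nCount <= max_counts, and mito_fraction <= max_mito
#' (violations are strict, so cells sitting exactly on a threshold are
#' kept). Idempotent. A per-criterion removal log is attached as the
#' `"qc_log"` attribute and a per-cell pass/fail report as `"qc_report"`.
#'
#' @param cells a `CellMatrix`.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `CellMatrix`.
#' @export
qc_filter <- function(cells, thresholds = qc_thresholds()) {
  stopifnot(inherits(cells, "CellMatrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- cells$meta
  fail <- data.frame(
    cell = m$cell,
    low_genes = m$nFeature < thresholds$min_genes,
    high_genes = m$nFeature > thresholds$max_genes,
    low_counts = m$nCount < thresholds$min_counts,
    high_counts = m$nCount > thresholds$max_counts,
    high_mito = m$mito_fraction > thresholds$max_mito,
    stringsAsFactors = FALSE
  )
  keep <- !(fail$low_genes | fail$high_genes | fail$low_counts |
              fail$high_counts | fail$high_mito)
  fail$pass <- keep
  if (!any(keep)) warnf("qc_filter removed every cell")
  out <- cell_matrix(cells$counts[, keep, drop = FALSE],
                     m[keep, setdiff(names(m),
                                     c("nFeature", "nCount",
                                       "mito_fraction")),
                       drop = FALSE],
                     mito_pattern = cells$mito_pattern)
  counts_removed <- vapply(
    fail[, c("low_genes", "high_genes", "low_counts", "high_counts",
             "high_mito")],
    sum, integer(1)
  )
  attr(out, "qc_log") <- c(counts_removed,
                           removed = sum(!keep), retained = sum(keep))
  attr(out, "qc_report") <- cbind(fail,
                                  m[, c("nFeature", "nCount",
                                        "mito_fraction")])
  out
}

#' Log-normalize counts
#'
#' value = log(1 + count / colsum * scale), the library-size scaling +
#' log1p convention of the standard single-cell toolchain.
#'
#' @param cells a `CellMatrix` (post-QC: no zero-count cells).
#' @param scale library-size scale factor (default 10,000).
#' @return an `ExpressionMatrix`: list(data, scale, meta). Values are
#'   finite, >= 0, zero exactly where the count is zero.
#' @export
normalize_log <- function(cells, scale = 10000) {
  stopifnot(inherits(cells, "CellMatrix"), scale > 0)
  cs <- Matrix::colSums(cells$counts)
  if (any(cs == 0)) {
    stopf("zero total counts for cell(s): %s",
          paste(head(colnames(cells$counts)[cs == 0], 5), collapse = ", "))
  }
  data <- cells$counts
  data@x <- log1p(data@x / rep.int(cs, diff(data@p)) * scale)
  structure(list(data = data, scale = scale, meta = cells$meta),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$data)

#' Select highly variable genes
#'
#' Ranks genes by the z-score of their dispersion (variance/mean of the
#' normalized expression) within 20 equal-occupancy mean-expression bins,
#' after removing genes matching the exclusion patterns (mitochondrial and
#' ribosomal by default). Ties break by gene name, so the ranking does not
#' depend on input gene order.
#'
#' @param expr an `ExpressionMatrix`.
#' @param n number of genes to return (default 5000).
#' @param exclude regex patterns removed before ranking.
#' @param n_bins number of mean-expression bins.
#' @return character vector of gene names, most variable first.
#' @export
select_variable_genes <- function(expr, n = 5000,
                                  exclude = c("^MT-", "^RPS", "^RPL"),
                                  n_bins = 20) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  genes <- rownames(expr$data)
  drop <- Reduce(`|`, lapply(exclude, grepl, x = genes), rep(FALSE,
                                                             length(genes)))
  keep <- genes[!drop]
  x <- expr$data[keep, , drop = FALSE]
  mu <- row_means(x)
  v <- row_vars(x)
  expressed <- mu > 0
  keep <- keep[expressed]
  mu <- mu[expressed]
  v <- v[expressed]
  disp <- v / mu
  ## equal-occupancy bins on the mean; z-score dispersion within each bin
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                         names = FALSE))
  bins <- cut(mu, breaks = brk, include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[v == 0] <- -Inf  # constant genes never outrank any varying gene
  ord <- order(-z, keep)
  ranked <- keep[ord]
  if (n > length(ranked)) {
    warnf("requested %d variable genes but only %d eligible; returning all",
          n, length(ranked))
    n <- length(ranked)
  }
  ranked[seq_len(n)]
}

#' Cluster cells (PCA + k-means stand-in)
#'
#' Scales the selected genes, projects cells onto the top principal
#' components and runs seeded k-means. This is a deterministic stand-in for
#' graph-based community detection: downstream stages only need per-cell
#' labels.
#'
#' @param expr an `ExpressionMatrix`.
#' @param genes genes to use (e.g. from [select_variable_genes()]).
#' @param n_clusters number of clusters (>= 2).
#' @param n_components principal components (capped at
#'   min(genes, cells) - 1).
#' @param seed integer seed.
#' @return integer vector of labels in 0..n_clusters-1, named by cell.
#' @export
cluster_cells <- function(expr, genes, n_clusters, n_components = 30,
                          seed = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), n_clusters >= 2)
  genes <- intersect(genes, rownames(expr$data))
  if (length(genes) < 2) stopf("need >= 2 genes present in the matrix")
  n_cells <- ncol(expr$data)
  if (n_clusters > n_cells) {
    stopf("n_clusters (%d) exceeds the number of cells (%d)",
          n_clusters, n_cells)
  }
  n_components <- min(n_components, length(genes) - 1L, n_cells - 1L)
  x <- t(as.matrix(expr$data[genes, , drop = FALSE]))
  sds <- apply(x, 2, sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds == 0, 1, sds))
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  set.seed(seed)
  km <- kmeans(pc$x, centers = n_clusters, nstart = 10, iter.max = 100)
  setNames(km$cluster - 1L, colnames(expr$data))
}
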