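## Cluster composition across pathologies, the Pearson-residual enrichment
## score against the PN baseline, one-vs-rest marker identification, and
## module-activity scoring.

#' Per-pathology cluster frequencies
#'
#' @param labels per-cell cluster labels.
#' @param pathology per-cell pathology, aligned with `labels`.
#' @return a `FrequencyTable` data.frame (pathology, cluster, count,
#'   frequency); frequencies sum to 1 within each pathology.
#' @export
cluster_frequencies <- function(labels, pathology) {
  stopifnot(length(labels) == length(pathology))
  pathology <- as.factor(pathology)
  empty <- levels(pathology)[tabulate(pathology,
                                      nbins = nlevels(pathology)) == 0]
  if (length(empty)) {
    warnf("pathology level(s) with zero cells excluded: %s",
          paste(empty, collapse = ", "))
    pathology <- droplevels(pathology)
  }
  tab <- table(cluster = as.character(labels), pathology = pathology)
  totals <- colSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("cluster", "pathology", "count")
  out$frequency <- out$count / totals[out$pathology]
  out <- out[order(out$pathology, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FrequencyTable", "data.frame")
  out
}

#' Pearson-residual enrichment score vs the PN baseline
#'
#' score(cluster, p) = (f_obs(cluster, p) - f_exp(cluster)) / sqrt(f_exp),
#' with f_exp the cluster's frequency in the baseline pathology. Baseline
#' scores are fixed at 0. Clusters absent from the baseline (f_exp = 0,
#' f_obs > 0) get the clamp ceiling +0.5 and an `absent_in_baseline` flag.
#' `score_pct` (= 100 x score) matches the percent display scale and the
#' display clamp at +/- 50%; `relative_change` = (obs - exp)/exp is exposed
#' alongside.
#'
#' @param freq a `FrequencyTable` from [cluster_frequencies()].
#' @param baseline baseline pathology (default "PN").
#' @param clamp display clamp half-width on the fractional scale.
#' @return an `EnrichmentTable` data.frame (cluster, pathology, score,
#'   score_pct, score_clamped, relative_change, absent_in_baseline).
#' @export
enrichment_score <- function(freq, baseline = "PN", clamp = 0.5) {
  stopifnot(inherits(freq, "FrequencyTable"))
  if (!baseline %in% freq$pathology) {
    stopf("baseline pathology '%s' not present", baseline)
  }
  base <- freq[freq$pathology == baseline, ]
  f_exp <- setNames(base$frequency, base$cluster)
  out <- freq[, c("cluster", "pathology")]
  fe <- f_exp[out$cluster]
  score <- (freq$frequency - fe) / sqrt(fe)
  absent <- fe == 0 & freq$frequency > 0
  score[fe == 0 & freq$frequency == 0] <- 0
  score[absent] <- clamp
  score[out$pathology == baseline] <- 0
  absent[out$pathology == baseline] <- FALSE
  out$score <- score
  out$score_pct <- 100 * score
  out$score_clamped <- pmin(pmax(score, -clamp), clamp)
  out$relative_change <- ifelse(fe > 0, (freq$frequency - fe) / fe,
                                ifelse(freq$frequency > 0, Inf, 0))
  out$relative_change[out$pathology == baseline] <- 0
  out$absent_in_baseline <- absent
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

## Vectorised one-vs-rest Wilcoxon rank-sum p-values (normal approximation
## with tie correction and continuity correction), per gene.
.wilcox_p <- function(x, in_cluster) {
  n1 <- sum(in_cluster)
  n2 <- sum(!in_cluster)
  n <- n1 + n2
  ranks <- t(apply(x, 1, rank))
  r1 <- rowSums(ranks[, in_cluster, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ## tie correction on the variance
  tie_term <- apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2[sigma2 <= 0] <- NA
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[is.na(p)] <- 1
  pmin(p, 1)
}

#' One-vs-rest cluster markers
#'
#' For each cluster, Wilcoxon rank-sum tests each gene against all other
#' cells. Genes expressed in fewer than `min_pct` of both the in-cluster
#' and out-cluster cells are not tested. avg_log2FC = log2(mean expm1
#' in-cluster + 1) - log2(mean expm1 out-cluster + 1). P-values are
#' Bonferroni-adjusted by the number of genes tested. The returned profile
#' keeps, per cluster, the top `top_n` genes with pct_in >= min_pct,
#' ordered by avg_log2FC (desc), then adjusted p (asc), then gene name.
#'
#' @param expr an `ExpressionMatrix`.
#' @param labels per-cell cluster labels aligned with the matrix columns.
#' @param min_pct minimum detection fraction (default 0.25).
#' @param top_n markers retained per cluster (default 50).
#' @param min_cells clusters smaller than this are skipped with a warning.
#' @return a `ClusterProfile` data.frame (cluster, gene, avg_log2FC, p_val,
#'   p_val_adj, pct_in, pct_out).
#' @export
find_markers <- function(expr, labels, min_pct = 0.25, top_n = 50,
                         min_cells = 3) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            length(labels) == ncol(expr$data))
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stopf("need >= 2 clusters")
  x <- expr$data
  res <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    if (sum(in_cl) < min_cells) {
      warnf("cluster '%s' has < %d cells; skipped", cl, min_cells)
      next
    }
    pct_in <- row_means(x[, in_cl, drop = FALSE] > 0)
    pct_out <- row_means(x[, !in_cl, drop = FALSE] > 0)
    testable <- pct_in >= min_pct | pct_out >= min_pct
    if (!any(testable)) next
    xt <- as.matrix(x[testable, , drop = FALSE])
    mean_in <- rowMeans(expm1(xt[, in_cl, drop = FALSE]))
    mean_out <- rowMeans(expm1(xt[, !in_cl, drop = FALSE]))
    lfc <- log2(mean_in + 1) - log2(mean_out + 1)
    p <- .wilcox_p(xt, in_cl)
    p_adj <- pmin(p * sum(testable), 1)
    df <- data.frame(
      cluster = cl, gene = rownames(xt), avg_log2FC = lfc,
      p_val = p, p_val_adj = p_adj,
      pct_in = pct_in[testable], pct_out = pct_out[testable],
      stringsAsFactors = FALSE
    )
    df <- df[df$pct_in >= min_pct, , drop = FALSE]
    df <- df[order(-df$avg_log2FC, df$p_val_adj, df$gene), , drop = FALSE]
    res[[cl]] <- head(df, top_n)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ClusterProfile", "data.frame")
  out
}

#' Module activity score
#'
#' Mean normalized expression over a gene set, per cell (the "average
#' expression of the top 50 marker genes" definition). Genes missing from
#' the matrix are dropped with a warning. `control_bins > 0` switches on a
#' control-gene adjustment: the mean expression of `control_size` genes
#' sampled from matched mean-expression bins is subtracted.
#'
#' @param expr an `ExpressionMatrix`.
#' @param gene_set character vector of genes.
#' @param control_bins 0 (plain mean, default) or the number of expression
#'   bins for control-gene sampling.
#' @param control_size control genes sampled per gene-set gene.
#' @param seed seed for control-gene sampling.
#' @return named numeric vector, one score per cell.
#' @export
module_activity <- function(expr, gene_set, control_bins = 0,
                            control_size = 10, seed = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(gene_set) > 0)
  present <- intersect(gene_set, rownames(expr$data))
  if (length(present) == 0) {
    stopf("no gene of the set is in the matrix: %s",
          paste(head(gene_set, 10), collapse = ", "))
  }
  if (length(present) < length(gene_set)) {
    warnf("%d gene(s) of the set missing from the matrix; dropped",
          length(gene_set) - length(present))
  }
  score <- Matrix::colMeans(expr$data[present, , drop = FALSE])
  if (control_bins > 0) {
    mu <- row_means(expr$data)
    brk <- unique(quantile(mu, probs = seq(0, 1,
                                           length.out = control_bins + 1),
                           names = FALSE))
    bins <- cut(mu, breaks = brk, include.lowest = TRUE)
    names(bins) <- rownames(expr$data)
    set.seed(seed)
    ctrl <- unique(unlist(lapply(present, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], present)
      if (length(pool) == 0) return(character(0))
      sample(pool, min(control_size, length(pool)))
    })))
    if (length(ctrl) > 0) {
      score <- score - Matrix::colMeans(expr$data[ctrl, , drop = FALSE])
    }
  }
  setNames(as.numeric(score), colnames(expr$data))
}
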