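## Expression-based copy-number inference along genomic coordinates,
## discrete six-state calling (neutral = 3), the per-cell cnv score,
## Ward hierarchical grouping of bridging cells, and the per-cell
## malignant score = indicator x prediction confidence x cnv score.

#' Infer smoothed CNV residual profiles
#'
#' Given normalized expression, gene positions and a set of presumed-diploid
#' reference cells, computes per-cell residual expression profiles along the
#' genome: (1) genes with mean expression < `cutoff` across all cells are
#' dropped; (2) the per-gene reference mean is subtracted; (3) residuals are
#' capped at +/- `cap`; (4) genes are ordered by (chromosome, start) and (5)
#' smoothed by a centered moving average of width `window` within each
#' chromosome (windows shrink at chromosome edges); (6) each cell's median
#' is subtracted; (7) optionally, residuals within +/- `denoise_sd` global
#' reference SDs are zeroed.
#'
#' @param expr an `ExpressionMatrix` holding reference and query cells.
#' @param positions a `GenePositions` table covering >= 80% of the genes.
#' @param reference_cells ids of reference cells (e.g. predicted pericyte,
#'   immune and endothelial cells); must be non-empty.
#' @param query_cells ids of query cells; default: all non-reference cells.
#' @param cutoff minimum mean expression for a gene to enter (default 0.1).
#' @param window moving-average width in genes (default 101).
#' @param cap residual cap (default 3).
#' @param denoise zero small residuals (default TRUE).
#' @param denoise_sd half-width of the zeroed band, in global SDs of the
#'   smoothed reference residuals (default 1.5).
#' @return a `CNVMatrix`: list(matrix = query cells x ordered genes,
#'   ref_matrix, genes (ordered position table), window,
#'   ref_summary (per-gene mean/SD of the smoothed reference residuals),
#'   denoise_band).
#' @export
infer_cnv_profile <- function(expr, positions, reference_cells,
                              query_cells = NULL, cutoff = 0.1,
                              window = 101, cap = 3, denoise = TRUE,
                              denoise_sd = 1.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  cells <- colnames(expr$data)
  if (length(reference_cells) == 0 || !any(reference_cells %in% cells)) {
    stopf("no reference cells present in the expression matrix")
  }
  reference_cells <- intersect(reference_cells, cells)
  if (is.null(query_cells)) query_cells <- setdiff(cells, reference_cells)
  query_cells <- intersect(query_cells, cells)

  genes <- rownames(expr$data)
  covered <- genes %in% positions$gene
  if (mean(covered) < 0.8) {
    stopf("positions cover only %.1f%% of genes (need >= 80%%)",
          100 * mean(covered))
  }
  if (!all(covered)) {
    warnf("%d gene(s) without positions dropped", sum(!covered))
  }
  x <- expr$data[covered, , drop = FALSE]

  ## (1) expression cutoff over all cells
  keep <- row_means(x) >= cutoff
  x <- x[keep, , drop = FALSE]

  ## (4) genomic ordering; chromosomes with < 3 surviving genes excluded
  pos <- positions[match(rownames(x), positions$gene), , drop = FALSE]
  ord <- order(pos$chrom, pos$start)
  pos <- pos[ord, , drop = FALSE]
  x <- x[ord, , drop = FALSE]
  n_per_chrom <- table(droplevels(factor(pos$chrom)))
  bad <- names(n_per_chrom)[n_per_chrom < 3]
  if (length(bad)) {
    warnf("chromosome(s) with < 3 surviving genes excluded: %s",
          paste(bad, collapse = ", "))
    keep <- !(as.character(pos$chrom) %in% bad)
    pos <- pos[keep, , drop = FALSE]
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0) stopf("no genes survive the cutoff")

  ## (2) reference-mean subtraction, (3) cap
  x <- as.matrix(x)
  ref_mean <- rowMeans(x[, reference_cells, drop = FALSE])
  resid <- x - ref_mean
  resid[resid > cap] <- cap
  resid[resid < -cap] <- -cap

  ## (5) within-chromosome moving average
  sm <- resid
  for (ch in unique(as.character(pos$chrom))) {
    rows <- which(as.character(pos$chrom) == ch)
    sm[rows, ] <- roll_mean_shrink(resid[rows, , drop = FALSE], window)
  }

  ## (6) per-cell median centering
  sm <- sweep(sm, 2, apply(sm, 2, median))

  ref_sm <- sm[, reference_cells, drop = FALSE]
  ref_summary <- data.frame(
    gene = rownames(sm),
    ref_mean = rowMeans(ref_sm),
    ref_sd = apply(ref_sm, 1, sd),
    stringsAsFactors = FALSE
  )
  band <- denoise_sd * sd(as.vector(ref_sm))

  ## (7) denoise against the reference noise floor
  if (denoise) sm[abs(sm) <= band] <- 0

  structure(list(
    matrix = t(sm[, query_cells, drop = FALSE]),
    ref_matrix = t(sm[, reference_cells, drop = FALSE]),
    genes = pos,
    window = window,
    ref_summary = ref_summary,
    denoise_band = if (denoise) band else 0
  ), class = "CNVMatrix")
}

#' Call discrete copy-number states
#'
#' Thresholds the smoothed residuals into the six-state convention with
#' neutral = 3: state 3 where |r| <= t1; gains 4/5/6 above t1/t2/t3; losses
#' 2/1 below -t1/-t2.
#'
#' @param cnv a `CNVMatrix`.
#' @param thresholds increasing positive thresholds (t1, t2, t3) in
#'   smoothed-residual units.
#' @return a `CNVStates`: integer matrix (cells x genes) with values in
#'   1..6.
#' @export
call_cnv_states <- function(cnv, thresholds = c(0.15, 0.4, 0.7)) {
  stopifnot(inherits(cnv, "CNVMatrix"), length(thresholds) == 3,
            all(diff(thresholds) > 0), thresholds[1] > 0)
  x <- cnv$matrix
  stopifnot(all(is.finite(x)))
  t1 <- thresholds[1]; t2 <- thresholds[2]; t3 <- thresholds[3]
  states <- matrix(3L, nrow(x), ncol(x), dimnames = dimnames(x))
  states[x > t1] <- 4L
  states[x > t2] <- 5L
  states[x > t3] <- 6L
  states[x < -t1] <- 2L
  states[x < -t2] <- 1L
  structure(states, class = c("CNVStates", class(states)))
}

#' Per-cell cnv score
#'
#' Aggregates each cell's deviation from the neutral state 3:
#' sum((state - 3)^2) / 2 (default), or sum(|state - 3|) / 2 with
#' `method = "absolute"`. Always >= 0, zero for an all-neutral cell,
#' invariant to gene order and monotone in every |state - 3|.
#'
#' @param states a `CNVStates` matrix (cells x genes).
#' @param method "squared" (default) or "absolute".
#' @return named numeric vector, one score per cell.
#' @export
cnv_score <- function(states, method = c("squared", "absolute")) {
  method <- match.arg(method)
  d <- unclass(states) - 3
  s <- if (method == "squared") rowSums(d^2) / 2 else rowSums(abs(d)) / 2
  setNames(as.numeric(s), rownames(states))
}

#' Hierarchical grouping of bridging cells by CNV profile
#'
#' Ward-linkage agglomerative clustering (Euclidean distance, ward.D2) of
#' the smoothed CNV profiles, cut at `n_groups`. Used to split the bridging
#' malignant cluster into CNV-defined groups.
#'
#' @param cnv a `CNVMatrix`.
#' @param cells cell ids to group (default: all query cells in `cnv`).
#' @param n_groups number of groups (default 8).
#' @return named integer vector of group labels in 1..n_groups.
#' @export
bridging_groups <- function(cnv, cells = NULL, n_groups = 8) {
  stopifnot(inherits(cnv, "CNVMatrix"))
  x <- cnv$matrix
  if (!is.null(cells)) {
    missing <- setdiff(cells, rownames(x))
    if (length(missing)) {
      stopf("cell(s) missing from the CNV matrix: %s",
            paste(head(missing, 5), collapse = ", "))
    }
    x <- x[cells, , drop = FALSE]
  }
  if (n_groups > nrow(x)) {
    stopf("n_groups (%d) exceeds the number of cells (%d)",
          n_groups, nrow(x))
  }
  hc <- hclust(dist(x), method = "ward.D2")
  cutree(hc, k = n_groups)
}

#' Per-cell malignant score
#'
#' malignant_score = indicator x prediction_score_max x cnv_score, with
#' indicator = 1 iff the transferred label is one of the malignant cell
#' types and 0 otherwise (in which case the score is exactly 0).
#'
#' @param pred a `PredictionTable`.
#' @param scores named per-cell cnv scores covering every cell in `pred`.
#' @param malignant_types labels treated as malignant (default
#'   [malignant_cell_types()]).
#' @return a `MalignantScoreTable` data.frame: cell, predicted_label,
#'   is_malignant, prediction_score_max, cnv_score, malignant_score.
#' @export
malignant_score <- function(pred, scores,
                            malignant_types = malignant_cell_types()) {
  stopifnot(inherits(pred, "PredictionTable"))
  missing <- setdiff(pred$cell, names(scores))
  if (length(missing)) {
    stopf("cnv score missing for cell(s): %s",
          paste(head(missing, 5), collapse = ", "))
  }
  ind <- as.integer(pred$predicted_label %in% malignant_types)
  cs <- as.numeric(scores[pred$cell])
  out <- data.frame(
    cell = pred$cell,
    predicted_label = pred$predicted_label,
    is_malignant = ind,
    prediction_score_max = pred$prediction_score_max,
    cnv_score = cs,
    malignant_score = ind * pred$prediction_score_max * cs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("MalignantScoreTable", "data.frame")
  out
}
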