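## Reference-based cell-type prediction: a principal-component reference
## basis plus a distance-weighted k-nearest-neighbor vote producing, per
## query cell, class-membership scores in [0,1] that sum to 1, a predicted
## label, and the "prediction.score.max" confidence used downstream in the
## malignant score.

#' Fit a reference model
#'
#' Centers and scales the reference expression on the given genes, computes
#' a principal-component basis, and stores the reference embeddings and
#' labels. Component signs are fixed by the largest-loading convention so
#' repeated fits are identical.
#'
#' @param expr reference `ExpressionMatrix`.
#' @param labels per-cell reference class labels.
#' @param genes genes spanning the basis (e.g. variable genes).
#' @param n_components number of components (< min(n_genes, n_cells)).
#' @return a `ReferenceModel`: list(genes, center, scale, rotation,
#'   embeddings, labels).
#' @export
fit_reference <- function(expr, labels, genes, n_components = 30) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            length(labels) == ncol(expr$data))
  genes <- intersect(genes, rownames(expr$data))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stopf("need >= 2 reference classes")
  small <- names(which(table(labels) < 3))
  if (length(small)) {
    warnf("reference class(es) with < 3 cells: %s",
          paste(small, collapse = ", "))
  }
  n_components <- min(n_components, length(genes) - 1L,
                      ncol(expr$data) - 1L)
  x <- t(as.matrix(expr$data[genes, , drop = FALSE]))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  ## sign convention: the largest-magnitude loading of each component is
  ## positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  emb <- xs %*% rot
  structure(list(genes = genes, center = ctr, scale = scl, rotation = rot,
                 embeddings = emb, labels = labels),
            class = "ReferenceModel")
}

#' Transfer reference labels to query cells
#'
#' Projects query cells with the reference centering/scaling and basis,
#' then scores each reference class by a distance-weighted k-nearest-
#' neighbor vote with weight 1/(d + eps), normalized to sum to 1. Model
#' genes missing from the query are imputed at the reference mean (zero
#' after centering). Requires >= 50% of model genes in the query.
#'
#' @param model a `ReferenceModel`.
#' @param query query `ExpressionMatrix`.
#' @param k neighbors (default 30).
#' @param eps distance regularizer in the vote weight.
#' @return a `PredictionTable` data.frame: cell, predicted_label,
#'   prediction_score_max, and one `score.<class>` column per reference
#'   class (rows sum to 1). The raw score matrix is attached as the
#'   `"scores"` attribute.
#' @export
transfer_labels <- function(model, query, k = 30, eps = 1e-9) {
  stopifnot(inherits(model, "ReferenceModel"),
            inherits(query, "ExpressionMatrix"))
  present <- intersect(model$genes, rownames(query$data))
  overlap <- length(present) / length(model$genes)
  if (overlap < 0.5) {
    stopf("only %.1f%% of model genes present in query (need >= 50%%)",
          100 * overlap)
  }
  n_q <- ncol(query$data)
  qx <- matrix(rep(model$center, each = n_q), nrow = n_q,
               dimnames = list(colnames(query$data), model$genes))
  qx[, present] <- t(as.matrix(query$data[present, , drop = FALSE]))
  qx <- scale(qx, center = model$center, scale = model$scale)
  emb_q <- qx %*% model$rotation

  ref <- model$embeddings
  classes <- sort(unique(model$labels))
  k <- min(k, nrow(ref))
  ## squared euclidean distances via the cross-product expansion
  d2 <- outer(rowSums(emb_q^2), rep(1, nrow(ref))) +
    outer(rep(1, n_q), rowSums(ref^2)) - 2 * emb_q %*% t(ref)
  d2[d2 < 0] <- 0
  scores <- matrix(0, n_q, length(classes),
                   dimnames = list(rownames(emb_q), classes))
  lab_idx <- match(model$labels, classes)
  for (i in seq_len(n_q)) {
    nn <- order(d2[i, ], model$labels)[seq_len(k)]
    w <- 1 / (sqrt(d2[i, nn]) + eps)
    vote <- vapply(seq_along(classes),
                   function(j) sum(w[lab_idx[nn] == j]), numeric(1))
    scores[i, ] <- vote / sum(vote)
  }
  max_idx <- apply(scores, 1, which.max)
  out <- data.frame(
    cell = rownames(scores),
    predicted_label = classes[max_idx],
    prediction_score_max = scores[cbind(seq_len(n_q), max_idx)],
    stringsAsFactors = FALSE
  )
  score_df <- as.data.frame(scores)
  names(score_df) <- paste0("score.", classes)
  out <- cbind(out, score_df)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  class(out) <- c("PredictionTable", "data.frame")
  out
}

#' Count predicted malignant cells per sample
#'
#' @param pred a `PredictionTable`.
#' @param samples per-cell sample ids aligned with `pred`.
#' @param malignant_types labels counted as malignant (default the three
#'   malignant cell types, [malignant_cell_types()]).
#' @return data.frame (sample, n_cells, n_malignant, fraction).
#' @export
count_malignant <- function(pred, samples,
                            malignant_types = malignant_cell_types()) {
  stopifnot(inherits(pred, "PredictionTable"),
            length(samples) == nrow(pred))
  is_mal <- pred$predicted_label %in% malignant_types
  out <- data.frame(
    sample = sort(unique(as.character(samples))),
    stringsAsFactors = FALSE
  )
  out$n_cells <- as.integer(table(samples)[out$sample])
  nm <- tapply(is_mal, samples, sum)
  out$n_malignant <- as.integer(nm[out$sample])
  out$fraction <- out$n_malignant / out$n_cells
  rownames(out) <- NULL
  out
}
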