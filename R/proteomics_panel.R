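## Plasma proteomics: NPX preprocessing (LOD imputation + per-protein
## standardization), vectorised ANOVA + Tukey HSD differential abundance,
## scRNA-seq-informed panel selection, per-protein one-versus-all ROC
## metrics, SVM kernel selection by LOOCV, the repeated cross-validated
## "MPNST probability score", and model evaluation.

#' Construct an NPXMatrix
#'
#' @param npx samples x proteins numeric matrix (NPX, log2-like scale) with
#'   sample rownames and protein colnames.
#' @param lod named per-protein limit of detection (use -Inf for none).
#' @param diagnosis per-sample factor over healthy/PN/AN/MPNST.
#' @param below_lod optional logical matrix flagging censored values;
#'   computed as npx < lod when missing.
#' @param scaled whether values are already standardized.
#' @return an `NPXMatrix` list.
#' @export
npx_matrix <- function(npx, lod, diagnosis, below_lod = NULL,
                       scaled = FALSE) {
  stopifnot(is.matrix(npx), !is.null(rownames(npx)), !is.null(colnames(npx)),
            length(diagnosis) == nrow(npx))
  if (is.null(names(lod))) names(lod) <- colnames(npx)
  lod <- lod[colnames(npx)]
  if (is.null(below_lod)) below_lod <- sweep(npx, 2, lod, "<")
  stopifnot(identical(dim(below_lod), dim(npx)))
  structure(list(npx = npx, lod = lod,
                 below_lod = below_lod,
                 diagnosis = factor(diagnosis,
                                    levels = c("healthy", "PN", "AN",
                                               "MPNST")),
                 scaled = scaled),
            class = "NPXMatrix")
}

#' @export
dim.NPXMatrix <- function(x) dim(x$npx)

#' Preprocess NPX values
#'
#' Values flagged below the limit of detection are replaced by LOD/sqrt(2);
#' each protein is then rescaled to mean 0 and SD 1 (population SD).
#' Proteins with zero variance after imputation cannot be scaled and are
#' dropped with a warning. Above-LOD values are never touched by the
#' imputation, and the censoring flags are preserved.
#'
#' @param raw an `NPXMatrix`.
#' @param standardize rescale each protein after imputation (default TRUE);
#'   FALSE returns the imputed, unscaled values.
#' @return the preprocessed `NPXMatrix` (`scaled = TRUE` when standardized).
#' @export
preprocess_npx <- function(raw, standardize = TRUE) {
  stopifnot(inherits(raw, "NPXMatrix"))
  x <- raw$npx
  flag <- raw$below_lod
  if (any(flag)) {
    cens_prot <- colnames(x)[colSums(flag) > 0]
    if (any(!is.finite(raw$lod[cens_prot]))) {
      stopf("below-LOD values present for protein(s) without a finite LOD")
    }
    imput <- matrix(rep(raw$lod / sqrt(2), each = nrow(x)), nrow = nrow(x))
    x[flag] <- imput[flag]
  }
  if (!standardize) {
    return(npx_matrix(x, lod = raw$lod, diagnosis = raw$diagnosis,
                      below_lod = flag, scaled = FALSE))
  }
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(pmax(0, colMeans(x^2) - mu^2))
  constant <- sd_pop == 0
  if (any(constant)) {
    warnf("dropping %d zero-variance protein(s): %s", sum(constant),
          paste(head(colnames(x)[constant], 5), collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    flag <- flag[, !constant, drop = FALSE]
    mu <- mu[!constant]
    sd_pop <- sd_pop[!constant]
  }
  x <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  npx_matrix(x, lod = (raw$lod[colnames(x)] - mu) / sd_pop,
             diagnosis = raw$diagnosis, below_lod = flag, scaled = TRUE)
}

#' Differential protein abundance (ANOVA + Tukey HSD)
#'
#' Per protein: one-way ANOVA over the diagnosis groups, Tukey HSD adjusted
#' p-values for every pairwise group comparison (studentised-range
#' distribution on the ANOVA mean-square error), the MPNST - PN mean
#' difference (delta NPX), and a Benjamini-Hochberg adjustment across
#' proteins applied to the MPNST-vs-PN Tukey p-values. The unadjusted
#' pairwise p (pooled-MSE t-test) for MPNST vs PN is emitted alongside as
#' `p_mpnst_pn_raw`: it is the uniform-under-the-null quantity, whereas the
#' Tukey p is family-adjusted and conservative for a single pair.
#'
#' @param npx an `NPXMatrix` (typically after [preprocess_npx()]).
#' @return a `DiffTable` data.frame: protein, anova_p, one
#'   `tukey_p_<A>_vs_<B>` column per group pair, delta_npx
#'   (MPNST mean - PN mean), p_mpnst_pn_raw, tukey_p_mpnst_pn,
#'   p_adj (BH across proteins).
#' @export
differential_abundance <- function(npx) {
  stopifnot(inherits(npx, "NPXMatrix"))
  g <- droplevels(npx$diagnosis)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warnf("group(s) with < 2 samples excluded from ANOVA: %s",
          paste(small, collapse = ", "))
    keep <- !(as.character(g) %in% small)
    g <- droplevels(g[keep])
    x <- npx$npx[keep, , drop = FALSE]
  } else {
    x <- npx$npx
  }
  k <- nlevels(g)
  if (k < 2) stopf("need >= 2 groups with >= 2 samples")
  n <- length(g)
  nj <- as.numeric(table(g))
  ## group means per protein: k x P
  gm <- rowsum(x, g) / nj
  grand <- colMeans(x)
  ssb <- colSums(nj * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(x, 2, grand)^2)
  sse <- pmax(0, sst - ssb)
  df1 <- k - 1
  df2 <- n - k
  mse <- sse / df2
  f <- (ssb / df1) / mse
  anova_p <- pf(f, df1, df2, lower.tail = FALSE)

  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(protein = colnames(x), anova_p = anova_p,
                    stringsAsFactors = FALSE)
  tukey_mpnst_pn <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- nj[match(a, lev)]; nb <- nj[match(b, lev)]
    se <- sqrt(mse / 2 * (1 / na + 1 / nb))
    q <- abs(gm[a, ] - gm[b, ]) / se
    p <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    col <- sprintf("tukey_p_%s_vs_%s", a, b)
    out[[col]] <- p
    if (setequal(c(a, b), c("MPNST", "PN"))) tukey_mpnst_pn <- p
  }
  if (all(c("MPNST", "PN") %in% lev)) {
    out$delta_npx <- as.numeric(gm["MPNST", ] - gm["PN", ])
    nm <- nj[match("MPNST", lev)]
    np <- nj[match("PN", lev)]
    tstat <- abs(out$delta_npx) / sqrt(mse * (1 / nm + 1 / np))
    out$p_mpnst_pn_raw <- 2 * stats::pt(tstat, df2, lower.tail = FALSE)
    out$tukey_p_mpnst_pn <- tukey_mpnst_pn
    out$p_adj <- p.adjust(tukey_mpnst_pn, method = "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("DiffTable", "data.frame")
  out
}

#' Select the scRNA-seq-informed protein panel
#'
#' Forward selection of circulating proteins by three rules: (1) elevated in
#' MPNST plasma relative to PN (adjusted p < `alpha` and delta NPX > 0);
#' (2) the encoded gene is a cluster marker; (3) that cluster's MPNST-vs-PN
#' enrichment score exceeds `min_enrichment` (percent scale, matching the
#' "> 25" convention). Proteins without a gene mapping are excluded and
#' logged in the `"unmapped"` attribute.
#'
#' @param diff a `DiffTable`.
#' @param markers a `ClusterProfile` from [find_markers()].
#' @param enrich an `EnrichmentTable` from [enrichment_score()].
#' @param gene_map data.frame (protein, gene).
#' @param min_enrichment minimum cluster enrichment, percent units
#'   (default 25).
#' @param alpha significance cutoff on the adjusted MPNST-vs-PN p
#'   (default 0.05).
#' @return a `PanelSpec` data.frame: protein, gene, cluster,
#'   enrichment_pct, delta_npx, p_adj; thresholds in attributes.
#' @export
select_panel <- function(diff, markers, enrich, gene_map,
                         min_enrichment = 25, alpha = 0.05) {
  stopifnot(inherits(diff, "DiffTable"),
            all(c("protein", "gene") %in% names(gene_map)))
  if (!all(c("delta_npx", "p_adj") %in% names(diff))) {
    stopf("diff table lacks the MPNST-vs-PN comparison")
  }
  enriched <- enrich[enrich$pathology == "MPNST" &
                       enrich$score_pct > min_enrichment, , drop = FALSE]
  marker_rows <- markers[markers$cluster %in% enriched$cluster, ,
                         drop = FALSE]
  unmapped <- setdiff(diff$protein, gene_map$protein)
  de <- diff[diff$protein %in% gene_map$protein &
               !is.na(diff$p_adj) & diff$p_adj < alpha &
               diff$delta_npx > 0, , drop = FALSE]
  de$gene <- gene_map$gene[match(de$protein, gene_map$protein)]
  hit <- de[de$gene %in% marker_rows$gene, , drop = FALSE]
  if (nrow(hit) == 0) {
    stopf(paste("no protein passed all three filters;",
                "consider relaxing min_enrichment or alpha"))
  }
  ## source cluster: among enriched clusters marking the gene, the most
  ## enriched one
  esc <- setNames(enriched$score_pct, enriched$cluster)
  src <- vapply(hit$gene, function(gn) {
    cl <- marker_rows$cluster[marker_rows$gene == gn]
    cl[which.max(esc[cl])]
  }, character(1))
  out <- data.frame(
    protein = hit$protein, gene = hit$gene, cluster = src,
    enrichment_pct = as.numeric(esc[src]),
    delta_npx = hit$delta_npx, p_adj = hit$p_adj,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$delta_npx, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(min_enrichment = min_enrichment,
                                  alpha = alpha)
  attr(out, "unmapped") <- unmapped
  class(out) <- c("PanelSpec", "data.frame")
  out
}

#' Per-protein one-versus-all ROC metrics
#'
#' For every protein, the ROC of its NPX value against the positive
#' diagnosis (default MPNST vs everything else, healthy included): AUC by
#' trapezoid, and the Youden-optimal threshold with its sensitivity and
#' specificity. Panel-level medians and IQRs are attached as the
#' `"summary"` attribute.
#'
#' @param npx an `NPXMatrix`.
#' @param proteins proteins to evaluate (default all).
#' @param positive the positive diagnosis (default "MPNST").
#' @return data.frame: protein, auc, youden_j, threshold, sensitivity,
#'   specificity.
#' @export
per_protein_ova <- function(npx, proteins = NULL, positive = "MPNST") {
  stopifnot(inherits(npx, "NPXMatrix"))
  if (!positive %in% npx$diagnosis) {
    stopf("positive class '%s' not present", positive)
  }
  if (is.null(proteins)) proteins <- colnames(npx$npx)
  y <- npx$diagnosis == positive
  rows <- lapply(proteins, function(p) {
    r <- roc_curve(npx$npx[, p], y)
    data.frame(protein = p, auc = r$auc, youden_j = r$youden_j,
               threshold = r$youden_threshold,
               sensitivity = r$sensitivity, specificity = r$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- vapply(
    c(auc = "auc", sensitivity = "sensitivity",
      specificity = "specificity"),
    function(cl) c(median = median(out[[cl]]),
                   q25 = quantile(out[[cl]], 0.25, names = FALSE),
                   q75 = quantile(out[[cl]], 0.75, names = FALSE)),
    numeric(3)
  )
  out
}

#' SVM configuration
#'
#' @param kernel one of linear/radial/polynomial/sigmoid.
#' @param cost SVM cost parameter C (fixed at 1 in the reference protocol
#'   to limit overfitting at small cohort sizes).
#' @param n_repeats cross-validation repeats (default 10).
#' @param n_folds folds per repeat (default 5).
#' @param seed base seed; repeat r uses seed + r.
#' @export
svm_config <- function(kernel = c("radial", "linear", "polynomial",
                                  "sigmoid"),
                       cost = 1, n_repeats = 10, n_folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, n_folds >= 2, n_repeats >= 1)
  structure(list(kernel = kernel, cost = cost, n_repeats = n_repeats,
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "svm_config")
}

.svm_fit_predict <- function(x_train, y_train, x_test, kernel, cost, seed) {
  set.seed(seed)
  fit <- e1071::svm(x = x_train, y = y_train, kernel = kernel, cost = cost,
                    probability = TRUE, scale = FALSE)
  pr <- predict(fit, x_test, probability = TRUE)
  attr(pr, "probabilities")[, "TRUE"]
}

#' Select the SVM kernel by leave-one-out cross-validation
#'
#' Runs LOOCV over the panel proteins for each candidate kernel, recording
#' accuracy (0.5 probability threshold) and AUC of the held-out
#' probabilities, then picks the kernel with the highest accuracy among
#' those with AUC > `min_auc`; remaining ties break by AUC, then by the
#' fixed kernel order.
#'
#' @param npx an `NPXMatrix`.
#' @param panel protein names (e.g. a `PanelSpec`'s proteins).
#' @param kernels candidate kernels.
#' @param min_auc AUC floor a kernel must maintain (default 0.8).
#' @param positive positive diagnosis (default "MPNST").
#' @param cost SVM cost (default 1).
#' @param seed seed for the probability-calibration internals.
#' @return list(kernel, table) where table has kernel, accuracy, auc.
#' @export
select_kernel <- function(npx, panel,
                          kernels = c("linear", "radial", "polynomial",
                                      "sigmoid"),
                          min_auc = 0.8, positive = "MPNST", cost = 1,
                          seed = 1) {
  stopifnot(inherits(npx, "NPXMatrix"), length(panel) > 0)
  if (nrow(npx$npx) < 10) stopf("need >= 10 samples for kernel selection")
  x <- npx$npx[, panel, drop = FALSE]
  y <- factor(npx$diagnosis == positive, levels = c("FALSE", "TRUE"))
  n <- nrow(x)
  tab <- data.frame(kernel = kernels, accuracy = NA_real_, auc = NA_real_,
                    stringsAsFactors = FALSE)
  for (ki in seq_along(kernels)) {
    prob <- numeric(n)
    for (i in seq_len(n)) {
      prob[i] <- .svm_fit_predict(x[-i, , drop = FALSE], y[-i],
                                  x[i, , drop = FALSE],
                                  kernels[ki], cost,
                                  seed = derive_seed(seed, kernels[ki]))
    }
    tab$accuracy[ki] <- mean((prob >= 0.5) == (y == "TRUE"))
    tab$auc[ki] <- roc_curve(prob, y == "TRUE")$auc
  }
  ok <- tab$auc > min_auc
  if (!any(ok)) {
    stopf("no kernel reached AUC > %.2f: %s", min_auc,
          paste(sprintf("%s acc=%.3f auc=%.3f", tab$kernel, tab$accuracy,
                        tab$auc), collapse = "; "))
  }
  cand <- which(ok)
  cand <- cand[order(-tab$accuracy[cand], -tab$auc[cand], cand)]
  list(kernel = tab$kernel[cand[1]], table = tab)
}

#' MPNST probability score (repeated cross-validated SVM)
#'
#' One-versus-all (MPNST vs healthy+PN+AN): for each repeat, a stratified
#' k-fold split; an SVM (chosen kernel, C, Platt-calibrated probabilities)
#' is fit on the training folds and the held-out probability recorded for
#' every sample. The per-sample median across repeats is the MPNST
#' probability score. Fold assignment is keyed to sorted sample ids, so the
#' scores do not depend on input row order.
#'
#' @param npx an `NPXMatrix`.
#' @param panel protein names used as features.
#' @param config an [svm_config()].
#' @param positive positive diagnosis (default "MPNST").
#' @return data.frame: sample, diagnosis, mpnst_probability (in `[0,1]`);
#'   the samples x repeats probability matrix is the `"repeats"` attribute.
#' @export
mpnst_probability <- function(npx, panel, config = svm_config(),
                              positive = "MPNST") {
  stopifnot(inherits(npx, "NPXMatrix"), inherits(config, "svm_config"))
  missing <- setdiff(panel, colnames(npx$npx))
  if (length(missing)) {
    stopf("panel protein(s) missing from the NPX matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  ## canonical sample order so results are invariant to input row order
  ord <- order(rownames(npx$npx))
  x <- npx$npx[ord, panel, drop = FALSE]
  diagnosis <- npx$diagnosis[ord]
  ids <- rownames(x)
  y <- factor(diagnosis == positive, levels = c("FALSE", "TRUE"))
  if (min(table(y)) < config$n_folds) {
    stopf("the smaller class (%d samples) cannot stratify %d folds",
          min(table(y)), config$n_folds)
  }
  probs <- matrix(NA_real_, length(ids), config$n_repeats,
                  dimnames = list(ids, NULL))
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(ids, y, config$n_folds, config$seed + r)
    for (f in seq_len(config$n_folds)) {
      test <- folds == f
      probs[test, r] <- .svm_fit_predict(
        x[!test, , drop = FALSE], y[!test], x[test, , drop = FALSE],
        config$kernel, config$cost,
        seed = derive_seed(config$seed + r, paste0("fold", f))
      )
    }
  }
  out <- data.frame(
    sample = ids,
    diagnosis = diagnosis,
    mpnst_probability = apply(probs, 1, median),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "repeats") <- probs
  out
}

#' Evaluate a probability score against labels
#'
#' ROC/AUC of the scores, plus sensitivity/specificity and confusion counts
#' both at the fixed threshold (default 0.5, "MPNST when >= threshold") and
#' at the Youden-optimal threshold. Constant scores yield a degenerate ROC,
#' flagged with AUC 0.5.
#'
#' @param scores per-sample probability scores.
#' @param labels logical (or coercible) positives, aligned with scores.
#' @param threshold fixed decision threshold (default 0.5).
#' @return list(auc, roc, degenerate, at_threshold, at_youden), each
#'   operating point carrying threshold, sensitivity, specificity and the
#'   confusion counts tp/fp/tn/fn.
#' @export
evaluate_model <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stopf("both classes must be present to evaluate")
  }
  r <- roc_curve(scores, labels)
  auc <- if (r$degenerate) 0.5 else r$auc
  point <- function(t) {
    pred <- scores >= t
    list(threshold = t,
         tp = sum(pred & labels), fp = sum(pred & !labels),
         tn = sum(!pred & !labels), fn = sum(!pred & labels),
         sensitivity = sum(pred & labels) / sum(labels),
         specificity = sum(!pred & !labels) / sum(!labels))
  }
  list(auc = auc, roc = r$points, degenerate = r$degenerate,
       at_threshold = point(threshold),
       at_youden = point(r$youden_threshold))
}
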