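#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats rnorm rlnorm rnbinom rmultinom quantile median sd var
#'   prcomp kmeans hclust cutree dist pf ptukey p.adjust pnorm predict
#'   aggregate setNames
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Row means/variances that work for both dense and Matrix sparse inputs.
row_means <- function(x) {
  if (inherits(x, "Matrix")) Matrix::rowMeans(x) else rowMeans(x)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(setNames(rep(0, nrow(x)), rownames(x)))
  mu <- row_means(x)
  if (inherits(x, "Matrix")) {
    ex2 <- Matrix::rowMeans(x^2)
  } else {
    ex2 <- rowMeans(x^2)
  }
  pmax(0, (ex2 - mu^2) * n / (n - 1))
}

col_sums <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colSums(x) else colSums(x)
}

## Centered moving average along rows with shrinking windows at the edges.
## x: numeric matrix (rows are ordered positions), w: odd window width.
roll_mean_shrink <- function(x, w) {
  g <- nrow(x)
  if (g == 0L || w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(x, 2L, cumsum))
  lo <- pmax(1L, seq_len(g) - h)
  hi <- pmin(g, seq_len(g) + h)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  dimnames(out) <- dimnames(x)
  out
}

## Deterministic per-stage seed derived from a base seed and a stage name,
## kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(stage)) * 977) %% 2147483647)
}

## Empirical ROC of a score against a binary label (TRUE = positive).
## AUC by trapezoid over the full empirical curve; Youden J maximised over
## observed thresholds (rule: predict positive when score >= threshold).
roc_curve <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stopf("ROC needs both classes; got %d positives and %d negatives", n1, n0)
  }
  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(score[positive] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(score[!positive] < t), numeric(1))
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- sens + spec - 1
  best <- which.max(j)
  degenerate <- length(thr) == 1L
  list(
    points = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
    auc = auc,
    youden_j = j[best],
    youden_threshold = thr[best],
    sensitivity = sens[best],
    specificity = spec[best],
    degenerate = degenerate
  )
}

## Stratified fold assignment keyed to sorted sample ids so the folds do not
## depend on the row order of the input.
stratified_folds <- function(ids, strata, n_folds, seed) {
  ord <- order(ids)
  folds <- integer(length(ids))
  set.seed(seed)
  for (g in unique(strata[ord])) {
    idx <- ord[strata[ord] == g]
    if (length(idx) < n_folds && length(unique(strata)) > 1L) {
      ## small class: still spread across folds as evenly as possible
    }
    perm <- idx[sample.int(length(idx))]
    folds[perm] <- rep_len(seq_len(n_folds), length(perm))
  }
  folds
}
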