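## A direct expression fixture for the CNV smoother: genes laid out on two
## chromosomes, reference cells around a per-gene baseline, query cells
## carrying an additive shift over a contiguous segment.
make_cnv_fixture <- function(n_genes = 400, n_ref = 60, n_query = 40,
                             shift = 0.8, seg = 51:200, seed = 5) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  positions <- simulate_gene_positions(n_genes, 2, seed = seed,
                                       gene_names = genes)
  base <- runif(n_genes, 0.5, 2)
  x <- matrix(rnorm(n_genes * (n_ref + n_query), sd = 0.3),
              n_genes, n_ref + n_query) + base
  x[x < 0] <- 0
  colnames(x) <- c(sprintf("ref%03d", seq_len(n_ref)),
                   sprintf("qry%03d", seq_len(n_query)))
  rownames(x) <- genes
  x[seg, (n_ref + 1):(n_ref + n_query)] <-
    x[seg, (n_ref + 1):(n_ref + n_query)] + shift
  list(expr = as_expression(x), positions = positions,
       ref = colnames(x)[seq_len(n_ref)],
       query = colnames(x)[(n_ref + 1):(n_ref + n_query)],
       seg_genes = genes[seg])
}

test_that("reference cells as their own query give a null profile", {
  fx <- make_cnv_fixture()
  cnv <- infer_cnv_profile(fx$expr, fx$positions, fx$ref,
                           query_cells = fx$ref)
  ## post-denoise the self-reference matrix is (almost) all zero
  expect_lt(mean(abs(cnv$matrix)), 0.01)
  expect_gt(mean(cnv$matrix == 0), 0.85)
})

test_that("a constant per-cell shift is removed by median centering", {
  fx <- make_cnv_fixture(shift = 0, seg = 1:2)
  ## one query cell equal to the reference mean plus a constant
  x <- as.matrix(fx$expr$data)
  ref_mean <- rowMeans(x[, fx$ref])
  x[, fx$query[1]] <- ref_mean + 0.7
  cnv <- infer_cnv_profile(as_expression(x), fx$positions, fx$ref,
                           query_cells = fx$query[1], denoise = FALSE)
  expect_lt(max(abs(cnv$matrix)), 1e-9)
})

test_that("per-cell medians vanish after centering", {
  fx <- make_cnv_fixture()
  cnv <- infer_cnv_profile(fx$expr, fx$positions, fx$ref, denoise = FALSE)
  med <- apply(cnv$matrix, 1, median)
  expect_lt(max(abs(med)), 1e-9)
})

test_that("planted segments dominate the smoothed residuals", {
  fx <- make_cnv_fixture()
  cnv <- infer_cnv_profile(fx$expr, fx$positions, fx$ref)
  inside <- colnames(cnv$matrix) %in% fx$seg_genes
  in_mean <- rowMeans(cnv$matrix[, inside, drop = FALSE])
  out_mean <- rowMeans(cnv$matrix[, !inside, drop = FALSE])
  ## every planted query cell shows the gain
  expect_true(all(in_mean > out_mean))
  ## diploid background stays below 10% of the planted amplitude
  expect_lt(mean(abs(cnv$matrix[, !inside])), 0.1 * 0.8)
})

test_that("state calling maps residual bands to the six-state convention", {
  fx <- make_cnv_fixture(n_genes = 40, n_ref = 5, n_query = 3,
                         shift = 0, seg = 1:2)
  cnv <- infer_cnv_profile(fx$expr, fx$positions, fx$ref, window = 1,
                           denoise = FALSE)
  ## overwrite the matrix with crafted residuals
  vals <- c(0, 0.1, -0.1, 0.2, -0.2, 0.5, -0.5, 1.0, -1.0)
  cnv$matrix <- matrix(rep(vals, length.out = length(cnv$matrix)),
                       nrow(cnv$matrix), ncol(cnv$matrix),
                       dimnames = dimnames(cnv$matrix))
  st <- call_cnv_states(cnv)
  lookup <- function(v) unique(st[cnv$matrix == v])
  expect_equal(lookup(0), 3L)
  expect_equal(lookup(0.1), 3L)    # inside the neutral band
  expect_equal(lookup(0.2), 4L)
  expect_equal(lookup(-0.2), 2L)
  expect_equal(lookup(0.5), 5L)
  expect_equal(lookup(-0.5), 1L)
  expect_equal(lookup(1.0), 6L)
  expect_equal(lookup(-1.0), 1L)
  ## all-zero residuals: everything neutral
  cnv$matrix[] <- 0
  expect_true(all(call_cnv_states(cnv) == 3L))
  cnv$matrix[] <- 1.0
  expect_true(all(call_cnv_states(cnv) == 6L))
})

test_that("cnv_score evaluates the squared-deviation formula", {
  st <- matrix(3L, 2, 4, dimnames = list(c("a", "b"), paste0("g", 1:4)))
  class(st) <- c("CNVStates", class(st))
  expect_equal(unname(cnv_score(st)), c(0, 0))
  st["a", 1] <- 5L                       # (5-3)^2 / 2 = 2
  expect_equal(unname(cnv_score(st)["a"]), 2.0)
  st["b", 1] <- 1L; st["b", 2] <- 6L     # 4/2 + 9/2 = 6.5
  expect_equal(unname(cnv_score(st)["b"]), 6.5)
  ## absolute variant: |1-3|/2 + |6-3|/2 = 2.5
  expect_equal(unname(cnv_score(st, method = "absolute")["b"]), 2.5)
  ## permutation invariance over genes and monotonicity
  perm <- c(3, 1, 4, 2)
  expect_equal(cnv_score(st[, perm]), cnv_score(st))
  st2 <- st; st2["a", 2] <- 6L
  expect_true(all(cnv_score(st2) >= cnv_score(st)))
})

test_that("bridging groups split planted CNV patterns perfectly", {
  set.seed(44)
  ## two CNV patterns over 100 genes
  pat1 <- c(rep(0.8, 40), rep(0, 60))
  pat2 <- c(rep(0, 60), rep(-0.8, 40))
  x <- rbind(matrix(rep(pat1, each = 15), 15) + rnorm(1500, sd = 0.05),
             matrix(rep(pat2, each = 15), 15) + rnorm(1500, sd = 0.05))
  rownames(x) <- sprintf("cell%02d", 1:30)
  colnames(x) <- sprintf("g%03d", 1:100)
  cnv <- structure(list(matrix = x, genes = NULL, window = 1),
                   class = "CNVMatrix")
  grp <- bridging_groups(cnv, n_groups = 2)
  expect_equal(ari(grp, rep(1:2, each = 15)), 1.0)
  ## duplicate cells land together
  x2 <- x; x2[2, ] <- x2[1, ]
  cnv2 <- structure(list(matrix = x2), class = "CNVMatrix")
  grp2 <- bridging_groups(cnv2, n_groups = 5)
  expect_equal(unname(grp2[1]), unname(grp2[2]))
  expect_error(bridging_groups(cnv, n_groups = 31), "exceeds")
})

test_that("malignant_score is the exact three-factor product", {
  pred <- data.frame(
    cell = c("c1", "c2", "c3"),
    predicted_label = c("Fibroblast", "Malignant cell 1",
                        "Malignant cell 2"),
    prediction_score_max = c(0.99, 1.0, 0.8),
    stringsAsFactors = FALSE
  )
  class(pred) <- c("PredictionTable", "data.frame")
  scores <- c(c1 = 50, c2 = 0, c3 = 10)
  ms <- malignant_score(pred, scores)
  ## non-malignant label: 0 regardless of aneuploidy
  expect_equal(ms$malignant_score[ms$cell == "c1"], 0)
  expect_equal(ms$is_malignant[ms$cell == "c1"], 0L)
  ## malignant with neutral genome: 0
  expect_equal(ms$malignant_score[ms$cell == "c2"], 0)
  ## indicator x confidence x cnv score
  expect_equal(ms$malignant_score[ms$cell == "c3"], 0.8 * 10)
  ## missing cnv score is an error naming the cell
  expect_error(malignant_score(pred, scores[1:2]), "c3")
})
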