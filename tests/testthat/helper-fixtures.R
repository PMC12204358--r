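## Shared fixtures, built in code at test time.

## Wrap a dense genes x cells matrix as an ExpressionMatrix without going
## through counts (for tests that plant expression values directly).
as_expression <- function(x, meta = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("G%04d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%04d", seq_len(ncol(x)))
  if (is.null(meta)) {
    meta <- data.frame(cell = colnames(x), stringsAsFactors = FALSE)
  }
  structure(list(data = Matrix::Matrix(x, sparse = TRUE), scale = 10000,
                 meta = meta),
            class = "ExpressionMatrix")
}

subset_expression <- function(expr, cells) {
  structure(list(data = expr$data[, cells, drop = FALSE],
                 scale = expr$scale,
                 meta = expr$meta[match(
                   colnames(expr$data[, cells, drop = FALSE]),
                   expr$meta$cell), , drop = FALSE]),
            class = "ExpressionMatrix")
}

## A small atlas with well-separated clusters and planted CNV segments,
## cached per session because several files reuse it.
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- atlas_sim_config(
        n_genes = 900,
        n_cells_per_pathology = c(PN = 250, AN = 250, MPNST = 300),
        n_clusters = 6,
        cluster_means_dispersion = 0.6,
        cnv_segments = data.frame(
          chrom = c("chr1", "chr2"),
          start_gene = c(20, 20), end_gene = c(130, 130),
          fold = c(1.5, 0.5), stringsAsFactors = FALSE),
        lowq_cell_fraction = 0.02,
        n_chromosomes = 4,
        seed = 42
      )
      sim <- simulate_cell_atlas(cfg)
      filtered <- qc_filter(sim$cells)
      expr <- normalize_log(filtered)
      truth <- sim$truth$cells[match(colnames(expr$data),
                                     sim$truth$cells$cell), ]
      cache <<- list(config = cfg, sim = sim, expr = expr, truth = truth)
    }
    cache
  }
})

## Adjusted Rand index (independent oracle from mclust where available).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## Hand-enumerated 12-cell QC fixture. Gene space: 8000 genes, the first
## 100 mitochondrial. Each cell is built to sit on a specific side of each
## threshold; the survivor list is derived by hand in the comments.
make_qc_fixture <- function() {
  n_genes <- 8000
  genes <- c(paste0("MT-", 1:100), sprintf("G%04d", 1:7900))
  cols <- list()
  put <- function(idx, val) {
    v <- numeric(n_genes)
    v[idx] <- val
    v
  }
  ## cell 1: nFeature 500, nCount 5000, mito 500/5000 = 0.1        -> keep
  cols$c01 <- put(101:600, 10); cols$c01[1:50] <- 10
  ## recompute: 550 genes, 5500 counts, mito 500/5500 ~ 0.09       -> keep
  ## cell 2: nFeature 200 (< 300)                                  -> drop
  cols$c02 <- put(101:300, 25)                 # nCount 5000 ok, mito 0
  ## cell 3: nFeature 300 exactly (boundary kept)                  -> keep
  cols$c03 <- put(101:400, 10)                 # nCount 3000
  ## cell 4: nFeature 7600 (> 7500)                                -> drop
  cols$c04 <- put(101:7700, 1)                 # nCount 7600 ok
  ## cell 5: nFeature 7500 exactly                                 -> keep
  cols$c05 <- put(201:7700, 1)                 # nCount 7500
  ## cell 6: nCount 499 (< 500)                                    -> drop
  cols$c06 <- put(101:599, 1)                  # nFeature 499 ok
  ## cell 7: nCount 500 exactly                                    -> keep
  cols$c07 <- put(101:600, 1)
  ## cell 8: nCount 50001 (> 50000)                                -> drop
  cols$c08 <- put(101:600, 100); cols$c08[101] <- 100 + 1  # 50001
  ## cell 9: nCount 50000 exactly                                  -> keep
  cols$c09 <- put(101:600, 100)
  ## cell 10: 100 mito genes x 30 = 3000; 300 genes x 3 = 900; one gene
  ## at 100 => nCount 4000, mito 3000/4000 = 0.75 (> 0.70)         -> drop
  cols$c10 <- put(1:100, 30); cols$c10[101:400] <- 3; cols$c10[401] <- 100
  ## cell 11: 100 mito x 7 = 700 plus 300 genes x 1 => nCount 1000,
  ## nFeature 400, mito exactly 0.70 (boundary kept)               -> keep
  cols$c11 <- put(1:100, 7); cols$c11[101:400] <- 1
  ## cell 12: nFeature 100 and mito 0.9 (multiple violations)      -> drop
  cols$c12 <- put(1:90, 10); cols$c12[101:110] <- 10  # 100 genes, mito .9
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  cell_matrix(Matrix::Matrix(m, sparse = TRUE))
}
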