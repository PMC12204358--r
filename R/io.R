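## Readers and writers for the pipeline's plain-text formats (Matrix Market
## counts + TSV features/barcodes, BED-like gene positions, CSV NPX
## tables), the JSON pipeline configuration, and the end-to-end driver.

#' Write a CellMatrix to a directory
#'
#' Writes `matrix.mtx` (Matrix Market), `features.tsv`, `barcodes.tsv` and
#' `metadata.tsv`. Round-trips bit-exactly through [read_cell_matrix()].
#'
#' @param cells a `CellMatrix`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cell_matrix <- function(cells, dir) {
  stopifnot(inherits(cells, "CellMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  write.table(cells$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CellMatrix from a directory
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` and optionally
#' `metadata.tsv`. QC metrics (nFeature, nCount, mito_fraction) are
#' recomputed on load. Errors on a dimension mismatch between the Matrix
#' Market header and the TSVs, and on duplicate gene names.
#'
#' @param dir directory written by [write_cell_matrix()].
#' @return a `CellMatrix`.
#' @export
read_cell_matrix <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) stopf("no matrix.mtx in %s", dir)
  counts <- tryCatch(Matrix::readMM(mtx_path),
                     error = function(e) stopf(
                       "malformed Matrix Market file %s: %s",
                       mtx_path, conditionMessage(e)))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    stopf("MTX header says %d x %d but features/barcodes give %d x %d",
          nrow(counts), ncol(counts), length(genes), length(cells))
  }
  if (anyDuplicated(genes)) {
    stopf("duplicate gene names in features.tsv: %s",
          paste(head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  }
  dimnames(counts) <- list(genes, cells)
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  cell_matrix(counts, meta)
}

#' Write/read gene positions (BED-like TSV)
#'
#' Columns: chrom, start, end, gene; 0-based half-open coordinates.
#'
#' @param positions a `GenePositions` data.frame.
#' @param path TSV path.
#' @return `write_gene_positions` the path, invisibly;
#'   `read_gene_positions` a `GenePositions`.
#' @export
write_gene_positions <- function(positions, path) {
  write.table(positions[, c("chrom", "start", "end", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_positions
#' @export
read_gene_positions <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(out)))
  chroms <- unique(out$chrom)
  num <- suppressWarnings(as.integer(sub("^chr", "", chroms)))
  lv <- if (!anyNA(num)) chroms[order(num)] else sort(chroms)
  out$chrom <- factor(out$chrom, levels = lv)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GenePositions", "data.frame")
  out
}

#' Write/read an NPX cohort as CSV
#'
#' `npx.csv` holds samples x proteins values (first column `sample`),
#' `lod.csv` the per-protein limits of detection, `labels.csv` the
#' per-sample diagnosis.
#'
#' @param npx an `NPXMatrix`.
#' @param dir directory.
#' @return `write_npx` the directory invisibly; `read_npx` an `NPXMatrix`.
#' @export
write_npx <- function(npx, dir) {
  stopifnot(inherits(npx, "NPXMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(sample = rownames(npx$npx), npx$npx,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, file.path(dir, "npx.csv"), row.names = FALSE)
  write.csv(data.frame(protein = names(npx$lod), lod = npx$lod,
                       stringsAsFactors = FALSE),
            file.path(dir, "lod.csv"), row.names = FALSE)
  write.csv(data.frame(sample = rownames(npx$npx),
                       diagnosis = as.character(npx$diagnosis),
                       stringsAsFactors = FALSE),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_npx
#' @export
read_npx <- function(dir) {
  vals <- read.csv(file.path(dir, "npx.csv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  lod <- read.csv(file.path(dir, "lod.csv"), stringsAsFactors = FALSE)
  labels <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample
  diagnosis <- labels$diagnosis[match(vals$sample, labels$sample)]
  npx_matrix(m, lod = setNames(lod$lod, lod$protein), diagnosis = diagnosis)
}

.default_config <- function() {
  list(
    seed = 1,
    outdir = "pipeline_out",
    stages = list(sc = TRUE, cnv = TRUE, panel = TRUE),
    atlas = list(n_genes = 1200, n_cells_per_pathology = c(PN = 300,
                                                           AN = 300,
                                                           MPNST = 300),
                 n_clusters = 6, holdout_fraction = 0.2,
                 cnv_segments = data.frame(
                   chrom = c("chr1", "chr2"),
                   start_gene = c(30, 30), end_gene = c(170, 170),
                   fold = c(1.5, 0.5), stringsAsFactors = FALSE)),
    qc = list(min_genes = 300, max_genes = 7500, min_counts = 500,
              max_counts = 50000, max_mito = 0.70),
    normalize = list(scale = 10000),
    variable_genes = list(n = 800),
    markers = list(min_pct = 0.25, top_n = 50),
    transfer = list(n_components = 30, k = 30),
    cnv = list(cutoff = 0.1, window = 101, cap = 3, denoise_sd = 1.5,
               state_thresholds = c(0.15, 0.4, 0.7)),
    panel = list(n_proteins = 400, n_signal = 40, effect_size = 1.5,
                 lod_quantile = 0.05, min_enrichment = 25, alpha = 0.05,
                 kernel = "radial", cost = 1, n_repeats = 10, n_folds = 5,
                 select_kernel = FALSE)
  )
}

#' Load a pipeline configuration
#'
#' Reads a JSON configuration, fills in defaults, and rejects unknown keys
#' (at the top level and within each section).
#'
#' @param path JSON file; NULL gives the bundled defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]]))) {
        bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(bad)) {
          stopf("unknown config key(s) under '%s': %s", k,
                paste(bad, collapse = ", "))
        }
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

.write_manifest <- function(outdir, config, seed, files) {
  files <- files[file.exists(file.path(outdir, files))]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("mpnstdetect")),
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(outdir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in order — simulate -> QC -> normalize ->
#' variable genes -> clustering -> markers/enrichment/module scores ->
#' reference fit + label transfer on a held-out query -> CNV inference,
#' state calling and malignant scores -> plasma simulation, preprocessing,
#' differential abundance, panel selection, MPNST probability score and
#' evaluation — writing TSV artifacts plus a JSON manifest (seed, config,
#' file checksums) under `config$outdir`. Identical config and seed
#' reproduce every artifact byte for byte.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list of written artifact paths and key results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }
  files <- character(0)

  ## --- simulate + single-cell stages -------------------------------------
  acfg <- atlas_sim_config(
    n_genes = config$atlas$n_genes,
    n_cells_per_pathology = unlist(config$atlas$n_cells_per_pathology),
    n_clusters = config$atlas$n_clusters,
    cnv_segments = config$atlas$cnv_segments,
    seed = derive_seed(seed, "atlas")
  )
  sim <- simulate_cell_atlas(acfg)
  message(sprintf("[simulate] %d genes x %d cells", nrow(sim$cells$counts),
                  ncol(sim$cells$counts)))
  if (isTRUE(config$stages$sc)) {
    thr <- do.call(qc_thresholds, config$qc)
    filtered <- qc_filter(sim$cells, thr)
    message(sprintf("[qc] retained %d / %d cells",
                    ncol(filtered$counts), ncol(sim$cells$counts)))
    files <- c(files, tsv(as.data.frame(t(attr(filtered, "qc_log"))),
                          "qc_log.tsv"))
    expr <- normalize_log(filtered, scale = config$normalize$scale)
    hv <- select_variable_genes(expr, n = config$variable_genes$n)
    truth <- sim$truth$cells[match(colnames(expr$data),
                                   sim$truth$cells$cell), ]
    labels <- truth$cluster
    freq <- cluster_frequencies(labels, truth$pathology)
    enr <- enrichment_score(freq)
    markers <- find_markers(expr, labels,
                            min_pct = config$markers$min_pct,
                            top_n = config$markers$top_n)
    files <- c(files, tsv(freq, "cluster_frequencies.tsv"),
               tsv(enr, "enrichment.tsv"), tsv(markers, "markers.tsv"))
    results$enrichment <- enr
    results$markers <- markers

    ## split reference/query, transfer labels
    set.seed(derive_seed(seed, "holdout"))
    n <- ncol(expr$data)
    q_idx <- sort(sample.int(n, round(config$atlas$holdout_fraction * n)))
    ref_cells <- colnames(expr$data)[-q_idx]
    qry_cells <- colnames(expr$data)[q_idx]
    subset_expr <- function(e, cells) {
      structure(list(data = e$data[, cells, drop = FALSE], scale = e$scale,
                     meta = e$meta[match(cells, e$meta$cell), ]),
                class = "ExpressionMatrix")
    }
    model <- fit_reference(subset_expr(expr, ref_cells),
                           labels[match(ref_cells, colnames(expr$data))],
                           genes = hv,
                           n_components = config$transfer$n_components)
    pred <- transfer_labels(model, subset_expr(expr, qry_cells),
                            k = config$transfer$k)
    acc <- mean(pred$predicted_label ==
                  labels[match(qry_cells, colnames(expr$data))])
    message(sprintf("[transfer] query accuracy %.3f", acc))
    files <- c(files,
               tsv(pred[, c("cell", "predicted_label",
                            "prediction_score_max")], "predictions.tsv"))
    results$transfer_accuracy <- acc

    if (isTRUE(config$stages$cnv)) {
      ref_types <- c("Pericyte", "Endothelial cell", "Myeloid immune cell",
                     "Lymphoid immune cell")
      cnv_ref <- pred$cell[pred$predicted_label %in% ref_types]
      if (length(cnv_ref) < 10) {
        cnv_ref <- colnames(expr$data)[labels %in% ref_types]
      }
      cnv_query <- setdiff(qry_cells, cnv_ref)
      cnv <- infer_cnv_profile(expr, sim$positions, cnv_ref,
                               query_cells = cnv_query,
                               cutoff = config$cnv$cutoff,
                               window = config$cnv$window,
                               cap = config$cnv$cap,
                               denoise_sd = config$cnv$denoise_sd)
      states <- call_cnv_states(cnv, unlist(config$cnv$state_thresholds))
      cscore <- cnv_score(states)
      pred_q <- pred[pred$cell %in% cnv_query, , drop = FALSE]
      class(pred_q) <- class(pred)
      mal <- malignant_score(pred_q, cscore)
      files <- c(files, tsv(mal, "malignant_scores.tsv"))
      counts_mal <- count_malignant(
        pred_q, truth$sample[match(pred_q$cell, truth$cell)])
      files <- c(files, tsv(counts_mal, "malignant_counts.tsv"))
      message(sprintf("[cnv] %d query cells scored", nrow(mal)))
      results$malignant_scores <- mal
    }
  }

  ## --- proteomics stage ---------------------------------------------------
  if (isTRUE(config$stages$panel)) {
    pc <- config$panel
    ## link signal proteins to marker genes of clusters enriched in MPNST
    gene_map <- NULL
    if (!is.null(results$markers)) {
      enr_cl <- results$enrichment
      top_cl <- enr_cl$cluster[enr_cl$pathology == "MPNST" &
                                 enr_cl$score_pct > pc$min_enrichment]
      mk <- results$markers[results$markers$cluster %in% top_cl, ]
      n_sig <- min(pc$n_signal, nrow(mk))
      proteins <- sprintf("PROT%04d", seq_len(pc$n_proteins))
      gene_map <- data.frame(
        protein = proteins,
        gene = c(mk$gene[seq_len(n_sig)],
                 sprintf("NONMARKER%04d",
                         seq_len(pc$n_proteins - n_sig))),
        stringsAsFactors = FALSE
      )
    }
    pcfg <- plasma_sim_config(n_proteins = pc$n_proteins,
                              signal_proteins = pc$n_signal,
                              effect_size = pc$effect_size,
                              lod_quantile = pc$lod_quantile,
                              seed = derive_seed(seed, "plasma"))
    cohort <- simulate_plasma_cohort(pcfg)
    npx <- preprocess_npx(cohort$npx)
    diff <- differential_abundance(npx)
    files <- c(files, tsv(diff[, c("protein", "anova_p", "delta_npx",
                                   "tukey_p_mpnst_pn", "p_adj")],
                          "differential_abundance.tsv"))
    panel_proteins <- cohort$truth
    if (!is.null(gene_map)) {
      spec <- select_panel(diff, results$markers, results$enrichment,
                           gene_map, min_enrichment = pc$min_enrichment,
                           alpha = pc$alpha)
      panel_proteins <- spec$protein
      jsonlite::write_json(as.list(spec), file.path(outdir,
                                                    "panel_spec.json"),
                           auto_unbox = FALSE, digits = NA)
      files <- c(files, "panel_spec.json")
      results$panel <- spec
    }
    if (isTRUE(pc$select_kernel)) {
      ks <- select_kernel(npx, panel_proteins, cost = pc$cost,
                          seed = derive_seed(seed, "kernel"))
      kernel <- ks$kernel
      files <- c(files, tsv(ks$table, "kernel_selection.tsv"))
    } else {
      kernel <- pc$kernel
    }
    scores <- mpnst_probability(
      npx, panel_proteins,
      svm_config(kernel = kernel, cost = pc$cost, n_repeats = pc$n_repeats,
                 n_folds = pc$n_folds, seed = derive_seed(seed, "svm"))
    )
    files <- c(files, tsv(scores, "mpnst_probability.tsv"))
    ev <- evaluate_model(scores$mpnst_probability,
                         scores$diagnosis == "MPNST")
    files <- c(files, tsv(data.frame(
      auc = ev$auc,
      sens_at_0.5 = ev$at_threshold$sensitivity,
      spec_at_0.5 = ev$at_threshold$specificity,
      youden_threshold = ev$at_youden$threshold,
      sens_at_youden = ev$at_youden$sensitivity,
      spec_at_youden = ev$at_youden$specificity
    ), "model_evaluation.tsv"))
    message(sprintf("[panel] AUC %.3f (sens %.2f / spec %.2f at 0.5)",
                    ev$auc, ev$at_threshold$sensitivity,
                    ev$at_threshold$specificity))
    results$evaluation <- ev
  }

  .write_manifest(outdir, config, seed, files)
  results$files <- file.path(outdir, files)
  invisible(results)
}
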