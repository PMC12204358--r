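## Synthetic data with planted ground truth: cell atlases spanning the
## PN -> AN -> MPNST pathology spectrum, gene genomic positions, and plasma
## NPX cohorts. Every generator is fully seeded and deterministic.

.pathologies <- c("PN", "AN", "MPNST")

.tme_cluster_pool <- c(
  "Fibroblast", "Schwann cell", "Myeloid immune cell", "Lymphoid immune cell",
  "Endothelial cell", "Pericyte", "Macrophage", "Monocyte", "T cell",
  "B cell", "NK cell", "Dendritic cell", "Mast cell", "Plasma cell",
  "Treg", "Smooth muscle cell"
)

.malignant_name_pool <- c(
  "Malignant cell 1", "Malignant cell 2", "Bridging malignant cell"
)

#' Default malignant cell-type labels
#'
#' The three transcriptional clusters treated as malignant when counting
#' malignant cells and computing malignant scores.
#' @export
malignant_cell_types <- function() .malignant_name_pool

#' Configuration for the synthetic cell atlas generator
#'
#' Describes a cluster-structured gamma-Poisson (negative binomial) count
#' atlas across the three pathologies (PN, AN, MPNST), with malignant
#' clusters carrying multiplicative chromosome-segment expression changes,
#' planted cluster marker genes, mitochondrial/ribosomal gene name blocks,
#' and a fraction of low-quality cells that deterministically violate QC.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_pathology named integer vector over PN/AN/MPNST.
#' @param n_clusters number of cell clusters.
#' @param cluster_means_dispersion SD of the per-gene log cluster effect;
#'   larger values separate clusters more.
#' @param pathology_composition optional list mapping pathology to a
#'   probability vector over clusters (each summing to 1). By default
#'   malignant clusters appear only in MPNST (30% of MPNST cells in total).
#' @param malignant_clusters integer indices of malignant clusters
#'   (default: the last cluster).
#' @param cnv_segments data.frame with columns `chrom`, `start_gene`,
#'   `end_gene`, `fold`: within-chromosome gene-index ranges whose expected
#'   expression is multiplied by `fold` (> 0) in malignant-cluster cells.
#' @param mito_gene_fraction fraction of genes named as mitochondrial
#'   ("MT-...").
#' @param ribo_gene_fraction fraction of genes named as ribosomal
#'   ("RPS...", "RPL...").
#' @param lowq_cell_fraction fraction of cells per pathology rendered
#'   low-quality (250 total counts, ~80% mitochondrial).
#' @param marker_genes_per_cluster planted cluster-specific marker genes.
#' @param marker_fold fold-change of planted markers in their cluster.
#' @param nb_size negative binomial size (inverse overdispersion).
#' @param n_samples_per_pathology tumors per pathology; cells are assigned
#'   to samples at random.
#' @param n_chromosomes chromosomes used for the gene position table.
#' @param cluster_names optional cluster names; defaults draw non-malignant
#'   names from a tumor-microenvironment pool and malignant names from
#'   [malignant_cell_types()].
#' @param seed integer seed.
#' @return an `atlas_sim_config` list, validated.
#' @export
atlas_sim_config <- function(n_genes = 2000,
                             n_cells_per_pathology = c(PN = 500, AN = 500,
                                                       MPNST = 500),
                             n_clusters = 8,
                             cluster_means_dispersion = 1,
                             pathology_composition = NULL,
                             malignant_clusters = NULL,
                             cnv_segments = NULL,
                             mito_gene_fraction = 0.02,
                             ribo_gene_fraction = 0.05,
                             lowq_cell_fraction = 0.02,
                             marker_genes_per_cluster = 25,
                             marker_fold = 4,
                             nb_size = 10,
                             n_samples_per_pathology = 3,
                             n_chromosomes = 6,
                             cluster_names = NULL,
                             seed = 1) {
  if (is.null(names(n_cells_per_pathology)) ||
      !setequal(names(n_cells_per_pathology), .pathologies)) {
    stopf("n_cells_per_pathology must be named with %s",
          paste(.pathologies, collapse = ", "))
  }
  n_cells_per_pathology <- n_cells_per_pathology[.pathologies]
  if (is.null(malignant_clusters)) malignant_clusters <- n_clusters
  malignant_clusters <- sort(unique(as.integer(malignant_clusters)))
  if (any(malignant_clusters < 1L) || any(malignant_clusters > n_clusters)) {
    stopf("malignant_clusters must be cluster indices in 1..%d", n_clusters)
  }
  if (is.null(cluster_names)) {
    n_mal <- length(malignant_clusters)
    if (n_mal > length(.malignant_name_pool) ||
        n_clusters - n_mal > length(.tme_cluster_pool)) {
      cluster_names <- paste0("Cluster ", seq_len(n_clusters))
    } else {
      cluster_names <- character(n_clusters)
      cluster_names[malignant_clusters] <- .malignant_name_pool[seq_len(n_mal)]
      cluster_names[-malignant_clusters] <-
        .tme_cluster_pool[seq_len(n_clusters - n_mal)]
    }
  }
  stopifnot(length(cluster_names) == n_clusters,
            !anyDuplicated(cluster_names))

  if (is.null(pathology_composition)) {
    nonmal <- setdiff(seq_len(n_clusters), malignant_clusters)
    base <- rep(0, n_clusters)
    base[nonmal] <- 1 / length(nonmal)
    mpnst <- rep(0, n_clusters)
    mpnst[malignant_clusters] <- 0.3 / length(malignant_clusters)
    mpnst[nonmal] <- 0.7 / length(nonmal)
    pathology_composition <- list(PN = base, AN = base, MPNST = mpnst)
  }
  for (p in .pathologies) {
    v <- pathology_composition[[p]]
    if (is.null(v) || length(v) != n_clusters) {
      stopf("pathology_composition[['%s']] must have %d entries",
            p, n_clusters)
    }
    if (abs(sum(v) - 1) > 1e-12 || any(v < 0)) {
      stopf("composition vector for %s must be non-negative and sum to 1", p)
    }
  }
  if (!is.null(cnv_segments)) {
    req <- c("chrom", "start_gene", "end_gene", "fold")
    if (!all(req %in% names(cnv_segments))) {
      stopf("cnv_segments needs columns %s", paste(req, collapse = ", "))
    }
    if (any(cnv_segments$fold <= 0)) stopf("cnv segment fold-change must be > 0")
    if (any(cnv_segments$start_gene < 1) ||
        any(cnv_segments$end_gene < cnv_segments$start_gene)) {
      stopf("cnv segment gene indices invalid")
    }
  }
  stopifnot(mito_gene_fraction >= 0, mito_gene_fraction < 1,
            ribo_gene_fraction >= 0, ribo_gene_fraction < 1,
            lowq_cell_fraction >= 0, lowq_cell_fraction < 1,
            cluster_means_dispersion >= 0, nb_size > 0,
            n_genes >= n_chromosomes, n_chromosomes >= 1)
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_pathology = n_cells_per_pathology,
    n_clusters = as.integer(n_clusters),
    cluster_means_dispersion = cluster_means_dispersion,
    pathology_composition = pathology_composition,
    malignant_clusters = malignant_clusters,
    cnv_segments = cnv_segments,
    mito_gene_fraction = mito_gene_fraction,
    ribo_gene_fraction = ribo_gene_fraction,
    lowq_cell_fraction = lowq_cell_fraction,
    marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
    marker_fold = marker_fold,
    nb_size = nb_size,
    n_samples_per_pathology = as.integer(n_samples_per_pathology),
    n_chromosomes = as.integer(n_chromosomes),
    cluster_names = cluster_names,
    seed = as.integer(seed)
  ), class = "atlas_sim_config")
}

.make_gene_names <- function(n_genes, mito_fraction, ribo_fraction) {
  n_mito <- round(n_genes * mito_fraction)
  n_ribo <- round(n_genes * ribo_fraction)
  nm <- sprintf("GENE%05d", seq_len(n_genes))
  if (n_mito > 0) nm[seq_len(n_mito)] <- paste0("MT-", seq_len(n_mito))
  if (n_ribo > 0) {
    idx <- n_mito + seq_len(n_ribo)
    half <- ceiling(n_ribo / 2)
    nm[idx[seq_len(half)]] <- paste0("RPS", seq_len(half))
    if (n_ribo > half) {
      nm[idx[(half + 1):n_ribo]] <- paste0("RPL", seq_len(n_ribo - half))
    }
  }
  nm
}

#' Simulate gene genomic positions
#'
#' Assigns genes to chromosomes in contiguous, nearly equal blocks and gives
#' each gene a non-overlapping 0-based half-open interval. Output is sorted
#' by (chromosome, start) and the sort is stable/idempotent.
#'
#' @param n_genes number of genes (>= n_chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param seed integer seed for interval lengths and gaps.
#' @param gene_names optional gene names (length n_genes).
#' @return a `GenePositions` data.frame with columns chrom (factor with
#'   levels in genomic order), start, end, gene.
#' @export
simulate_gene_positions <- function(n_genes, n_chromosomes, seed = 1,
                                    gene_names = NULL) {
  stopifnot(n_genes >= n_chromosomes, n_chromosomes >= 1)
  if (is.null(gene_names)) gene_names <- sprintf("GENE%05d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  set.seed(seed)
  base <- n_genes %/% n_chromosomes
  sizes <- rep(base, n_chromosomes)
  extra <- n_genes - base * n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- factor(rep(paste0("chr", seq_len(n_chromosomes)), times = sizes),
                  levels = paste0("chr", seq_len(n_chromosomes)))
  lens <- sample(200:2000, n_genes, replace = TRUE)
  gaps <- sample(100:1000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  end <- integer(n_genes)
  offset <- 0L
  pos <- 0L
  for (i in seq_len(n_genes)) {
    if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 0L
    start[i] <- pos
    end[i] <- pos + lens[i]
    pos <- end[i] + gaps[i]
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    gene = gene_names, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GenePositions", "data.frame")
  out
}

## Per-gene CNV multiplier implied by the planted segments, given positions.
.segment_multiplier <- function(positions, cnv_segments) {
  mult <- setNames(rep(1, nrow(positions)), positions$gene)
  if (is.null(cnv_segments)) return(mult)
  for (i in seq_len(nrow(cnv_segments))) {
    seg <- cnv_segments[i, ]
    genes_on <- positions$gene[positions$chrom == seg$chrom]
    if (seg$end_gene > length(genes_on)) {
      stopf("cnv segment on %s exceeds chromosome bounds (%d genes)",
            seg$chrom, length(genes_on))
    }
    idx <- genes_on[seg$start_gene:seg$end_gene]
    mult[idx] <- mult[idx] * seg$fold
  }
  mult
}

#' Simulate a seeded cell atlas with planted truth
#'
#' Draws a genes x cells negative binomial count matrix with
#' cluster-specific expected means (log-normal cluster effects plus planted
#' marker-gene blocks), multiplies malignant-cluster cell means by the
#' configured CNV segment fold-changes, and replaces a fraction of cells
#' with low-quality cells (250 total counts, ~80% mitochondrial) that
#' violate the default QC thresholds deterministically.
#'
#' @param config an [atlas_sim_config()].
#' @param positions optional `GenePositions` for the config's genes;
#'   generated with [simulate_gene_positions()] when missing.
#' @return list with elements `cells` (a `CellMatrix`), `truth` (per-cell
#'   data.frame plus per-gene `cnv_multiplier` and planted `marker_genes`),
#'   and `positions`.
#' @export
simulate_cell_atlas <- function(config, positions = NULL) {
  stopifnot(inherits(config, "atlas_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  K <- config$n_clusters
  gene_names <- .make_gene_names(G, config$mito_gene_fraction,
                                 config$ribo_gene_fraction)
  if (is.null(positions)) {
    positions <- simulate_gene_positions(G, config$n_chromosomes,
                                         seed = config$seed,
                                         gene_names = gene_names)
  }
  mito <- grepl("^MT-", gene_names)

  ## Base gene means; mitochondrial genes boosted so normal cells sit near a
  ## ~10% mitochondrial fraction.
  mu <- rlnorm(G, meanlog = 0, sdlog = 1)
  mu[mito] <- mu[mito] * 8

  ## Cluster effects: log-normal per gene x cluster, plus planted markers.
  fac <- matrix(exp(rnorm(G * K, 0, config$cluster_means_dispersion)),
                nrow = G, ncol = K)
  eligible <- which(!mito & !grepl("^RP[SL]", gene_names))
  marker_genes <- vector("list", K)
  npl <- config$marker_genes_per_cluster
  if (npl > 0 && length(eligible) >= npl * K) {
    for (k in seq_len(K)) {
      idx <- eligible[((k - 1) * npl + 1):(k * npl)]
      fac[idx, k] <- fac[idx, k] * config$marker_fold
      marker_genes[[k]] <- gene_names[idx]
    }
  }
  names(marker_genes) <- config$cluster_names

  cnv_mult <- .segment_multiplier(positions, config$cnv_segments)
  cnv_mult <- cnv_mult[gene_names]

  ## Cell assignments in fixed pathology order.
  n_cells <- sum(config$n_cells_per_pathology)
  pathology <- rep(.pathologies, times = config$n_cells_per_pathology)
  cluster_idx <- integer(n_cells)
  sample_id <- character(n_cells)
  is_lowq <- logical(n_cells)
  off <- 0L
  for (p in .pathologies) {
    n_p <- config$n_cells_per_pathology[[p]]
    if (n_p == 0L) next
    idx <- off + seq_len(n_p)
    cluster_idx[idx] <- sample.int(K, n_p, replace = TRUE,
                                   prob = config$pathology_composition[[p]])
    sample_id[idx] <- paste0(p, "_S",
                             sample.int(config$n_samples_per_pathology, n_p,
                                        replace = TRUE))
    n_lowq <- floor(config$lowq_cell_fraction * n_p)
    if (n_lowq > 0) is_lowq[idx[sample.int(n_p, n_lowq)]] <- TRUE
    off <- off + n_p
  }
  is_malignant <- cluster_idx %in% config$malignant_clusters

  ## Expected means per cell; CNV multiplies malignant-cluster cells.
  M <- mu * fac[, cluster_idx, drop = FALSE]
  if (any(is_malignant)) {
    M[, is_malignant] <- M[, is_malignant, drop = FALSE] * cnv_mult
  }
  counts <- matrix(rnbinom(G * n_cells, mu = as.vector(M),
                           size = config$nb_size),
                   nrow = G, ncol = n_cells)

  ## Low-quality cells: exactly 250 counts with ~80% mitochondrial mass.
  if (any(is_lowq)) {
    for (i in which(is_lowq)) {
      w <- M[, i]
      w <- w / sum(w)
      if (any(mito)) {
        w[mito] <- 0.8 * (M[mito, i] / sum(M[mito, i]))
        w[!mito] <- 0.2 * (M[!mito, i] / sum(M[!mito, i]))
      }
      counts[, i] <- rmultinom(1, 250, prob = w)
    }
  }

  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_names, cell_ids)
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  meta <- data.frame(
    cell = cell_ids,
    sample = sample_id,
    pathology = factor(pathology, levels = .pathologies),
    stringsAsFactors = FALSE
  )
  cells <- cell_matrix(counts, meta)

  truth <- list(
    cells = data.frame(
      cell = cell_ids,
      cluster = config$cluster_names[cluster_idx],
      pathology = factor(pathology, levels = .pathologies),
      sample = sample_id,
      is_malignant = is_malignant,
      is_lowq = is_lowq,
      stringsAsFactors = FALSE
    ),
    cnv_multiplier = cnv_mult,
    marker_genes = marker_genes,
    malignant_clusters = config$cluster_names[config$malignant_clusters]
  )
  class(truth) <- "TruthLabels"
  list(cells = cells, truth = truth, positions = positions)
}

#' Configuration for the synthetic plasma NPX cohort
#'
#' NPX values are simulated directly on the normalized (log2-like) scale:
#' per-protein baseline + a mean shift in MPNST samples for signal proteins
#' + Gaussian noise, with per-protein limit-of-detection censoring at a
#' configurable quantile.
#'
#' @param n_proteins number of assayed proteins.
#' @param group_sizes named integer vector over healthy/PN/AN/MPNST (>= 2
#'   each).
#' @param signal_proteins either a count (the first so many proteins) or a
#'   character vector of protein names carrying the MPNST shift.
#' @param effect_size mean NPX shift added to MPNST samples for signal
#'   proteins (>= 0; the panel's direction rule assumes elevation).
#' @param lod_quantile per-protein fraction of values censored below the
#'   limit of detection (0 disables censoring).
#' @param noise_sd per-value Gaussian noise SD (NPX units).
#' @param seed integer seed.
#' @export
plasma_sim_config <- function(n_proteins = 1436,
                              group_sizes = c(healthy = 10, PN = 29,
                                              AN = 25, MPNST = 54),
                              signal_proteins = 50,
                              effect_size = 1.5,
                              lod_quantile = 0.05,
                              noise_sd = 1,
                              seed = 1) {
  groups <- c("healthy", "PN", "AN", "MPNST")
  if (is.null(names(group_sizes)) || !setequal(names(group_sizes), groups)) {
    stopf("group_sizes must be named with %s", paste(groups, collapse = ", "))
  }
  group_sizes <- group_sizes[groups]
  if (any(group_sizes < 2)) stopf("every group needs >= 2 samples")
  if (effect_size < 0) {
    stopf("effect_size must be >= 0: signal proteins are elevated in MPNST")
  }
  proteins <- sprintf("PROT%04d", seq_len(n_proteins))
  if (is.numeric(signal_proteins) && length(signal_proteins) == 1L) {
    stopifnot(signal_proteins <= n_proteins)
    signal_proteins <- proteins[seq_len(signal_proteins)]
  }
  if (!all(signal_proteins %in% proteins)) {
    stopf("signal_proteins must be a subset of the assayed proteins")
  }
  stopifnot(lod_quantile >= 0, lod_quantile < 1, noise_sd > 0)
  structure(list(
    n_proteins = as.integer(n_proteins),
    proteins = proteins,
    group_sizes = group_sizes,
    signal_proteins = signal_proteins,
    effect_size = effect_size,
    lod_quantile = lod_quantile,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "plasma_sim_config")
}

#' Simulate a plasma NPX cohort with planted signal proteins
#'
#' @param config a [plasma_sim_config()].
#' @param marker_link optional data.frame (protein, gene, cluster) linking
#'   proteins to single-cell marker genes; attached to the result so panel
#'   selection can be exercised end to end.
#' @return list with `npx` (an `NPXMatrix`: samples x proteins values,
#'   per-protein LOD, below-LOD flags, per-sample diagnosis) and `truth`
#'   (the signal protein names).
#' @export
simulate_plasma_cohort <- function(config, marker_link = NULL) {
  stopifnot(inherits(config, "plasma_sim_config"))
  set.seed(config$seed)
  P <- config$n_proteins
  N <- sum(config$group_sizes)
  diagnosis <- factor(rep(names(config$group_sizes),
                          times = config$group_sizes),
                      levels = names(config$group_sizes))
  samples <- sprintf("S%03d", seq_len(N))
  baseline <- rnorm(P, mean = 5, sd = 1.5)
  npx <- matrix(rnorm(N * P, sd = config$noise_sd), nrow = N, ncol = P)
  npx <- sweep(npx, 2, baseline, "+")
  sig <- config$proteins %in% config$signal_proteins
  if (any(sig) && config$effect_size != 0) {
    npx[diagnosis == "MPNST", sig] <- npx[diagnosis == "MPNST", sig] +
      config$effect_size
  }
  dimnames(npx) <- list(samples, config$proteins)
  if (config$lod_quantile > 0) {
    lod <- apply(npx, 2, quantile, probs = config$lod_quantile, names = FALSE)
  } else {
    lod <- rep(-Inf, P)
  }
  names(lod) <- config$proteins
  below <- sweep(npx, 2, lod, "<")
  out <- npx_matrix(npx, lod = lod, diagnosis = diagnosis,
                    below_lod = below)
  if (!is.null(marker_link)) attr(out, "gene_map") <- marker_link
  list(npx = out, truth = config$signal_proteins)
}
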