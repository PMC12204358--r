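make_npx <- function(values, lod = NULL, diagnosis = NULL) {
  if (is.null(lod)) lod <- rep(-Inf, ncol(values))
  if (is.null(diagnosis)) {
    diagnosis <- rep(c("healthy", "PN", "AN", "MPNST"),
                     length.out = nrow(values))
  }
  npx_matrix(values, lod = setNames(lod, colnames(values)),
             diagnosis = diagnosis)
}

test_that("below-LOD values become LOD/sqrt(2) and scaling is exact", {
  set.seed(61)
  x <- matrix(rnorm(40 * 3, mean = 5), 40, 3,
              dimnames = list(sprintf("s%02d", 1:40), c("P1", "P2", "P3")))
  lod <- c(P1 = 2.0, P2 = -Inf, P3 = -Inf)
  x[1:4, "P1"] <- 1.5  # below LOD
  raw <- make_npx(x, lod = lod)
  imputed <- preprocess_npx(raw, standardize = FALSE)
  expect_equal(unname(imputed$npx[1:4, "P1"]), rep(2.0 / sqrt(2), 4))
  expect_equal(round(2.0 / sqrt(2), 5), 1.41421)
  ## values at or above LOD are untouched
  expect_identical(imputed$npx[-(1:4), ], x[-(1:4), ])
  ## standardization: population mean/SD exactly 0/1
  scaled <- preprocess_npx(raw)
  n <- nrow(scaled$npx)
  expect_lt(max(abs(colMeans(scaled$npx))), 1e-9)
  sd_pop <- sqrt(colMeans(scaled$npx^2) - colMeans(scaled$npx)^2)
  expect_lt(max(abs(sd_pop - 1)), 1e-9)
  ## censoring flags preserved
  expect_identical(scaled$below_lod, raw$below_lod)
})

test_that("scaling is idempotent and constant proteins are dropped", {
  set.seed(62)
  x <- matrix(rnorm(30 * 2), 30, 2,
              dimnames = list(sprintf("s%02d", 1:30), c("A", "B")))
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")   # already mean 0, pop SD 1
  raw <- make_npx(x)
  out <- preprocess_npx(raw)
  expect_lt(max(abs(out$npx - x)), 1e-12)
  xc <- cbind(x, CONST = rep(3, 30))
  expect_warning(out2 <- preprocess_npx(make_npx(xc)), "zero-variance")
  expect_identical(colnames(out2$npx), c("A", "B"))
})

test_that("vectorised ANOVA + Tukey agrees with aov/TukeyHSD", {
  set.seed(63)
  n <- c(healthy = 6, PN = 9, AN = 7, MPNST = 12)
  g <- factor(rep(names(n), n), levels = names(n))
  x <- matrix(rnorm(sum(n) * 5), sum(n), 5,
              dimnames = list(sprintf("s%02d", seq_len(sum(n))),
                              paste0("P", 1:5)))
  x[g == "MPNST", 1] <- x[g == "MPNST", 1] + 2
  d <- differential_abundance(make_npx(x, diagnosis = g))
  for (j in 1:5) {
    fit <- aov(x[, j] ~ g)
    ref_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    expect_equal(d$anova_p[j], ref_p, tolerance = 1e-8)
    tk <- TukeyHSD(fit)$g
    ref_pair <- tk["MPNST-PN", "p adj"]
    expect_equal(d$tukey_p_mpnst_pn[j], ref_pair, tolerance = 1e-6)
    ## another pair as well
    expect_equal(d$tukey_p_PN_vs_AN[j], tk["AN-PN", "p adj"],
                 tolerance = 1e-6)
  }
  ## delta NPX of two identical groups is 0
  x2 <- x; x2[g == "MPNST", ] <- x2[g == "PN", ][seq_len(sum(g == "MPNST")) %%
                                                   sum(g == "PN") + 1, ]
  x2[g == "MPNST", ] <- matrix(rep(colMeans(x2[g == "PN", ]),
                                   each = sum(g == "MPNST")),
                               sum(g == "MPNST"))
  x2[g == "PN", ] <- matrix(rep(colMeans(x2[g == "PN", ]),
                                each = sum(g == "PN")), sum(g == "PN"))
  d2 <- differential_abundance(make_npx(x2, diagnosis = g))
  expect_lt(max(abs(d2$delta_npx)), 1e-12)
})

test_that("a planted +2SD shift is detected with near-certain power", {
  ## analytic power for the raw pairwise comparison at n = 25 per group is
  ## > 0.99; check a batch of simulated proteins all reject
  set.seed(64)
  g <- factor(rep(c("PN", "MPNST"), each = 25), levels = c("PN", "MPNST"))
  x <- matrix(rnorm(50 * 40), 50, 40,
              dimnames = list(sprintf("s%02d", 1:50), paste0("P", 1:40)))
  x[g == "MPNST", ] <- x[g == "MPNST", ] + 2
  d <- suppressWarnings(differential_abundance(make_npx(x, diagnosis = g)))
  expect_true(all(d$tukey_p_mpnst_pn < 0.05))
  expect_true(all(d$delta_npx > 0))
})

test_that("select_panel applies the three filter rules", {
  diff <- data.frame(
    protein = c("P1", "P2", "P3", "P4", "P5"),
    delta_npx = c(1.2, 1.2, -0.5, 1.0, 1.0),
    p_adj = c(0.01, 0.01, 0.001, 0.01, 0.20),
    stringsAsFactors = FALSE
  )
  class(diff) <- c("DiffTable", "data.frame")
  markers <- data.frame(
    cluster = c("Malignant cell 1", "Treg", "Malignant cell 1",
                "Malignant cell 1", "Malignant cell 1"),
    gene = c("G1", "G2", "G3", "G4", "G5"),
    stringsAsFactors = FALSE
  )
  class(markers) <- c("ClusterProfile", "data.frame")
  enrich <- data.frame(
    cluster = c("Malignant cell 1", "Treg"),
    pathology = c("MPNST", "MPNST"),
    score_pct = c(30, 20),
    stringsAsFactors = FALSE
  )
  gene_map <- data.frame(protein = paste0("P", 1:5),
                         gene = paste0("G", 1:5), stringsAsFactors = FALSE)
  panel <- select_panel(diff, markers, enrich, gene_map)
  ## P1: p ok, delta > 0, cluster enrichment 30 > 25          -> in
  ## P2: cluster enrichment 20 < 25                           -> out
  ## P3: delta < 0                                            -> out
  ## P4: all three rules pass                                 -> in
  ## P5: p_adj 0.20                                           -> out
  expect_setequal(panel$protein, c("P1", "P4"))
  expect_true(all(panel$cluster == "Malignant cell 1"))
  expect_true(all(panel$enrichment_pct > 25))
  ## empty panel is an error suggesting relaxation
  expect_error(select_panel(diff, markers,
                            transform(enrich, score_pct = c(10, 10)),
                            gene_map),
               "relaxing")
})

test_that("per-protein OVA metrics behave like ROC analysis", {
  d <- factor(c(rep("PN", 6), rep("MPNST", 6)),
              levels = c("healthy", "PN", "AN", "MPNST"))
  perfect <- c(rep(0, 6), rep(1, 6))
  x <- cbind(SEP = perfect, NEG = -perfect)
  rownames(x) <- sprintf("s%02d", 1:12)
  npx <- npx_matrix(x, lod = c(SEP = -Inf, NEG = -Inf), diagnosis = d)
  ova <- per_protein_ova(npx)
  expect_equal(ova$auc[ova$protein == "SEP"], 1.0)
  expect_equal(ova$youden_j[ova$protein == "SEP"], 1.0)
  ## negation symmetry
  expect_equal(ova$auc[ova$protein == "NEG"],
               1 - ova$auc[ova$protein == "SEP"])
  ## label-independent protein sits near 0.5 at n = 118
  set.seed(66)
  cohort <- simulate_plasma_cohort(
    plasma_sim_config(n_proteins = 1, signal_proteins = 0, effect_size = 0,
                      lod_quantile = 0, seed = 66))
  ova2 <- per_protein_ova(cohort$npx)
  expect_gt(ova2$auc, 0.4 - 1e-12)
  expect_lt(ova2$auc, 0.6 + 1e-12)
})

test_that("pROC agrees with the internal ROC on a noisy protein", {
  skip_if_not_installed("pROC")
  set.seed(67)
  score <- rnorm(60)
  y <- rbinom(60, 1, plogis(score))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ev <- evaluate_model(plogis(score), y == 1)
  ref <- pROC::roc(y, plogis(score), quiet = TRUE)
  expect_equal(ev$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("evaluate_model matches a hand-enumerated confusion table", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  ev <- evaluate_model(scores, labels, threshold = 0.5)
  ## by hand: predictions at 0.5 -> {T,T,T,F,F,F};
  ## tp = 2 (0.9, 0.8), fp = 1 (0.6), fn = 1 (0.4), tn = 2 (0.3, 0.1)
  expect_equal(ev$at_threshold[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  expect_equal(ev$at_threshold$sensitivity, 2 / 3)
  expect_equal(ev$at_threshold$specificity, 2 / 3)
  ## by hand: positive scores {.9,.8,.4} vs negative {.6,.3,.1}:
  ## 8 of 9 pairs correctly ordered -> AUC = 8/9
  expect_equal(ev$auc, 8 / 9)
  ## scores identical to labels: perfect
  ev2 <- evaluate_model(as.numeric(labels), labels)
  expect_equal(ev2$auc, 1.0)
  expect_equal(ev2$at_threshold$sensitivity, 1.0)
  expect_equal(ev2$at_threshold$specificity, 1.0)
  ## constant scores: degenerate, AUC pinned at 0.5
  ev3 <- evaluate_model(rep(0.5, 6), labels)
  expect_true(ev3$degenerate)
  expect_equal(ev3$auc, 0.5)
  expect_error(evaluate_model(scores, rep(TRUE, 6)), "both classes")
})

test_that("kernel selection follows the accuracy-with-AUC-floor rule", {
  set.seed(68)
  cohort <- simulate_plasma_cohort(
    plasma_sim_config(n_proteins = 25,
                      group_sizes = c(healthy = 5, PN = 10, AN = 8,
                                      MPNST = 15),
                      signal_proteins = 20, effect_size = 3,
                      lod_quantile = 0, seed = 68))
  npx <- preprocess_npx(cohort$npx)
  sel <- select_kernel(npx, cohort$truth, seed = 1)
  ## the grid is exactly the four named kernels
  expect_identical(sel$table$kernel,
                   c("linear", "radial", "polynomial", "sigmoid"))
  ## strongly separable cohort: every kernel discriminates well
  expect_true(all(sel$table$auc > 0.9))
  ## the chosen kernel maximises accuracy among AUC > 0.8
  ok <- sel$table[sel$table$auc > 0.8, ]
  expect_equal(max(ok$accuracy),
               sel$table$accuracy[sel$table$kernel == sel$kernel])
})

test_that("mpnst_probability separates a strong cohort and ignores row order", {
  cohort <- simulate_plasma_cohort(
    plasma_sim_config(n_proteins = 40,
                      group_sizes = c(healthy = 6, PN = 12, AN = 10,
                                      MPNST = 20),
                      signal_proteins = 40, effect_size = 3,
                      lod_quantile = 0, seed = 69))
  npx <- preprocess_npx(cohort$npx)
  cfg <- svm_config(kernel = "radial", n_repeats = 5, n_folds = 5, seed = 2)
  sc <- mpnst_probability(npx, cohort$truth, cfg)
  expect_true(all(sc$mpnst_probability >= 0 & sc$mpnst_probability <= 1))
  expect_true(all(sc$mpnst_probability[sc$diagnosis == "MPNST"] >= 0.5))
  expect_true(all(sc$mpnst_probability[sc$diagnosis != "MPNST"] < 0.5))
  ## permuting the sample rows leaves per-sample scores unchanged
  set.seed(70)
  perm <- sample(nrow(npx$npx))
  npx_perm <- npx_matrix(npx$npx[perm, ], lod = npx$lod,
                         diagnosis = npx$diagnosis[perm],
                         below_lod = npx$below_lod[perm, ])
  sc_perm <- mpnst_probability(npx_perm, cohort$truth, cfg)
  expect_equal(sc_perm, sc)
})

test_that("integrating weak distributed effects beats the median protein", {
  ## 40 signal proteins at 0.8 SD each: the integrated model should do at
  ## least as well as the median individual protein
  cohort <- simulate_plasma_cohort(
    plasma_sim_config(n_proteins = 60, signal_proteins = 40,
                      effect_size = 0.8, lod_quantile = 0, seed = 71))
  npx <- preprocess_npx(cohort$npx)
  ova <- per_protein_ova(npx, proteins = cohort$truth)
  sc <- mpnst_probability(npx, cohort$truth,
                          svm_config(kernel = "radial", n_repeats = 5,
                                     seed = 72))
  ev <- evaluate_model(sc$mpnst_probability, sc$diagnosis == "MPNST")
  expect_gte(ev$auc, median(ova$auc))
})
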