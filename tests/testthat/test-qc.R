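test_that("hard filters apply strict thresholds and handle zero cells", {
  # 2000-gene matrix, custom thresholds so every boundary is constructible
  th <- qc_thresholds(min_umi = 500, min_genes = 300, max_umi = 10000,
                      max_genes = 1500, max_mito_fraction = 0.10)
  G <- 2000
  # gene rows 1..10 are MT- flagged; non-mito cells start at row 11
  build_cell <- function(umi, genes, from = 11) {
    stopifnot(genes <= G - from + 1, umi >= genes)
    x <- numeric(G)
    idx <- seq(from, from + genes - 1)
    x[idx] <- umi %/% genes
    extra <- umi %% genes
    if (extra) x[idx[seq_len(extra)]] <- x[idx[seq_len(extra)]] + 1
    x
  }
  mb <- numeric(G); mb[1] <- 100; mb[11:310] <- 3      # 1000 umi, mito 10.0%
  mbad <- numeric(G); mbad[1] <- 110; mbad[11:310] <- 3 # 1010 umi, mito 10.9%
  m <- cbind(
    pass_boundary = build_cell(500, 300),   # exactly at both lower limits
    low_umi = build_cell(400, 300),
    low_genes = build_cell(600, 299),
    high_umi = build_cell(10001, 1500),
    high_genes = build_cell(3005, 1501, from = 11),
    mito_boundary = mb,
    mito_bad = mbad)
  rownames(m) <- c(sprintf("MT-%02d", 1:10), sprintf("g%04d", 11:G))
  sce <- make_sce(m)
  hf <- hard_filters(sce, th)
  expect_false(any(unlist(hf["pass_boundary", c("depth_low", "depth_high", "mito")])))
  expect_true(hf["low_umi", "depth_low"])
  expect_true(hf["low_genes", "depth_low"])
  expect_true(hf["high_umi", "depth_high"])
  expect_true(hf["high_genes", "depth_high"])
  expect_false(hf["mito_boundary", "mito"])   # exactly 10% passes (strict)
  expect_true(hf["mito_bad", "mito"])

  # zero-count cell: depth_low, mito fraction defined as 0
  m0 <- cbind(m, empty = numeric(G))
  hf0 <- hard_filters(make_sce(m0), th)
  expect_true(hf0["empty", "depth_low"])
  expect_equal(hf0["empty", "mito_fraction"], 0)
})

test_that("gene~UMI polynomial flags constructed outliers only", {
  # cells exactly on genes = 2 * UMI^0.8 (a quadratic in log space fits
  # perfectly), one cell pushed far above the curve
  G <- 6000
  umis <- round(seq(2000, 9000, length.out = 30))
  genes <- round(2 * umis^0.8)
  m <- sapply(seq_along(umis), function(i) {
    x <- numeric(G)
    g <- genes[i]; u <- umis[i]
    base <- u %/% g; extra <- u %% g
    x[seq_len(g)] <- base
    if (extra) x[seq_len(extra)] <- x[seq_len(extra)] + 1
    x
  })
  colnames(m) <- sprintf("cell%02d", seq_along(umis))
  sce <- make_sce(m)
  pf <- fit_gene_umi_polynomial(sce, qc_thresholds())
  expect_false(any(pf$flag))

  # raise one cell's gene count by ~3000 above the curve at constant UMI
  mv <- m
  g_new <- genes[15] + 3000
  u15 <- umis[15] + 3000 - genes[15]  # keep umi >= genes
  x <- numeric(G)
  x[seq_len(g_new)] <- u15 %/% g_new
  extra <- u15 %% g_new
  if (extra) x[seq_len(extra)] <- x[seq_len(extra)] + 1
  mv[, 15] <- x
  scev <- make_sce(mv)
  pfv <- fit_gene_umi_polynomial(scev, qc_thresholds())
  expect_identical(unname(which(pfv$flag)), 15L)

  # refit after removing the flagged cell: no new flags on the clean cells
  pf2 <- fit_gene_umi_polynomial(scev, qc_thresholds(), fit_on = !pfv$flag)
  expect_false(any(pf2$flag[-15]))
  expect_lt(max(abs(pf2$coefficients - pf$coefficients)), 0.05)

  expect_error(fit_gene_umi_polynomial(sce[, 1:5], qc_thresholds()), "10")
})

test_that("marker scores are panel means of log-normalized expression", {
  ln <- rbind(GAD1 = c(2, 0), GAD2 = c(4, 0), ACTB = c(1, 1))
  colnames(ln) <- c("c1", "c2")
  expect_equal(unname(marker_score(ln, c("GAD1", "GAD2"))), c(3, 0))
  expect_equal(unname(marker_score(ln, "GAD2")), c(4, 0))
  expect_warning(s <- marker_score(ln, c("GAD1", "NOPE"), "p"), "NOPE")
  expect_equal(unname(s), c(2, 0))
  expect_error(marker_score(ln, c("ABSENT1", "ABSENT2"), "ghost"), "ghost")
})

test_that("consensus respects the strict >10% of runs rule", {
  set.seed(1)
  m <- matrix(rpois(50 * 120, 5), nrow = 50,
              dimnames = list(NULL, sprintf("b%03d", 1:120)))
  sce <- make_sce(m)
  th <- qc_thresholds(doublet_runs = 100)
  scorer <- stub_scorer(c(b020 = 11L, b021 = 10L, b022 = 100L), base_seed = 1)
  fl <- consensus_doublets(sce, th, base_seed = 1, scorer = scorer)
  expect_true(fl[["b020"]])    # 11/100 > 0.10
  expect_false(fl[["b021"]])   # 10/100 is not > 0.10 (strict)
  expect_true(fl[["b022"]])
  expect_true(all(fl[sprintf("b%03d", 1:15)]))  # always-high block
  expect_false(any(fl[sprintf("b%03d", 30:120)]))

  # a single run: any call implies the flag (1.0 > 0.10)
  th1 <- qc_thresholds(doublet_runs = 1)
  fl1 <- consensus_doublets(sce, th1, base_seed = 1,
                            scorer = stub_scorer(c(b030 = 1L), base_seed = 1))
  expect_true(fl1[["b030"]])
})

test_that("doublet scorer separates planted doublets and is deterministic", {
  cfg <- sim_config(n_donors = 1, regions = "CN", cells_per_sample = 400,
                    n_genes = 1500, class_tree = celltype_class_tree(n_class_markers = 40),
                    doublet_rate = 0.05, seed = 15)
  sce <- simulate_dataset(cfg)
  sc1 <- score_doublets_once(sce, seed = 3)
  sc2 <- score_doublets_once(sce, seed = 3)
  expect_identical(sc1, sc2)
  dbl <- sce$true_doublet
  expect_lt(mean(sc1[!dbl]), 0.2)
  expect_gt(median(sc1[dbl]), median(sc1[!dbl]))
  expect_error(score_doublets_once(sce, seed = 1, k = 0), "positive")
})

test_that("multitype flags need two positive panels; contamination is per marker", {
  cfg <- sim_config(n_donors = 1, regions = "CN", cells_per_sample = 500,
                    n_genes = 3500, class_tree = celltype_class_tree(),
                    doublet_rate = 0, seed = 9)
  sce <- normalize_log(simulate_dataset(cfg))
  mt <- multitype_doublet_flags(sce)
  # single-positive cells are called their type, never flagged
  one_pos <- rowSums(mt$positive) == 1
  expect_false(any(mt$flag[one_pos]))
  called <- !is.na(mt$calls) & mt$calls != "multiple"
  expect_gt(mean(mt$calls[called] == sce$true_class[called]), 0.95)

  # constructed Neuron+Oligo doublets are flagged
  m <- counts(sce)
  neur <- which(sce$true_class == "Neurons")[1:25]
  olig <- which(sce$true_class == "Oligos")[1:25]
  md <- m[, neur] + m[, olig]
  colnames(md) <- sprintf("dbl%02d", 1:25)
  sce2 <- make_sce(as.matrix(cbind(m, md)))
  mt2 <- multitype_doublet_flags(normalize_log(sce2))
  expect_gte(mean(mt2$flag[501:525]), 0.8)

  # contamination: flags only cells above the cutoff; absent markers warn-free
  ln <- matrix(0, 5, 60, dimnames = list(
    c("NEUROD2", "TMEM155", "CARTPT", "SLC17A7", "ACTB"), sprintf("c%02d", 1:60)))
  ln["NEUROD2", 1] <- 2.0
  ln["CARTPT", 2] <- 0.5
  sceC <- make_sce(ln)
  logcounts(sceC) <- Matrix::Matrix(ln, sparse = TRUE)
  fl <- contamination_filter(sceC)
  expect_true(fl[["c01"]])
  expect_false(fl[["c02"]])
  expect_equal(sum(fl), 1)
})

test_that("run_qc applies the staged waterfall with first-failure attribution", {
  # clean world plus 5 constructed violations; consensus stage stubbed off
  cfg <- sim_config(n_donors = 1, regions = "CN", cells_per_sample = 400,
                    n_genes = 8000, class_tree = celltype_class_tree(),
                    doublet_rate = 0, seed = 33)
  sce <- simulate_dataset(cfg)
  m <- as.matrix(counts(sce))
  rownames(m)[nrow(m)] <- "NEUROD2"   # a silent claustrum marker
  m["NEUROD2", ] <- 0
  G <- nrow(m)
  v <- function(i) colnames(m)[i]
  # depth low / high
  m[, 1] <- 0; m[1:300, 1] <- 1                       # 300 umi
  m[, 2] <- 0; m[1:7000, 2] <- 40                     # 280000 umi
  # mito 15%
  mito_rows <- which(startsWith(rownames(m), "MT-"))
  m[, 3] <- 0; m[1:2000, 3] <- 3; m[mito_rows[1], 3] <- 1059  # 1059/7059 = 15%
  # poly outlier: 1900 genes at 4 counts (far below the ~4000-gene curve)
  m[, 4] <- 0; m[1:1300, 4] <- 6
  # contamination
  m["NEUROD2", 5] <- 60
  sce2 <- make_sce(m)
  sce2$sample <- rep("S1", ncol(m))
  res <- run_qc(sce2, skip_consensus = TRUE)
  ex <- res$report$exclusions
  expect_equal(unname(ex[c("depth_low", "depth_high", "mito", "poly_outlier",
                           "contamination")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(ex[["doublet_consensus"]], 0L)
  removed <- setdiff(colnames(sce2), colnames(res$filtered))
  expect_setequal(removed, v(1:5))
  # determinism
  res2 <- run_qc(sce2, skip_consensus = TRUE)
  expect_identical(res$report$exclusions, res2$report$exclusions)
})

test_that("tightening thresholds never increases survivors", {
  cfg <- sim_config(n_donors = 1, regions = "CN", cells_per_sample = 300,
                    n_genes = 2000, class_tree = celltype_class_tree(n_class_markers = 40),
                    doublet_rate = 0, seed = 19)
  sce <- simulate_dataset(cfg)
  loose <- qc_thresholds(min_umi = 100, min_genes = 100)
  tight <- qc_thresholds(min_umi = 2000, min_genes = 900)
  hf_loose <- hard_filters(sce, loose)
  hf_tight <- hard_filters(sce, tight)
  expect_lte(sum(!(hf_tight$depth_low | hf_tight$depth_high | hf_tight$mito)),
             sum(!(hf_loose$depth_low | hf_loose$depth_high | hf_loose$mito)))
  # per-rule flags are order-invariant in the cells
  perm <- sample(ncol(sce))
  hf_perm <- hard_filters(sce[, perm], loose)
  expect_equal(hf_perm[colnames(sce), "depth_low"], hf_loose$depth_low)
})
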