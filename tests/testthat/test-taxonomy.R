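test_that("log-normalization scales cells to the target sum", {
  m <- Matrix::Matrix(cbind(c(1, 1, 2), c(10, 10, 20), c(0, 5, 5)),
                      sparse = TRUE)
  rownames(m) <- c("a", "b", "c"); colnames(m) <- c("x", "y", "z")
  sce <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
  ln <- logcounts(normalize_log(sce))
  expect_equal(as.numeric(ln[, "x"]), log1p(c(2500, 2500, 5000)))
  # proportional cells normalize identically
  expect_equal(as.numeric(ln[, "x"]), as.numeric(ln[, "y"]))
  # a cell already at the target sum only gets log1p
  m2 <- Matrix::Matrix(matrix(c(4000, 6000), ncol = 1), sparse = TRUE)
  dimnames(m2) <- list(c("a", "b"), "w")
  sce2 <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = m2))
  expect_equal(as.numeric(logcounts(normalize_log(sce2))),
               log1p(c(4000, 6000)))
  # zero cells are rejected
  m3 <- Matrix::Matrix(cbind(c(1, 1), c(0, 0)), sparse = TRUE)
  sce3 <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = m3))
  expect_error(normalize_log(sce3), "zero total")
})

test_that("HVG selection ranks by binned dispersion and honours exclusions", {
  set.seed(5)
  n <- 200
  base <- matrix(rpois(50 * n, 5), nrow = 50)
  bimodal <- c(rpois(n / 2, 1), rpois(n / 2, 30))
  m <- rbind(base, bimodal, constant = rep(3, n))
  rownames(m) <- c(sprintf("g%03d", 1:50), "BIMODAL", "CONSTANT")
  ln <- log1p(m)  # already comparable scale
  expect_equal(select_hvg(ln, n = 1), "BIMODAL")
  expect_false("CONSTANT" %in% select_hvg(ln, n = 51))
  excl <- rownames(ln) == "BIMODAL"
  expect_false("BIMODAL" %in% select_hvg(ln, n = 10, exclude = excl))
  expect_warning(out <- select_hvg(ln, n = 1000), "eligible")
  expect_lte(length(out), 51)
})

test_that("embedding + Louvain recovers planted blobs deterministically", {
  set.seed(2)
  n <- 500
  centers <- matrix(rnorm(2 * 30, sd = 6), nrow = 2)
  blob <- rep(1:2, each = n / 2)
  ln <- t(centers[blob, ] + matrix(rnorm(n * 30), nrow = n))
  rownames(ln) <- sprintf("g%02d", 1:30)
  colnames(ln) <- sprintf("c%03d", 1:n)
  ec <- embed_and_cluster(ln, n_pcs = 10, resolution = 0.5, seed = 3)
  expect_equal(nlevels(ec$clusters), 2)
  expect_equal(ari(ec$clusters, blob), 1.0)
  # same seed, same partition
  ec2 <- embed_and_cluster(ln, n_pcs = 10, resolution = 0.5, seed = 3)
  expect_identical(ec$clusters, ec2$clusters)
  # resolution -> 0 on connected data collapses to one cluster
  ln1 <- t(matrix(rnorm(300 * 30), nrow = 300))
  rownames(ln1) <- sprintf("g%02d", 1:30)
  colnames(ln1) <- sprintf("c%03d", 1:300)
  ec0 <- embed_and_cluster(ln1, n_pcs = 10, resolution = 1e-4, seed = 3)
  expect_equal(nlevels(ec0$clusters), 1)
  expect_error(embed_and_cluster(ln[, 1:10], n_pcs = 5, seed = 1), "k")
})

test_that("annotate_clusters takes the argmax panel with name tie-break", {
  ln <- matrix(0, 4, 60, dimnames = list(
    c("AQP4", "ADGRV1", "MBP", "MEG3"), sprintf("c%02d", 1:60)))
  ln[c("AQP4", "ADGRV1"), 1:30] <- 3       # astro-like cluster
  ln["MBP", 31:50] <- 4                    # oligo-like cluster
  clusters <- rep(c("k1", "k2", "k3"), c(30, 20, 10))
  panels <- list(Astrocytes = c("AQP4", "ADGRV1"), Oligos = "MBP",
                 Neurons = "MEG3")
  expect_warning(ann <- annotate_clusters(ln, clusters, panels), "tie")
  expect_equal(unname(ann$cluster_labels[c("k1", "k2")]),
               c("Astrocytes", "Oligos"))
  # all-zero cluster k3: alphabetically first label
  expect_equal(unname(ann$cluster_labels["k3"]), "Astrocytes")
})

test_that("neuron refinement applies strict depth bounds to neurons only", {
  G <- 13000
  cell <- function(umi, genes) {
    x <- numeric(G)
    x[seq_len(genes)] <- umi %/% genes
    extra <- umi %% genes
    if (extra) x[seq_len(extra)] <- x[seq_len(extra)] + 1
    x
  }
  m <- cbind(n_ok = cell(5000, 3000),       # exactly at the kept boundary
             n_low_umi = cell(4999, 3000),
             n_low_genes = cell(6000, 2999),
             n_high_genes = cell(13000, 12001),
             n_boundary_high = cell(12000, 12000),
             glia_deep = cell(8000, 5000))
  sce <- make_sce(m)
  labels <- c(rep("Neurons", 5), "Oligos")
  kept <- refine_neurons(sce, labels)
  expect_setequal(colnames(kept), c("n_ok", "n_boundary_high"))
  expect_error(refine_neurons(sce, rep("Oligos", 6)), "Neurons")
})

test_that("interneuron clusters need GAD and no MSN/excitatory expression", {
  cfg <- sim_config(n_donors = 2, regions = "CN", cells_per_sample = 400,
                    n_genes = 6000, class_tree = neuron_world_tree(),
                    doublet_rate = 0, seed = 21,
                    composition = list(CN = c(Astrocytes = 0.2, Oligos = 0.2,
                                              Neurons = 0.6)))
  sce <- normalize_log(simulate_dataset(cfg))
  neu <- sce[, sce$true_class == "Neurons"]
  clusters <- neu$true_subclass   # cluster = planted program
  sel <- select_interneurons(neu, clusters)
  expect_identical(sel$clusters_selected, "INT")
  expect_gte(mean(colnames(neu)[neu$true_subclass == "INT"] %in% sel$cells),
             0.95)
  st <- sel$cluster_status
  expect_true(st$MSN[st$cluster == "MSN"])
  expect_true(st$excitatory[st$cluster == "EXC"])
  expect_false(st$selected[st$cluster == "MSN"])
  expect_false(st$selected[st$cluster == "EXC"])
})

test_that("wilcoxon marker ranking matches the exact oracle and flags markers", {
  # {1,2} vs {3,4}: exact two-sided p = 2/6
  wr <- wilcox_ranksum(c(1, 2), c(3, 4))
  expect_equal(wr$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(wr$method, "exact")

  # table version on a small two-group matrix
  ln <- rbind(gene1 = c(1, 2, 3, 4), gene2 = c(5, 5, 5, 5))
  colnames(ln) <- sprintf("c%d", 1:4)
  res <- rank_markers_wilcoxon(ln, c("a", "a", "b", "b"))
  expect_equal(res$p[res$gene == "gene1" & res$group == "a"], 1 / 3,
               tolerance = 1e-12)
  expect_equal(res$p[res$gene == "gene2" & res$group == "a"], 1)

  # a gene expressed only in one group tops that group's ranking
  set.seed(31)
  X <- matrix(rnorm(50 * 60, 1), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:60)))
  X[X < 0] <- 0
  X["g07", ] <- 0
  grp <- rep(c("u", "v"), each = 30)
  X["g07", grp == "u"] <- 5
  res2 <- rank_markers_wilcoxon(X, grp)
  top_u <- res2[res2$group == "u", ]
  expect_equal(top_u$gene[1], "g07")

  # null p-values are roughly uniform (normal-approximation path)
  set.seed(32)
  Xn <- matrix(rnorm(1000 * 40), nrow = 1000)
  rownames(Xn) <- sprintf("g%04d", 1:1000)
  resn <- rank_markers_wilcoxon(Xn, rep(c("u", "v"), each = 20))
  ks <- suppressWarnings(ks.test(resn$p[resn$group == "u"], "punif"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("BH adjustment matches brute force and keeps monotonicity", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    adj
  }
  set.seed(77)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.5)
  a <- bh_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
})

test_that("correlation merging uses strict clique semantics", {
  # one cell per subtype: centroids are the cells themselves
  set.seed(12)
  base <- rnorm(200)
  A <- base + rnorm(200, sd = 0.6)
  B <- base + rnorm(200, sd = 0.6)
  C <- rnorm(200)
  ln <- cbind(A = A, B = B, C = C)
  rownames(ln) <- sprintf("g%03d", 1:200)
  subtypes <- c("A", "B", "C")
  r_ab <- cor(A, B)
  expect_gt(r_ab, 0.49)
  mb <- merge_by_correlation(t(t(ln)), subtypes, threshold = 0.49)
  expect_equal(mb$classes, list("A/B" = c("A", "B"), "C" = "C"))
  expect_equal(unname(mb$merge_map[c("A", "B", "C")]),
               c("A/B", "A/B", "C"))

  # exact boundary: threshold equal to the observed correlation -> no merge
  r_exact <- mb$correlations["A", "B"]
  mb_strict <- merge_by_correlation(t(t(ln)), subtypes, threshold = r_exact)
  expect_equal(length(mb_strict$classes), 3L)

  # threshold -1: everything joins one class
  mb_all <- merge_by_correlation(t(t(ln)), subtypes, threshold = -1)
  expect_equal(length(mb_all$classes), 1L)

  # invariance to cell order and to global scaling
  perm <- c(3, 1, 2)
  mb_perm <- merge_by_correlation(t(t(ln[, perm])), subtypes[perm],
                                  threshold = 0.49)
  expect_equal(mb_perm$classes, mb$classes)
  mb_scaled <- merge_by_correlation(t(t(ln * 7)), subtypes, threshold = 0.49)
  expect_equal(mb_scaled$classes, mb$classes)
})

test_that("correlation dendrogram uses average linkage on 1 - r", {
  set.seed(9)
  base <- rnorm(100)
  ln <- cbind(A = base + rnorm(100, sd = 0.2),
              B = base + rnorm(100, sd = 0.2),
              C = rnorm(100),
              A2 = base + rnorm(100, sd = 0.2))
  rownames(ln) <- sprintf("g%03d", 1:100)
  groups <- c("A", "B", "C", "A")  # A has two cells; centroid averaging
  dd <- correlation_dendrogram(ln, groups)
  # A and B merge first (r ~ 0.9), then C
  expect_equal(sort(dd$hclust$labels[dd$hclust$merge[1, ] * -1]),
               c("A", "B"))
  expect_true(all(diff(dd$hclust$height) >= -1e-12))
  expect_match(dd$newick, "C")
  # identical centroids merge at height ~0
  ln2 <- cbind(X = base, Y = base, Z = rnorm(100))
  rownames(ln2) <- sprintf("g%03d", 1:100)
  dd2 <- correlation_dendrogram(ln2, c("X", "Y", "Z"))
  expect_lt(dd2$hclust$height[1], 1e-10)
})

test_that("gene panels subset by prefix and explicit list", {
  genes <- c("DRD1", "GABRA1", "ACTB", "GRIN2B", "POLR2M")
  spec <- receptor_panel_spec()
  out <- subset_gene_panel(genes, prefixes = spec$prefixes, genes = spec$extra)
  expect_equal(out, c("DRD1", "GABRA1", "GRIN2B", "POLR2M"),
               ignore_attr = TRUE)
  info <- attr(out, "panel_info")
  expect_equal(info$n_matched, 4L)
  expect_equal(info$n_unmatched, 2L)  # PEPL1, GCOM1 absent
  # matrix form preserves order; empty match warns
  m <- matrix(1, 5, 2, dimnames = list(genes, c("c1", "c2")))
  sub <- subset_gene_panel(m, prefixes = "DRD")
  expect_equal(rownames(sub), "DRD1")
  expect_warning(subset_gene_panel(genes, prefixes = "ZZZ"), "no genes")
})
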