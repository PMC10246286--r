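# shared fixture builders for the test suite; everything is generated in
# code, no files

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tb <- table(a, b)
  s <- sum(choose(tb, 2))
  r <- sum(choose(rowSums(tb), 2))
  cc <- sum(choose(colSums(tb), 2))
  n <- choose(sum(tb), 2)
  (s - r * cc / n) / ((r + cc) / 2 - r * cc / n)
}

# SingleCellExperiment from a plain counts matrix
make_sce <- function(m, sample = NULL, region = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%04d", seq_len(ncol(m)))
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(sample)) cd$sample <- sample
  if (!is.null(region)) cd$region <- region
  rd <- S4Vectors::DataFrame(
    gene = rownames(m),
    mito = startsWith(rownames(m), "MT-"),
    ribo = startsWith(rownames(m), "RPS") | startsWith(rownames(m), "RPL"),
    sex = rep(FALSE, nrow(m)),
    row.names = rownames(m))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
    colData = cd, rowData = rd)
}

# a marker panel padded with synthetic companion genes
pad_panel <- function(markers, prefix, n) {
  c(markers, sprintf("%s.M%02d", prefix, seq_len(max(0, n - length(markers)))))
}

# three-level world for the interneuron-detection stage: two glia types and
# a Neurons class split into MSN / inhibitory / excitatory programs
neuron_world_tree <- function(n_markers = 60, n_sub = 30) {
  list(
    Astrocytes = list(markers = pad_panel(c("AQP4", "ADGRV1"), "AST", n_markers),
                      effect = log(8),
                      subclasses = list(Astrocytes = list(markers = character(0), effect = 0))),
    Oligos = list(markers = pad_panel(c("MBP", "MOG", "MAG"), "OLI", n_markers),
                  effect = log(8),
                  subclasses = list(Oligos = list(markers = character(0), effect = 0))),
    Neurons = list(markers = pad_panel("MEG3", "NEU", n_markers), effect = log(8),
                   subclasses = list(
                     MSN = list(markers = pad_panel(c("PPP1R1B", "DRD1", "DRD2", "MEIS2"), "MSN", n_sub),
                                effect = log(12)),
                     INT = list(markers = pad_panel(c("GAD1", "GAD2"), "INT", n_sub),
                                effect = log(12)),
                     EXC = list(markers = pad_panel(c("SLC17A7", "RORB"), "EXC", n_sub),
                                effect = log(12)))))
}

# deterministic stub doublet scorer: a low background, a stable high-score
# block (cells 1-15, so the per-run mixture fit is well conditioned), and
# chosen cells scoring high in exactly the first N runs
stub_scorer <- function(high_in_first_n_runs, base_seed) {
  function(sce, seed, k) {
    n <- ncol(sce)
    set.seed(seed * 7919L)
    sc <- runif(n, 0.01, 0.06)
    sc[seq_len(min(15, n))] <- runif(min(15, n), 0.85, 0.95)
    run_index <- seed - base_seed + 1L
    for (nm in names(high_in_first_n_runs)) {
      if (run_index <= high_in_first_n_runs[[nm]])
        sc[match(nm, colnames(sce))] <- 0.9
    }
    setNames(sc, colnames(sce))
  }
}

build_qc_acceptance_fixture <- function(seed = 101) {
  simulate_qc_benchmark(seed)
}
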