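#' Simulation configuration for synthetic multi-sample snRNA-seq data
#'
#' Describes a synthetic multi-donor, two-region single-nucleus experiment:
#' a hierarchical class/subclass marker structure, negative-binomial count
#' noise, per-cell depth variation, planted heterotypic doublets,
#' mitochondrial/ribosomal/sex-linked gene groups, region-dependent class
#' composition, region-dependent differential expression within chosen
#' classes, and a continuous standard-normal latent gradient within chosen
#' subclasses.
#'
#' The negative binomial is parameterized by mean `mu` and dispersion `phi`
#' with `Var = mu + phi * mu^2` (the same parameterization used by
#' [nb_glm_lrt()]).  All planted effects are on the natural-log scale of the
#' mean: a marker with effect `log(6)` multiplies the baseline mean by 6.
#' Per-cell sequencing-depth variation is a log-normal scaling factor with
#' standard deviation `depth_sd` on the log scale.
#'
#' @param n_donors number of donors; each donor contributes one sample per
#'   region, so there are `n_donors * length(regions)` samples.
#' @param regions character vector of region labels (default `c("CN","Pu")`).
#' @param cells_per_sample cells simulated per sample.
#' @param n_genes total gene universe size (markers and special gene groups
#'   included).
#' @param class_tree nested class specification; see [default_class_tree()].
#' @param baseline_mean baseline NB mean per gene per cell before scaling.
#' @param nb_dispersion NB dispersion `phi` (`Var = mu + phi mu^2`).
#' @param depth_sd SD of the per-cell log-normal depth factor (log scale).
#' @param doublet_rate fraction of cells simulated as heterotypic doublets.
#' @param mito_gene_count,ribo_gene_count,sex_gene_count sizes of the
#'   mitochondrial (`MT-` prefixed), ribosomal-protein (`RPS`/`RPL`) and
#'   sex-linked gene groups.
#' @param composition named list `region -> named class-proportion vector`;
#'   each vector must cover all classes in `class_tree` and sum to 1.
#'   Default: uniform over classes in every region.
#' @param regional_de list of `list(class=, genes=, effect=)` triples: the
#'   named genes gain `effect` (natural log) in the second region relative
#'   to the first, within the given class.
#' @param gradient list of `list(subclass=, genes=, weights=)`: cells of the
#'   subclass receive a standard-normal latent score `z`, and gene `g`'s
#'   log-mean gains `weights[g] * z`.
#' @param seed integer seed controlling every random draw.
#' @return object of class `sim_config` (a validated list).
#' @seealso [build_ground_truth()], [simulate_counts()]
#' @export
sim_config <- function(n_donors = 6,
                       regions = c("CN", "Pu"),
                       cells_per_sample = 500,
                       n_genes = 2000,
                       class_tree = default_class_tree(),
                       baseline_mean = 1,
                       nb_dispersion = 0.3,
                       depth_sd = 0.3,
                       doublet_rate = 0.05,
                       mito_gene_count = 13,
                       ribo_gene_count = 40,
                       sex_gene_count = 10,
                       composition = NULL,
                       regional_de = list(),
                       gradient = list(),
                       seed = 1L) {
  classes <- names(class_tree)
  if (is.null(composition)) {
    uni <- setNames(rep(1 / length(classes), length(classes)), classes)
    composition <- setNames(rep(list(uni), length(regions)), regions)
  }
  cfg <- list(n_donors = as.integer(n_donors), regions = regions,
              cells_per_sample = as.integer(cells_per_sample),
              n_genes = as.integer(n_genes), class_tree = class_tree,
              baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
              depth_sd = depth_sd, doublet_rate = doublet_rate,
              mito_gene_count = as.integer(mito_gene_count),
              ribo_gene_count = as.integer(ribo_gene_count),
              sex_gene_count = as.integer(sex_gene_count),
              composition = composition, regional_de = regional_de,
              gradient = gradient, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config$class_tree), length(config$class_tree) >= 1)
  classes <- names(config$class_tree)
  if (config$doublet_rate < 0 || config$doublet_rate >= 1)
    stop("doublet_rate must lie in [0, 1)")
  if (config$baseline_mean < 0) stop("baseline_mean must be non-negative")
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  for (rg in names(config$composition)) {
    v <- config$composition[[rg]]
    if (!setequal(names(v), classes))
      stop("composition for region '", rg,
           "' must name exactly the classes of class_tree")
    if (abs(sum(v) - 1) > 1e-9)
      stop("composition for region '", rg, "' does not sum to 1 (sum = ",
           format(sum(v), digits = 12), ")")
    if (any(v < 0)) stop("composition for region '", rg, "' has negative entries")
  }
  genes <- sim_gene_universe(config)
  for (de in config$regional_de) {
    if (!de$class %in% classes) stop("regional_de references unknown class '", de$class, "'")
    bad <- setdiff(de$genes, genes)
    if (length(bad)) stop("regional_de references unknown gene(s): ",
                          paste(bad, collapse = ", "))
    stopifnot(all(is.finite(de$effect)))
  }
  subclasses <- unlist(lapply(config$class_tree, function(cl) names(cl$subclasses)))
  for (gr in config$gradient) {
    if (!gr$subclass %in% subclasses)
      stop("gradient references unknown subclass '", gr$subclass, "'")
    bad <- setdiff(gr$genes, genes)
    if (length(bad)) stop("gradient references unknown gene(s): ",
                          paste(bad, collapse = ", "))
    stopifnot(length(gr$weights) == length(gr$genes), all(is.finite(gr$weights)))
  }
  for (cl in config$class_tree) {
    stopifnot(all(is.finite(cl$effect)), length(cl$subclasses) >= 1)
    for (sc in cl$subclasses) stopifnot(all(is.finite(sc$effect)))
  }
  invisible(config)
}

.sanitize <- function(x) gsub("[^A-Za-z0-9]+", "-", x)

.sex_gene_names <- function(n) {
  base <- c("XIST", "UTY", "USP9Y", "DDX3Y", "KDM5D", "EIF1AY", "NLGN4Y",
            "TXLNGY", "ZFY", "PRKY")
  out <- c(base, sprintf("SEXL%d", seq_len(max(0, n - length(base)))))
  out[seq_len(n)]
}

#' Built-in class trees
#'
#' `default_class_tree()` returns the 8-class / 14-subclass striatal
#' interneuron taxonomy used throughout the test suite (PTHLH, TAC3, CCK,
#' CCK/VIP, SST/NPY, SST/GRIK3, PVALB and CHAT classes).  Each class has
#' `n_class_markers` shared marker genes (its eponymous gene plus synthetic
#' companions) and each subclass `n_subclass_markers` private markers, all
#' elevated multiplicatively over baseline.
#'
#' `celltype_class_tree()` returns a flat 6-type tree of the major striatal
#' cell populations (Oligos, Microglia, OPCs, Neurons, Astrocytes,
#' Vascular) whose marker genes are the canonical human symbols keyed on by
#' [default_marker_panels()]; each type is its own (single) subclass, so
#' planted doublets are always cross-type.
#'
#' @param n_class_markers,n_subclass_markers marker genes per class/subclass.
#' @param class_effect,subclass_effect natural-log elevation of marker genes
#'   over baseline.
#' @return a nested list: `class -> list(markers, effect, subclasses)` with
#'   `subclasses: subclass -> list(markers, effect)`.
#' @export
default_class_tree <- function(n_class_markers = 40, n_subclass_markers = 14,
                               class_effect = log(8), subclass_effect = log(12)) {
  spec <- list(
    "PTHLH"     = c("PTHLH-1", "PTHLH-2", "PTHLH-3"),
    "TAC3"      = c("TAC3-1", "TAC3-2"),
    "CCK"       = c("CCK-1", "CCK-2"),
    "CCK/VIP"   = "CCK/VIP-1",
    "SST/NPY"   = c("SST/NPY-1", "SST/NPY-2"),
    "SST/GRIK3" = "SST/GRIK3-1",
    "PVALB"     = c("PVALB-1", "PVALB-2"),
    "CHAT"      = "CHAT-1")
  tree <- list()
  for (cl in names(spec)) {
    cm <- c(.sanitize(cl),
            sprintf("%s.M%02d", .sanitize(cl), seq_len(n_class_markers)[-1]))
    subs <- list()
    for (sc in spec[[cl]]) {
      subs[[sc]] <- list(
        markers = sprintf("%s.S%02d", .sanitize(sc), seq_len(n_subclass_markers)),
        effect = subclass_effect)
    }
    tree[[cl]] <- list(markers = cm, effect = class_effect, subclasses = subs)
  }
  tree
}

#' @rdname default_class_tree
#' @export
celltype_class_tree <- function(n_class_markers = 80, class_effect = log(32),
                                neuron_effect = log(64)) {
  canon <- list(
    Astrocytes = c("AQP4", "ADGRV1"),
    Microglia  = c("CSF1R", "FYB1"),
    Oligos     = c("MBP", "MOG", "MAG"),
    OPCs       = c("PTPRZ1", "PDGFRA", "VCAN"),
    Vascular   = c("EBF1", "ABCB1", "ABCA9"),
    Neurons    = "MEG3")
  tree <- list()
  for (cl in names(canon)) {
    cm <- c(canon[[cl]],
            sprintf("%s.M%02d", .sanitize(cl),
                    seq_len(max(0, n_class_markers - length(canon[[cl]])))))
    subs <- setNames(list(list(markers = character(0), effect = 0)), cl)
    # MEG3 and companions are far above baseline in neurons, mirroring the
    # extreme abundance of the canonical neuronal markers
    eff <- if (cl == "Neurons") neuron_effect else class_effect
    tree[[cl]] <- list(markers = cm, effect = eff, subclasses = subs)
  }
  tree
}

# Gene universe implied by a config: markers, then special groups, then
# filler genes up to n_genes. Order is fixed so that identical configs give
# identical universes.
sim_gene_universe <- function(config) {
  tree <- config$class_tree
  markers <- unique(unlist(lapply(tree, function(cl) {
    c(cl$markers, unlist(lapply(cl$subclasses, `[[`, "markers")))
  }), use.names = FALSE))
  mito <- sprintf("MT-G%02d", seq_len(config$mito_gene_count))
  nr <- config$ribo_gene_count
  ribo <- c(sprintf("RPS%d", seq_len(ceiling(nr / 2))),
            sprintf("RPL%d", seq_len(floor(nr / 2))))
  sexg <- .sex_gene_names(config$sex_gene_count)
  special <- c(mito, ribo, sexg)
  n_fill <- config$n_genes - length(markers) - length(special)
  if (n_fill < 0)
    stop("n_genes (", config$n_genes, ") smaller than markers + special genes (",
         length(markers) + length(special), ")")
  filler <- sprintf("GENE%05d", seq_len(n_fill))
  c(markers, special, filler)
}

#' Draw the ground truth for a synthetic experiment
#'
#' Assigns every cell a sample, region, class (multinomial from the
#' region's composition vector), a subclass (uniform within class), a
#' heterotypic-doublet indicator (`Bernoulli(doublet_rate)`, with a partner
#' subclass drawn from a different subclass), and a standard-normal latent
#' factor score for cells of gradient-bearing subclasses.  Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return object of class `ground_truth`: list with `cells` (a data.frame
#'   with one row per cell: `barcode`, `donor`, `sample`, `region`,
#'   `class`, `subclass`, `label` (subclass, or `"doublet"`),
#'   `is_doublet`, `partner_subclass`, `z`) and `config`.
#' @export
build_ground_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  tree <- config$class_tree
  classes <- names(tree)
  sub_of <- lapply(tree, function(cl) names(cl$subclasses))
  all_subs <- unlist(sub_of, use.names = FALSE)
  class_of_sub <- setNames(rep(names(sub_of), lengths(sub_of)), all_subs)
  grad_subs <- vapply(config$gradient, `[[`, "", "subclass")

  rows <- list()
  for (donor in seq_len(config$n_donors)) {
    for (rg in config$regions) {
      smp <- sprintf("D%02d_%s", donor, rg)
      n <- config$cells_per_sample
      comp <- config$composition[[rg]][classes]
      cl_draw <- sample(classes, n, replace = TRUE, prob = comp)
      sc_draw <- vapply(cl_draw, function(cl) {
        s <- sub_of[[cl]]
        if (length(s) == 1) s else sample(s, 1)
      }, "")
      dbl <- runif(n) < config$doublet_rate
      partner <- rep(NA_character_, n)
      if (any(dbl)) {
        partner[dbl] <- vapply(sc_draw[dbl], function(sc) {
          pool <- setdiff(all_subs, sc)
          sample(pool, 1)
        }, "")
      }
      z <- rep(NA_real_, n)
      in_grad <- sc_draw %in% grad_subs & !dbl
      z[in_grad] <- rnorm(sum(in_grad))
      rows[[smp]] <- data.frame(
        barcode = sprintf("%s_C%05d", smp, seq_len(n)),
        donor = sprintf("D%02d", donor), sample = smp, region = rg,
        class = cl_draw, subclass = sc_draw,
        label = ifelse(dbl, "doublet", sc_draw),
        is_doublet = dbl, partner_subclass = partner, z = z,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- list(cells = cells, config = config,
              class_of_subclass = class_of_sub)
  class(out) <- "ground_truth"
  out
}

# per-subclass additive log-mean effect vector over the gene universe
.subclass_log_effects <- function(config, genes) {
  eff <- list()
  for (cl_name in names(config$class_tree)) {
    cl <- config$class_tree[[cl_name]]
    base <- setNames(numeric(length(genes)), genes)
    base[cl$markers] <- base[cl$markers] + cl$effect
    for (sc_name in names(cl$subclasses)) {
      sc <- cl$subclasses[[sc_name]]
      v <- base
      if (length(sc$markers)) v[sc$markers] <- v[sc$markers] + sc$effect
      eff[[sc_name]] <- unname(v)
    }
  }
  eff
}

#' Simulate a UMI count matrix from a ground truth
#'
#' Gene/cell means follow
#' `mu = baseline * depth_factor * exp(marker effects) * exp(regional DE) *
#' exp(w_g z_c)` and counts are drawn `NB(mu, phi)` with
#' `Var = mu + phi mu^2`.  A doublet cell is the sum of two independently
#' simulated singlet profiles from its two (distinct) subclasses, each with
#' its own depth factor.  Regional DE effects apply in the *second* region
#' of `config$regions` (so with the default `c("CN","Pu")`, a positive
#' planted effect means higher expression in Pu).
#'
#' @param truth a [build_ground_truth()] result.
#' @param config the same [sim_config()] used to build `truth`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, per-cell metadata (`sample`, `donor`,
#'   `region`) and ground-truth columns (`true_class`, `true_subclass`,
#'   `true_label`, `true_doublet`, `true_z`) in `colData`, and gene flags
#'   (`mito`, `ribo`, `sex`) in `rowData`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genes <- sim_gene_universe(config)
  G <- length(genes)
  cells <- truth$cells
  n <- nrow(cells)
  eff <- .subclass_log_effects(config, genes)
  gidx <- setNames(seq_len(G), genes)

  # regional DE: additive log effect per (class, region2)
  de_eff <- list()
  region2 <- config$regions[2]
  for (de in config$regional_de) {
    v <- de_eff[[de$class]]
    if (is.null(v)) v <- numeric(G)
    v[gidx[de$genes]] <- v[gidx[de$genes]] + de$effect
    de_eff[[de$class]] <- v
  }
  grad_w <- list()
  for (gr in config$gradient) {
    w <- numeric(G)
    w[gidx[gr$genes]] <- gr$weights
    grad_w[[gr$subclass]] <- w
  }

  log_base <- if (config$baseline_mean > 0) log(config$baseline_mean) else -Inf
  size <- 1 / config$nb_dispersion

  singlet_counts <- function(subclass, region, z, sf) {
    lm <- log_base + eff[[subclass]]
    cl <- truth$class_of_subclass[[subclass]]
    if (!is.null(de_eff[[cl]]) && !is.na(region) && region == region2)
      lm <- lm + de_eff[[cl]]
    if (!is.null(grad_w[[subclass]]) && !is.na(z))
      lm <- lm + grad_w[[subclass]] * z
    mu <- exp(lm) * sf
    if (config$baseline_mean == 0) return(integer(G))
    rnbinom(G, mu = mu, size = size)
  }

  mat <- matrix(0L, nrow = G, ncol = n)
  for (i in seq_len(n)) {
    ci <- cells[i, ]
    # one depth factor per droplet: a doublet's two nuclei share it
    sf <- rlnorm(1, 0, config$depth_sd)
    x <- singlet_counts(ci$subclass, ci$region, ci$z, sf)
    if (ci$is_doublet)
      x <- x + singlet_counts(ci$partner_subclass, ci$region, NA_real_, sf)
    mat[, i] <- x
  }
  counts <- as(as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(genes, cells$barcode)

  rd <- DataFrame(
    gene = genes,
    mito = startsWith(genes, "MT-"),
    ribo = startsWith(genes, "RPS") | startsWith(genes, "RPL"),
    sex = genes %in% .sex_gene_names(config$sex_gene_count),
    row.names = genes)

  cd <- DataFrame(
    sample = cells$sample, donor = cells$donor, region = cells$region,
    true_class = cells$class, true_subclass = cells$subclass,
    true_label = cells$label, true_doublet = cells$is_doublet,
    true_partner = cells$partner_subclass, true_z = cells$z,
    row.names = cells$barcode)

  sce <- SingleCellExperiment(assays = list(counts = counts),
                              colData = cd, rowData = rd)
  metadata(sce)$sim_config <- config
  sce
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [build_ground_truth()] then
#' [simulate_counts()].
#'
#' @inheritParams build_ground_truth
#' @return a `SingleCellExperiment`; the ground truth is embedded in
#'   `colData` (columns prefixed `true_`).
#' @export
simulate_dataset <- function(config) {
  simulate_counts(build_ground_truth(config), config)
}

#' Synthetic QC benchmark with planted rule violations
#'
#' Builds the dataset used to audit the full QC procedure: 3,000 cells
#' (three samples of 1,000) over an 8,000-gene universe with 5%
#' heterotypic doublets, plus six constructed cells — a low-depth violator
#' (300 UMIs), a high-depth violator (280,000 UMIs), a 15%-mitochondrial
#' violator, a gene~UMI polynomial outlier (1,300 detected genes at six
#' counts each, ~2,500 genes below the fitted curve), a regional
#' contamination violator (NEUROD2-positive; NEUROD2 is silent everywhere
#' else), and one boundary cell at exactly 10.0% mitochondrial content
#' that every rule must let through.
#'
#' @param seed integer seed for the underlying simulation.
#' @return list with `sce` (the `SingleCellExperiment`), `violators`
#'   (barcodes of the five planted rule violators, in the order
#'   depth-low, depth-high, mito, poly, contamination) and `boundary`
#'   (the barcode of the 10.0%-mito boundary cell).
#' @export
simulate_qc_benchmark <- function(seed = 101) {
  cfg <- sim_config(n_donors = 3, regions = "CN", cells_per_sample = 1000,
                    n_genes = 8000, class_tree = celltype_class_tree(),
                    doublet_rate = 0.05, seed = seed)
  sce <- simulate_dataset(cfg)
  m <- as.matrix(counts(sce))
  # NEUROD2 (claustrum/amygdala marker) is silent in striatal nuclei
  rownames(m)[nrow(m)] <- "NEUROD2"
  m["NEUROD2", ] <- 0
  singlets <- which(!sce$true_doublet)
  vio <- colnames(m)[singlets[1:5]]
  m[, vio[1]] <- 0; m[1:300, vio[1]] <- 1
  m[, vio[2]] <- 0; m[1:7000, vio[2]] <- 40
  mito_rows <- which(startsWith(rownames(m), "MT-"))
  m[, vio[3]] <- 0; m[1:2000, vio[3]] <- 3; m[mito_rows[1], vio[3]] <- 1059
  m[, vio[4]] <- 0; m[1:1300, vio[4]] <- 6
  m["NEUROD2", vio[5]] <- 60
  bcell <- colnames(m)[singlets[6]]
  x <- m[, bcell]; x[mito_rows] <- 0
  excess <- sum(x) %% 9
  x[which(x > excess)[1]] <- x[which(x > excess)[1]] - excess
  x[mito_rows[1]] <- sum(x) / 9
  m[, bcell] <- x
  counts_new <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  rd <- DataFrame(gene = rownames(m),
                  mito = startsWith(rownames(m), "MT-"),
                  ribo = startsWith(rownames(m), "RPS") |
                    startsWith(rownames(m), "RPL"),
                  sex = rownames(m) %in% .sex_gene_names(cfg$sex_gene_count),
                  row.names = rownames(m))
  out <- SingleCellExperiment(assays = list(counts = counts_new),
                              colData = colData(sce), rowData = rd)
  metadata(out)$sim_config <- cfg
  list(sce = out, violators = vio, boundary = bcell)
}
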