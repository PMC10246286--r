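#' PCA embedding and Louvain clustering
#'
#' Standardizes each gene (zero mean, unit variance) over the chosen
#' highly-variable genes, projects cells on the first `n_pcs` principal
#' components, builds a k-nearest-neighbor graph (Euclidean in PC space)
#' and partitions it with the Louvain algorithm at the given resolution.
#' Deterministic given `seed`.
#'
#' @param x `SingleCellExperiment` (logcounts computed if absent) or a
#'   genes-by-cells log-normalized matrix.
#' @param n_pcs number of principal components (30 for the glia/neuron
#'   pass, 20 for interneuron subclustering).
#' @param resolution Louvain resolution (0.2 for the glia/neuron pass).
#' @param seed integer seed.
#' @param k neighbors in the kNN graph (default 15).
#' @param hvg optional character vector of genes to restrict to (e.g. from
#'   [select_hvg()]).
#' @return list with `clusters` (integer factor per cell), `pca` (cells x
#'   PCs matrix), `graph` (the igraph object).
#' @export
embed_and_cluster <- function(x, n_pcs = 30, resolution = 0.2, seed = 1,
                              k = 15, hvg = NULL) {
  m <- .get_logcounts(x)
  if (!is.null(hvg)) m <- m[intersect(hvg, rownames(m)), , drop = FALSE]
  n <- ncol(m)
  if (n <= k) stop("fewer cells (", n, ") than k+1 (", k + 1, ")")
  if (n_pcs >= min(dim(m))) stop("n_pcs must be below min(cells, genes)")
  X <- as.matrix(Matrix::t(m))
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  set.seed(seed)
  pc <- irlba::prcomp_irlba(X, n = n_pcs, center = FALSE, scale. = FALSE)
  emb <- pc$x
  rownames(emb) <- colnames(m)
  nn <- FNN::get.knn(emb, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  clusters <- factor(igraph::membership(cl))
  names(clusters) <- colnames(m)
  list(clusters = clusters, pca = emb, graph = g)
}

#' Label clusters by canonical marker panels
#'
#' Assigns every cluster the panel label with the highest mean marker
#' score over its cells; ties (including the all-zero case) go to the
#' alphabetically first label, with a warning.
#'
#' @param x `SingleCellExperiment` or log-normalized matrix.
#' @param clusters per-cell cluster factor.
#' @param panels named list of marker panels; see [default_marker_panels()].
#' @return list with `cluster_labels` (named character: cluster -> label),
#'   `cell_labels` (character per cell), `scores` (cluster x panel matrix).
#' @export
annotate_clusters <- function(x, clusters, panels = default_marker_panels()) {
  stopifnot(length(panels) >= 1, length(clusters) > 0)
  ln <- .get_logcounts(x)
  clusters <- as.factor(clusters)
  present <- vapply(panels, function(p) any(p %in% rownames(ln)), TRUE)
  if (any(!present))
    .msg("dropping panels with no measurable marker: ",
         paste(names(panels)[!present], collapse = ", "))
  panels <- panels[present]
  stopifnot(length(panels) >= 1)
  sc <- vapply(names(panels), function(p)
    marker_score(ln, panels[[p]], panel_name = p),
    numeric(ncol(ln)))
  cl_scores <- apply(sc, 2, function(col) tapply(col, clusters, mean))
  cl_scores <- matrix(cl_scores, nrow = nlevels(clusters),
                      dimnames = list(levels(clusters), names(panels)))
  labs <- apply(cl_scores, 1, function(r) {
    top <- names(r)[r == max(r)]
    if (length(top) > 1)
      warning("tie between panels ", paste(top, collapse = ", "),
              "; taking ", sort(top)[1])
    sort(top)[1]
  })
  list(cluster_labels = labs,
       cell_labels = unname(labs[as.character(clusters)]),
       scores = cl_scores)
}

#' Refine the neuronal subset by depth
#'
#' Keeps neuron-labeled nuclei, discarding those with fewer than 5000
#' UMIs, fewer than 3000 genes, or more than 12000 genes (all strict).
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param labels per-cell label vector; cells labeled `neuron_label` are
#'   considered neurons.
#' @param min_umi,min_genes,max_genes depth limits (exclusive).
#' @param neuron_label the label naming neurons (default "Neurons").
#' @return the neuronal `SingleCellExperiment` subset.
#' @export
refine_neurons <- function(sce, labels, min_umi = 5000, min_genes = 3000,
                           max_genes = 12000, neuron_label = "Neurons") {
  stopifnot(length(labels) == ncol(sce))
  if (!any(labels == neuron_label)) stop("no cell labeled '", neuron_label, "'")
  m <- counts(sce)
  umi <- Matrix::colSums(m)
  genes <- Matrix::colSums(m > 0)
  keep <- labels == neuron_label & !(umi < min_umi) & !(genes < min_genes) &
    !.gt(genes, max_genes)
  sce[, keep]
}

#' Select interneuron clusters
#'
#' Cluster-level rule: a cluster is an interneuron cluster when its mean
#' GAD1 or GAD2 score exceeds the gene's mixture threshold (inhibitory
#' positive) while its MSN (PPP1R1B, DRD1, DRD2, MEIS2) and excitatory
#' (RORB, SLC17A7) panel scores stay at or below their thresholds.
#' Mixture thresholds are fitted on the strictly positive per-cell scores
#' (cells expressing no panel gene are trivially negative); a unimodal fit
#' yields no positive clusters for that panel.
#'
#' @param x `SingleCellExperiment` or log-normalized matrix (neuron-refined).
#' @param clusters per-cell cluster factor.
#' @param panels list with elements `inhibitory`, `MSN`, `excitatory`
#'   (default [default_marker_panels()] neuron subsets).
#' @param sd_multiplier mixture threshold SD multiplier (default 4).
#' @return list with `cells` (barcodes of qualifying clusters),
#'   `clusters_selected` (cluster IDs), `cluster_status` (data.frame of
#'   per-cluster positivity calls).
#' @export
select_interneurons <- function(x, clusters, panels = NULL, sd_multiplier = 4) {
  ln <- .get_logcounts(x)
  clusters <- as.factor(clusters)
  if (is.null(panels))
    panels <- default_marker_panels(include_neuron_subsets = TRUE)[
      c("inhibitory", "MSN", "excitatory")]

  panel_positive <- function(score) {
    fit <- .positive_mixture(score, sd_multiplier)
    cl_mean <- tapply(score, clusters, mean)
    if (fit$unimodal) setNames(rep(FALSE, nlevels(clusters)), levels(clusters))
    else cl_mean > fit$threshold
  }

  inh_genes <- intersect(panels$inhibitory, rownames(ln))
  if (!length(inh_genes)) stop("no inhibitory marker present in the matrix")
  # "GAD1 and/or GAD2": positive on any single inhibitory gene or on the
  # panel mean
  inh_scores <- c(lapply(inh_genes, function(g) marker_score(ln, g, g)),
                  list(marker_score(ln, inh_genes, "inhibitory")))
  inh_pos <- Reduce(`|`, lapply(inh_scores, panel_positive))
  msn_pos <- panel_positive(marker_score(ln, panels$MSN, "MSN"))
  exc_pos <- panel_positive(marker_score(ln, panels$excitatory, "excitatory"))

  ok <- inh_pos & !msn_pos & !exc_pos
  status <- data.frame(cluster = levels(clusters), inhibitory = inh_pos,
                       MSN = msn_pos, excitatory = exc_pos, selected = ok)
  sel <- levels(clusters)[ok]
  if (!length(sel)) warning("no cluster qualifies as interneurons")
  list(cells = colnames(ln)[as.character(clusters) %in% sel],
       clusters_selected = sel, cluster_status = status)
}

#' One-vs-rest Wilcoxon marker ranking
#'
#' For every group and gene, a two-sided Wilcoxon rank-sum test of the
#' group's cells against all other cells, with tie correction and normal
#' approximation (exact enumeration when both sides have at most 8 cells),
#' a base-2 log fold change of group mean versus rest mean of normalized
#' expression (pseudocount 1e-9), and Benjamini-Hochberg adjustment within
#' each group.
#'
#' @param x `SingleCellExperiment` or log-normalized matrix.
#' @param groups per-cell group factor (>= 2 groups of >= 2 cells).
#' @return data.frame (class `gene_stat_table`) with columns `gene`,
#'   `group`, `logFC`, `statistic`, `p`, `padj`, ordered by group then p.
#' @export
rank_markers_wilcoxon <- function(x, groups) {
  ln <- .get_logcounts(x)
  groups <- as.factor(droplevels(as.factor(groups)))
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2),
            length(groups) == ncol(ln))
  X <- as.matrix(ln)
  n <- ncol(X)
  R <- t(apply(X, 1, rank))
  # per-gene tie term sum(t^3 - t) over pooled values
  tie_term <- apply(X, 1, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  expr_mean <- expm1(X)  # normalized-scale expression
  out <- list()
  for (g in levels(groups)) {
    in_g <- groups == g
    n1 <- sum(in_g); n2 <- n - n1
    W <- rowSums(R[, in_g, drop = FALSE])
    if (n1 <= 8 && n2 <= 8) {
      p <- vapply(seq_len(nrow(X)), function(i)
        wilcox_ranksum(X[i, in_g], X[i, !in_g])$p.value, 0)
    } else {
      mu <- n1 * (n + 1) / 2
      sig2 <- pmax(0, n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
      p <- rep(1, length(W))
      pos <- sig2 > 0
      z <- (abs(W[pos] - mu) - 0.5) / sqrt(sig2[pos])
      p[pos] <- pmin(1, 2 * pnorm(z, lower.tail = FALSE))
    }
    m1 <- pmax(rowMeans(expr_mean[, in_g, drop = FALSE]), 0)
    m2 <- pmax(rowMeans(expr_mean[, !in_g, drop = FALSE]), 0)
    lfc <- log2((m1 + 1e-9) / (m2 + 1e-9))
    df <- data.frame(gene = rownames(X), group = g, logFC = lfc,
                     statistic = W, p = p, padj = bh_adjust(p),
                     row.names = NULL)
    out[[g]] <- df[order(df$p, -df$logFC, df$gene), ]
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("gene_stat_table", "data.frame")
  res
}

# centroid profiles (mean log-normalized expression across all genes)
.group_centroids <- function(ln, groups) {
  groups <- as.factor(groups)
  vapply(levels(groups), function(g)
    Matrix::rowMeans(ln[, groups == g, drop = FALSE]),
    numeric(nrow(ln)))
}

#' Merge subtypes into classes by centroid correlation
#'
#' Computes subtype centroid profiles (mean log-normalized expression
#' across all genes) and their pairwise Pearson correlations, then groups
#' subtypes so that every within-group pair has correlation strictly above
#' `threshold` (clique semantics, built greedily in alphabetical subtype
#' order for determinism).  Singletons become their own class.  A class is
#' named by joining its members with "/".
#'
#' @param x `SingleCellExperiment` or log-normalized matrix.
#' @param subtypes per-cell subtype factor.
#' @param threshold correlation threshold (default 0.49, strict).
#' @return list with `merge_map` (named character: subtype -> class),
#'   `classes` (list class -> subtypes), `correlations` (subtype
#'   correlation matrix), `cell_classes` (character per cell).
#' @export
merge_by_correlation <- function(x, subtypes, threshold = 0.49) {
  ln <- .get_logcounts(x)
  subtypes <- as.factor(droplevels(as.factor(subtypes)))
  stopifnot(nlevels(subtypes) >= 1)
  cent <- .group_centroids(ln, subtypes)
  if (nlevels(subtypes) == 1) {
    mm <- setNames(levels(subtypes), levels(subtypes))
    return(list(merge_map = mm,
                classes = setNames(list(levels(subtypes)), levels(subtypes)),
                correlations = matrix(1, 1, 1, dimnames = list(levels(subtypes), levels(subtypes))),
                cell_classes = unname(mm[as.character(subtypes)])))
  }
  cc <- cor(cent)
  members <- list()
  remaining <- sort(levels(subtypes))
  while (length(remaining)) {
    grp <- remaining[1]
    remaining <- remaining[-1]
    for (cand in remaining) {
      if (all(cc[cand, grp] > threshold)) grp <- c(grp, cand)
    }
    remaining <- setdiff(remaining, grp)
    members[[paste(sort(grp), collapse = "/")]] <- sort(grp)
  }
  mm <- setNames(rep(names(members), lengths(members)),
                 unlist(members, use.names = FALSE))
  list(merge_map = mm, classes = members, correlations = cc,
       cell_classes = unname(mm[as.character(subtypes)]))
}

#' Correlation dendrogram over groups
#'
#' Agglomerative average-linkage clustering of group centroid profiles with
#' distance `1 - Pearson correlation`.
#'
#' @param x `SingleCellExperiment` or log-normalized matrix.
#' @param groups per-cell group factor (>= 2 groups).
#' @return list with `hclust` (the tree with merge heights), `newick`
#'   (Newick string), `correlations`.
#' @export
correlation_dendrogram <- function(x, groups) {
  ln <- .get_logcounts(x)
  groups <- as.factor(droplevels(as.factor(groups)))
  stopifnot(nlevels(groups) >= 2)
  cent <- .group_centroids(ln, groups)
  cc <- cor(cent)
  hc <- hclust(stats::as.dist(1 - cc), method = "average")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nw, correlations = cc)
}

#' Receptor-gene prefixes
#'
#' Prefixes of neurotransmitter-receptor gene families (dopamine DRD;
#' GABA GABR; acetylcholine CHRN/CHRM; glutamate GRIA/GRIN/GRIK/GRM/GRID/
#' GRIP) plus three glutamate-receptor genes that do not follow the
#' pattern.
#'
#' @return list with `prefixes` and `extra` character vectors.
#' @export
receptor_panel_spec <- function() {
  list(prefixes = c("DRD", "GABR", "CHRN", "CHRM",
                    "GRIA", "GRIN", "GRIK", "GRM", "GRID", "GRIP"),
       extra = c("PEPL1", "POLR2M", "GCOM1"))
}

#' Subset genes by prefixes and/or an explicit list
#'
#' Returns the genes matching any prefix or contained in the explicit
#' list, preserving matrix order, with matched/unmatched tallies.
#'
#' @param x `SingleCellExperiment`, matrix, or character vector of gene
#'   names.
#' @param prefixes character vector of gene-name prefixes.
#' @param genes explicit gene names (e.g. from [read_gene_list()]).
#' @return same type as `x`, restricted to matching genes; attribute
#'   `panel_info` holds `n_matched` and `n_unmatched` (requested explicit
#'   genes not present).
#' @export
subset_gene_panel <- function(x, prefixes = character(0), genes = character(0)) {
  nm <- if (is.character(x)) x else rownames(x)
  hit <- rep(FALSE, length(nm))
  for (p in prefixes) hit <- hit | startsWith(nm, p)
  hit <- hit | nm %in% genes
  n_unmatched <- length(setdiff(genes, nm))
  if (!any(hit)) warning("gene panel matched no genes")
  out <- if (is.character(x)) x[hit] else x[hit, , drop = FALSE]
  attr(out, "panel_info") <- list(n_matched = sum(hit),
                                  n_unmatched = n_unmatched)
  out
}
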