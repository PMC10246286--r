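#' Depth-normalize and log-transform counts
#'
#' Scales every cell to `target_sum` total counts, then applies
#' `log(1 + x)`.  The result is stored as the `logcounts` assay.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay and no all-zero
#'   cells.
#' @param target_sum per-cell total after scaling (default 10000).
#' @return `sce` with a `logcounts` assay added.
#' @export
normalize_log <- function(sce, target_sum = 10000) {
  m <- counts(sce)
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("normalize_log: ", sum(cs == 0), " cell(s) have zero total counts")
  ln <- m %*% Matrix::Diagonal(x = target_sum / cs)
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(m)
  logcounts(sce) <- ln
  sce
}

# logcounts for a plain matrix or an SCE (computing them if absent)
.get_logcounts <- function(x, target_sum = 10000) {
  if (is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% assayNames(x)) x <- normalize_log(x, target_sum)
    logcounts(x)
  } else x
}

#' Select highly variable genes by binned dispersion
#'
#' Ranks genes by normalized dispersion: dispersion = variance/mean of
#' log-normalized expression, z-scored within 20 bins of equal occupancy
#' along the mean.  Genes carrying an exclusion flag (mitochondrial,
#' ribosomal-protein or sex-linked by default) are never selected;
#' zero-variance genes are never selected.  Ties are broken by gene name so
#' the selection is deterministic.
#'
#' @param x `SingleCellExperiment` (logcounts computed if missing) or a
#'   genes-by-cells log-normalized matrix.
#' @param n number of genes to select.
#' @param exclude logical per-gene exclusion vector; defaults to the
#'   `mito | ribo | sex` flags when `x` is an SCE with those columns, else
#'   none.
#' @param n_bins number of mean-occupancy bins (default 20).
#' @return character vector of selected gene names (length `<= n`).
#' @export
select_hvg <- function(x, n = 1500, exclude = NULL, n_bins = 20) {
  if (is(x, "SummarizedExperiment")) {
    rd <- rowData(x)
    if (is.null(exclude) && all(c("mito", "ribo", "sex") %in% colnames(rd)))
      exclude <- rd$mito | rd$ribo | rd$sex
    m <- .get_logcounts(x)
  } else m <- x
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(m))
  stopifnot(length(exclude) == nrow(m))
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- pmax(0, ex2 - mu^2) * ncol(m) / max(1, ncol(m) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  eligible <- !exclude & v > 0
  if (n > sum(eligible)) {
    warning("only ", sum(eligible), " eligible variable genes; requested ", n)
    n <- sum(eligible)
  }
  idx <- which(eligible)
  if (!length(idx)) return(character(0))
  br <- unique(quantile(mu[idx], probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu[idx], breaks = br, include.lowest = TRUE)
  zd <- disp[idx]
  for (b in levels(bins)) {
    sel <- bins == b
    mb <- mean(zd[sel]); sb <- sd(zd[sel])
    zd[sel] <- if (is.na(sb) || sb < 1e-12) 0 else (zd[sel] - mb) / sb
  }
  nm <- rownames(m)[idx]
  ord <- order(-zd, nm)
  nm[ord][seq_len(n)]
}

#' Mean marker expression score
#'
#' Per-cell mean of log-normalized expression over a marker panel.  Panel
#' genes absent from the matrix are dropped with a warning; if none are
#' present an error names the panel.
#'
#' @param x `SingleCellExperiment` or log-normalized matrix.
#' @param panel character vector of marker genes.
#' @param panel_name label used in messages.
#' @return numeric per-cell score vector (named by barcode).
#' @export
marker_score <- function(x, panel, panel_name = "panel") {
  m <- .get_logcounts(x)
  present <- intersect(panel, rownames(m))
  if (!length(present))
    stop("no gene of panel '", panel_name, "' present in the matrix (",
         paste(panel, collapse = ", "), ")")
  if (length(present) < length(panel))
    warning("panel '", panel_name, "': dropping absent gene(s) ",
            paste(setdiff(panel, present), collapse = ", "))
  if (length(present) == 1) {
    s <- m[present, ]
    if (is(s, "sparseVector") || is(s, "Matrix")) s <- as.numeric(s)
  } else {
    s <- Matrix::colMeans(m[present, , drop = FALSE])
  }
  setNames(as.numeric(s), colnames(m))
}
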