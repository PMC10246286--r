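#' Prepare the input of a within-subclass gradient fit
#'
#' Restricts the cells to one (subclass, region) stratum, removes
#' sex-linked, mitochondrial and ribosomal-protein genes, keeps the
#' `n_hvg` most variable remaining genes ([select_hvg()] semantics) and
#' centers every gene.
#'
#' @param sce `SingleCellExperiment` with `counts` (logcounts computed if
#'   absent) and `mito`/`ribo`/`sex` flags in `rowData`.
#' @param subclass_labels per-cell subclass labels.
#' @param subclass subclass to keep.
#' @param region optional region to keep (requires a `region` column).
#' @param n_hvg number of variable genes (default 1200).
#' @param min_cells minimum stratum size (default 50).
#' @return genes-by-cells dense centered matrix.
#' @export
prepare_gradient_input <- function(sce, subclass_labels, subclass,
                                   region = NULL, n_hvg = 1200,
                                   min_cells = 50) {
  stopifnot(length(subclass_labels) == ncol(sce))
  keep <- subclass_labels == subclass
  if (!is.null(region)) keep <- keep & sce$region == region
  if (sum(keep) < min_cells)
    stop("stratum (", subclass, if (!is.null(region)) paste0(", ", region),
         ") has ", sum(keep), " cells; need at least ", min_cells)
  sub <- normalize_log(sce[, keep])
  rd <- rowData(sub)
  excl <- rd$mito | rd$ribo | rd$sex
  hvg <- select_hvg(logcounts(sub), n = n_hvg, exclude = excl)
  X <- as.matrix(logcounts(sub)[hvg, , drop = FALSE])
  X - rowMeans(X)
}

#' Fit a single-latent-factor model by EM
#'
#' Maximum-likelihood factor analysis with one factor:
#' `x_c = w z_c + eps_c`, `z ~ N(0, 1)`, `eps ~ N(0, diag(psi))`.  EM with
#' a spectral initialization (leading eigenvector of the sample
#' covariance) plus seed-controlled jitter; converged when the
#' log-likelihood gain drops below `tol`.  The fit is canonicalized so
#' that `||w|| = 1` (scale absorbed into the scores) and the gene with the
#' largest `|w|` has a positive weight.  Factor scores are posterior
#' means.
#'
#' @param Xc genes-by-cells centered matrix (from
#'   [prepare_gradient_input()]); >= 2 genes and >= 3 cells.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).
#' @param seed seed for the initialization jitter.
#' @param psi_floor lower bound on noise variances (default 1e-8).
#' @return object of class `factor_model`: list with `weights` (named,
#'   unit norm), `psi` (noise variances), `scores` (per-cell posterior
#'   means, scale-carrying), `loglik_trace`, `converged`, `iterations`.
#' @export
fit_factor_model <- function(Xc, tol = 1e-6, max_iter = 1000, seed = 1,
                             psi_floor = 1e-8) {
  X <- as.matrix(Xc)
  G <- nrow(X); n <- ncol(X)
  stopifnot(G >= 2, n >= 3)
  X <- X - rowMeans(X)
  S_diag <- rowSums(X^2) / n

  set.seed(seed)
  # spectral init: leading eigenvector of the sample covariance via the
  # cell-space Gram matrix, with a small jitter
  gram <- crossprod(X) / n
  ev <- eigen(gram, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  lam1 <- max(ev$values[1], 1e-8)
  w <- as.numeric(X %*% v1) / sqrt(n * lam1) * sqrt(lam1)
  w <- w + rnorm(G, 0, 1e-3 * max(sd(w), 1e-6))
  psi <- pmax(S_diag - w^2, 1e-4)

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    a <- w / psi                        # G
    alpha <- 1 + sum(w * a)             # 1 + w' Psi^-1 w
    # log-likelihood of N(0, ww' + Psi) via determinant lemma / Woodbury
    u <- as.numeric(crossprod(X, a))    # n vector: a' x_c
    quad <- sum(X^2 / psi) - sum(u^2) / alpha
    ll <- -0.5 * (n * (G * log(2 * pi) + sum(log(psi)) + log(alpha)) + quad)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol) { converged <- TRUE; break }
    # E-step: posterior z_c ~ N(m_c, v); v = 1/alpha, m_c = u_c / alpha
    mz <- u / alpha
    vz <- 1 / alpha
    Ezz <- sum(mz^2) + n * vz
    # M-step
    xz <- as.numeric(X %*% mz)          # G vector: sum_c x_gc m_c
    w <- xz / Ezz
    psi <- pmax(S_diag - w * xz / n, psi_floor)
  }
  if (!converged)
    warning("factor-model EM did not converge in ", max_iter, " iterations")

  # final posterior scores, then canonicalize
  a <- w / psi
  alpha <- 1 + sum(w * a)
  z <- as.numeric(crossprod(X, a)) / alpha
  nw <- sqrt(sum(w^2))
  if (nw > 0) { w <- w / nw; z <- z * nw }
  if (w[which.max(abs(w))] < 0) { w <- -w; z <- -z }
  names(w) <- rownames(X)
  names(psi) <- rownames(X)
  if (!is.null(colnames(X))) names(z) <- colnames(X)
  out <- list(weights = w, psi = psi, scores = z, loglik_trace = ll_trace,
              converged = converged, iterations = it)
  class(out) <- "factor_model"
  out
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Single-latent-factor model: ", length(x$weights), " genes, ",
      length(x$scores), " cells; ", x$iterations, " EM iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("Top-weight genes:",
      paste(names(sort(abs(x$weights), decreasing = TRUE))[1:min(5, length(x$weights))],
            collapse = ", "), "\n")
  invisible(x)
}

#' Extreme-weight genes of a factor model
#'
#' Returns the `k` genes with the largest (top) and smallest (bottom)
#' signed weights; ties broken by gene name.
#'
#' @param model a [fit_factor_model()] result.
#' @param k genes per tail.
#' @return list with `top` and `bottom` named numeric vectors (weights).
#' @export
top_weight_genes <- function(model, k) {
  w <- model$weights
  stopifnot(k <= length(w))
  ord_top <- order(-w, names(w))
  ord_bot <- order(w, names(w))
  list(top = w[ord_top[seq_len(k)]],
       bottom = w[ord_bot[seq_len(k)]])
}
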