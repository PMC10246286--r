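#' Two-component Gaussian mixture threshold
#'
#' Fits a univariate two-component Gaussian mixture by EM and returns the
#' threshold `mu_low + mixture_sd_multiplier * sd_low`, where "low" is the
#' component with the smaller mean (ties broken towards the smaller
#' variance).  Used to binarize marker scores and doublet scores.
#'
#' Initialization is deterministic: component means at the 25% and 75%
#' quantiles, a shared starting standard deviation, equal weights.  EM stops
#' when the log-likelihood improves by less than `tol` or after `max_iter`
#' iterations.  A degenerate fit (component weight below `1e-3` or standard
#' deviation below `1e-6`), or an input with no spread at all, is reported
#' as unimodal; callers then treat every observation as negative.
#'
#' @param scores numeric vector (at least 50 finite values).
#' @param sd_multiplier multiplier on the low component's SD (default 4).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return an object of class `mixture_threshold`: list with `threshold`
#'   (numeric, `NA` if unimodal), `unimodal` (logical), `means`, `sds`,
#'   `weights` (low component first), `loglik`, `iterations`.
#' @export
mixture_threshold <- function(scores, sd_multiplier = 4, tol = 1e-6,
                              max_iter = 500) {
  stopifnot(sd_multiplier > 0)
  x <- scores[is.finite(scores)]
  if (length(x) < 50)
    stop("mixture_threshold needs at least 50 finite scores, got ", length(x))
  out <- list(threshold = NA_real_, unimodal = TRUE,
              means = c(NA_real_, NA_real_), sds = c(NA_real_, NA_real_),
              weights = c(NA_real_, NA_real_), loglik = NA_real_,
              iterations = 0L)
  class(out) <- "mixture_threshold"
  if (sd(x) < 1e-12) return(out)

  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (diff(mu) < 1e-12) mu <- mu + c(-1, 1) * sd(x) / 2
  sig <- rep(max(sd(x) / 2, 1e-4), 2)
  pw <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- pw[1] * stats::dnorm(x, mu[1], sig[1])
    d2 <- pw[2] * stats::dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    if (!is.finite(n1) || n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sig <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                  sum((1 - g1) * (x - mu[2])^2) / n2))
    sig <- pmax(sig, 1e-10)
    pw <- c(n1, n2) / length(x)
    if (any(!is.finite(c(mu, sig, pw)))) break
    if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  if (any(!is.finite(c(mu, sig, pw))) || min(pw) < 1e-3 || min(sig) < 1e-6)
    return(out)

  low <- if (abs(mu[1] - mu[2]) < 1e-12) which.min(sig) else which.min(mu)
  hi <- 3L - low
  out$unimodal <- FALSE
  out$threshold <- mu[low] + sd_multiplier * sig[low]
  out$means <- mu[c(low, hi)]
  out$sds <- sig[c(low, hi)]
  out$weights <- pw[c(low, hi)]
  out$loglik <- ll_old
  out$iterations <- it
  out
}

# mixture threshold over the strictly positive scores; cells scoring 0 are
# trivially negative, and the zero spike would otherwise collapse the low
# component. Falls back to "unimodal" (no positives) when fewer than 50
# positive scores exist or the fit degenerates.
.positive_mixture <- function(score, sd_multiplier = 4) {
  x <- score[score > 0]
  if (length(x) < 50) {
    out <- list(threshold = NA_real_, unimodal = TRUE,
                means = c(NA_real_, NA_real_), sds = c(NA_real_, NA_real_),
                weights = c(NA_real_, NA_real_), loglik = NA_real_,
                iterations = 0L)
    class(out) <- "mixture_threshold"
    return(out)
  }
  tryCatch(mixture_threshold(x, sd_multiplier = sd_multiplier),
           error = function(e) {
             out <- list(threshold = NA_real_, unimodal = TRUE,
                         means = c(NA_real_, NA_real_),
                         sds = c(NA_real_, NA_real_),
                         weights = c(NA_real_, NA_real_),
                         loglik = NA_real_, iterations = 0L)
             class(out) <- "mixture_threshold"
             out
           })
}

#' @export
print.mixture_threshold <- function(x, ...) {
  if (x$unimodal) {
    cat("Gaussian mixture threshold: unimodal/degenerate fit (no threshold)\n")
  } else {
    cat(sprintf(
      "Gaussian mixture threshold: %.4f  (low: mean %.4f sd %.4f w %.2f; high: mean %.4f sd %.4f w %.2f)\n",
      x$threshold, x$means[1], x$sds[1], x$weights[1],
      x$means[2], x$sds[2], x$weights[2]))
  }
  invisible(x)
}
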