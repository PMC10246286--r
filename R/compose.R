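#' Centered log-ratio transform
#'
#' `CLR_x = log(r_x / g)` with `g` the geometric mean of the class
#' fractions `r_x` (natural log).  Components of a CLR vector sum to zero.
#'
#' @param fractions strictly positive per-class fractions (need not be
#'   normalized; CLR is invariant to a global scale).
#' @return numeric CLR vector (same names).
#' @export
clr <- function(fractions) {
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("clr needs strictly positive fractions; apply the zero policy ",
         "(pseudocount) upstream")
  lg <- log(fractions)
  lg - mean(lg)
}

#' Per-sample class composition with CLR values
#'
#' Counts cells per class within every (sample, region), applies a
#' pseudocount to every class count (so classes absent from a sample keep
#' the CLR defined), converts to fractions and computes CLR values.
#' Samples with zero cells are excluded with a warning.
#'
#' @param labels per-cell class labels.
#' @param sample per-cell sample IDs.
#' @param region per-cell region labels.
#' @param classes class universe (default: observed labels); every class is
#'   tallied in every sample.
#' @param pseudocount added to every class count in every sample (default
#'   0.5).
#' @return data.frame (class `composition_table`) with one row per
#'   (sample, region, class): columns `sample`, `region`, `class`, `count`
#'   (raw), `fraction` (post-pseudocount), `clr`.
#' @export
composition_per_sample <- function(labels, sample, region,
                                   classes = NULL, pseudocount = 0.5) {
  stopifnot(length(labels) == length(sample), length(sample) == length(region))
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  reg_of <- tapply(as.character(region), sample, function(r) r[1])
  out <- list()
  for (smp in sort(unique(as.character(sample)))) {
    sel <- sample == smp
    if (!sum(sel)) next
    cnt <- table(factor(labels[sel], levels = classes))
    cnt <- as.numeric(cnt)
    frac <- (cnt + pseudocount) / sum(cnt + pseudocount)
    out[[smp]] <- data.frame(sample = smp, region = reg_of[[smp]],
                             class = classes, count = cnt, fraction = frac,
                             clr = clr(frac), row.names = NULL)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("composition_table", "data.frame")
  res
}

#' Regional comparison of one class's CLR values
#'
#' Two-sided Wilcoxon rank-sum test of a class's per-sample CLR values
#' between the two regions (unpaired by default; exact enumeration when
#' both regions have at most 8 samples).  With `paired = TRUE`, samples
#' are matched by donor via the `donor` argument and a signed-rank test is
#' performed.
#'
#' @param table a [composition_per_sample()] result.
#' @param class_x the class to test.
#' @param regions the two region labels (default: the two present).
#' @param paired match samples by donor (requires `donor`).
#' @param donor optional named vector `sample -> donor` for pairing.
#' @return list with `statistic`, `p.value`, `method`, `n` (samples per
#'   region).
#' @export
region_wilcoxon <- function(table, class_x, regions = NULL, paired = FALSE,
                            donor = NULL) {
  tb <- table[table$class == class_x, , drop = FALSE]
  if (!nrow(tb)) stop("class '", class_x, "' not present in the table")
  if (is.null(regions)) regions <- sort(unique(tb$region))
  stopifnot(length(regions) == 2)
  x <- tb$clr[tb$region == regions[1]]
  y <- tb$clr[tb$region == regions[2]]
  for (i in 1:2) {
    nn <- c(length(x), length(y))[i]
    if (nn < 2) stop("region '", regions[i], "' has ", nn,
                     " sample(s); need at least 2")
  }
  if (paired) {
    if (is.null(donor)) stop("paired test requires a donor map")
    dx <- donor[tb$sample[tb$region == regions[1]]]
    dy <- donor[tb$sample[tb$region == regions[2]]]
    common <- intersect(dx, dy)
    d <- x[match(common, dx)] - y[match(common, dy)]
    wt <- stats::wilcox.test(d, exact = length(d) <= 20)
    return(list(statistic = unname(wt$statistic), p.value = wt$p.value,
                method = "signed-rank", n = c(length(d), length(d))))
  }
  wr <- wilcox_ranksum(x, y)
  list(statistic = wr$statistic, p.value = wr$p.value, method = wr$method,
       n = c(length(x), length(y)))
}

#' Regional tests for every class
#'
#' Convenience wrapper applying [region_wilcoxon()] to each class of a
#' composition table.  P-values are reported raw (per-class), matching the
#' way regional abundance differences are usually quoted.
#'
#' @inheritParams region_wilcoxon
#' @return data.frame with columns `class`, `statistic`, `p`, and the
#'   per-region mean CLR values.
#' @export
region_tests <- function(table, regions = NULL, paired = FALSE, donor = NULL) {
  classes <- sort(unique(table$class))
  if (is.null(regions)) regions <- sort(unique(table$region))
  rows <- lapply(classes, function(cl) {
    rt <- region_wilcoxon(table, cl, regions = regions, paired = paired,
                          donor = donor)
    m1 <- mean(table$clr[table$class == cl & table$region == regions[1]])
    m2 <- mean(table$clr[table$class == cl & table$region == regions[2]])
    data.frame(class = cl, statistic = rt$statistic, p = rt$p.value,
               mean_clr_1 = m1, mean_clr_2 = m2)
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- paste0("mean_clr_", regions)
  out
}
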