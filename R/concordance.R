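#' Per-variant allele-count concordance R-squared
#'
#' Squared Pearson correlation between two representations of the same
#' variant's alternate-allele counts (e.g. sequenced hard calls vs imputed
#' dosages) over the shared individuals. Pairs with a missing entry on
#' either side are dropped; a variant with fewer than two complete pairs,
#' or zero variance on either side, is flagged `NA` (not-a-value) and is
#' excluded from bin means downstream.
#'
#' @param calls_a,values_b Numeric matrices (individuals x variants, same
#'   shape) or vectors of equal length.
#' @return Numeric vector of per-variant R-squared values in \[0, 1\]
#'   (`NA` where undefined).
#' @export
allele_count_r2 <- function(calls_a, values_b) {
  a <- as.matrix(calls_a)
  b <- as.matrix(values_b)
  if (!all(dim(a) == dim(b))) stop("inputs must have identical dimensions")
  vapply(seq_len(ncol(a)), function(j) {
    ok <- !is.na(a[, j]) & !is.na(b[, j])
    if (sum(ok) < 2L) return(NA_real_)
    x <- a[ok, j]; y <- b[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
}

#' Concordance summarized by MAF bin
#'
#' Averages defined per-variant R-squared values within half-open MAF bins
#' `[lower, upper)`; the default edges `{0.0001, 0.001, 0.01}` give the
#' bins <0.01%, 0.01-0.1%, 0.1-1% and >=1% (labelled ">1%" following the
#' conventional printed label). The grand mean is the unweighted mean over
#' all defined variants, which equals the variant-count-weighted mean of
#' the bin means. Set `pooled = TRUE` to instead pool all (call, value)
#' pairs within a bin into a single correlation.
#'
#' @param r2 Per-variant R-squared from [allele_count_r2()] (ignored when
#'   `pooled = TRUE`).
#' @param maf Per-variant MAF used for binning (conventionally from the
#'   sequenced side).
#' @param edges Interior bin edges on MAF (increasing, within (0, 0.5)).
#' @param pooled Logical; pooled-pairs mode. Requires `calls_a`/`values_b`.
#' @param calls_a,values_b Matrices for pooled mode.
#' @return Data frame of class `concordance_report` with one row per bin
#'   (`bin`, `lower`, `upper`, `n_variants`, `mean_r2`) and attribute
#'   `grand_mean_r2`.
#' @export
binned_concordance <- function(r2, maf, edges = c(1e-4, 1e-3, 1e-2),
                               pooled = FALSE, calls_a = NULL,
                               values_b = NULL) {
  if (length(maf) != length(r2) && !pooled) {
    stop("r2 and maf must have one entry per variant")
  }
  lower <- c(0, edges)
  upper <- c(edges, 0.5)
  labels <- c(sprintf("<%g%%", edges[1] * 100),
              sprintf("%g-%g%%", lower[-c(1, length(lower))] * 100,
                      upper[-c(1, length(upper))] * 100),
              sprintf(">%g%%", edges[length(edges)] * 100))
  bin <- findInterval(maf, lower, rightmost.closed = FALSE)
  if (pooled) {
    if (is.null(calls_a) || is.null(values_b)) {
      stop("pooled mode requires calls_a and values_b")
    }
    r2 <- rep(NA_real_, length(maf))
    mean_r2 <- vapply(seq_along(lower), function(k) {
      sel <- which(bin == k)
      if (!length(sel)) return(NA_real_)
      x <- as.vector(as.matrix(calls_a)[, sel])
      y <- as.vector(as.matrix(values_b)[, sel])
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(x[ok], y[ok])^2
    }, numeric(1))
    n_var <- tabulate(bin, nbins = length(lower))
    grand <- NA_real_
  } else {
    defined <- !is.na(r2)
    mean_r2 <- vapply(seq_along(lower), function(k) {
      sel <- defined & bin == k
      if (!any(sel)) return(NA_real_)
      mean(r2[sel])
    }, numeric(1))
    n_var <- vapply(seq_along(lower), function(k) sum(defined & bin == k),
                    integer(1))
    grand <- if (any(defined)) mean(r2[defined]) else NA_real_
  }
  out <- data.frame(bin = labels, lower = lower, upper = upper,
                    n_variants = n_var, mean_r2 = mean_r2,
                    stringsAsFactors = FALSE)
  attr(out, "grand_mean_r2") <- grand
  class(out) <- c("concordance_report", class(out))
  out
}
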