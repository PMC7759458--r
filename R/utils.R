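#' Canonical variant identity key
#'
#' Variants are identified throughout the package by the 1-based VCF tuple
#' (chrom, pos, ref, alt), serialized as `"chrom:pos:ref:alt"`.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Rank-based inverse-normal transform
#'
#' Maps the non-missing values of `x` to normal quantiles of their
#' mid-ranks, `qnorm((rank - 0.5) / n)`. The result has (approximately)
#' zero mean and unit variance, so regression effects on the transformed
#' scale are in trait standard-deviation units.
#'
#' @param x Numeric vector; `NA` is preserved.
#' @return Numeric vector, same length as `x`.
#' @export
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0L) {
    r <- rank(x[ok], ties.method = "average")
    out[ok] <- stats::qnorm((r - 0.5) / n)
  }
  out
}

# Deterministic per-stage substream seed derived from one global seed, so
# that e.g. genotype and phenotype draws do not share a stream. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code)) %% 99991L
  as.integer((abs(as.numeric(seed)) + h * 1009) %% (.Machine$integer.max - 1L)) + 1L
}

# Format a p-value under the package-wide 2-significant-digit policy.
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_, formatC(p, digits = 2, format = "g"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
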