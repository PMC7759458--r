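#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the genotype counts of a biallelic variant.
#' Conditional on the observed allele counts, the probability of observing
#' `h` heterozygotes among `n` diploid individuals is
#' \deqn{P(h) = \frac{n!}{n_{AA}! \, h! \, n_{aa}!} \;
#'   \frac{2^h \, m! \, (2n-m)!}{(2n)!}}
#' where `m` is the minor allele count and the heterozygote count ranges
#' over values of the same parity as `m`. The two-sided p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one, so p is in (0, 1]; a monomorphic variant has a single configuration
#' and p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer genotype counts
#'   (vectors are recycled to a common length).
#' @return Numeric vector of exact p-values.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  ln <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  a <- rep_len(as.numeric(n_hom_ref), ln)
  h <- rep_len(as.numeric(n_het), ln)
  b <- rep_len(as.numeric(n_hom_alt), ln)
  vapply(seq_len(ln), function(i) hwe_exact_one(a[i], h[i], b[i]), numeric(1))
}

hwe_exact_one <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0) ||
      any(c(n_hom_ref, n_het, n_hom_alt) != round(c(n_hom_ref, n_het, n_hom_alt)))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotyped individual required")
  m <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)  # minor allele count
  if (m == 0) return(1)

  hets <- seq(m %% 2, m, by = 2)
  # log conditional probability for each possible heterozygote count
  hom_minor <- (m - hets) / 2
  hom_major <- n - hets - hom_minor
  lp <- lfactorial(n) - lfactorial(hom_major) - lfactorial(hets) -
    lfactorial(hom_minor) + hets * log(2) +
    lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  # normalize in log space for numerical stability
  lp <- lp - max(lp)
  prob <- exp(lp)
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  p <- sum(prob[prob <= obs * (1 + 1e-7)])
  min(p, 1)
}
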