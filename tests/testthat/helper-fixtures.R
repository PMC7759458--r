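# Fixtures are built in code at test time; nothing binary is stored.

# Write a small plain-text VCF; `gt` is a character matrix
# (records x samples), `alt` may contain comma-separated alleles.
write_vcf_fixture <- function(path, chrom, pos, ref, alt, gt,
                              samples = paste0("S", seq_len(ncol(gt))),
                              format = "GT", info = ".") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=A,Type=Float,Description=\"Dosage\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- rep_len(info, length(pos))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", info[i],
            format, gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Build a genotype_matrix directly from an individuals x variants call
# matrix, with optional variant-table overrides.
make_gm <- function(calls, ...) {
  calls <- as.matrix(calls)
  nv <- ncol(calls)
  defaults <- list(chrom = rep("1", nv), pos = seq_len(nv) * 100L,
                   ref = rep("A", nv), alt = rep("T", nv))
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  v <- as.data.frame(defaults, stringsAsFactors = FALSE)
  compute_variant_stats(genotype_matrix(
    calls, v, sprintf("I%04d", seq_len(nrow(calls)))))
}

# ---- independent oracles ---------------------------------------------------

# HWE exact test oracle: multiplicative recurrence over heterozygote
# counts (distinct numeric route from the package's log-gamma formula).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  m <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      hom_minor <- (m - h) / 2
      hom_major <- n - h - hom_minor
      # P(h+2) / P(h) under the conditional distribution
      probs[i + 1] <- probs[i] * 4 * hom_minor * hom_major /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Fisher exact two-sided oracle: explicit enumeration of all tables with
# the observed margins, probabilities via lchoose.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(a, support)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Cox partial log likelihood (Breslow ties) for a single binary covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}
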