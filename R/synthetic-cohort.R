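#' Default MAF-bin imputation accuracy profile
#'
#' Target allele-count R-squared per MAF bin for the simulated imputation
#' channel. The outermost bins reflect the degradation typically seen when
#' imputing rare variants (about 0.32 below 0.01% MAF, about 0.95 above 1%
#' MAF); interior decade bins are interpolated.
#'
#' @return Data frame with columns `lower`, `upper` (half-open MAF bins)
#'   and `r2` (target squared correlation in (0, 1]).
#' @export
default_imputation_noise <- function() {
  data.frame(
    lower = c(0, 1e-4, 1e-3, 1e-2),
    upper = c(1e-4, 1e-3, 1e-2, 0.5),
    r2 = c(0.322, 0.50, 0.70, 0.952)
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' define a cohort with the statistical structure the downstream analyses
#' assume: a heavy-tailed site frequency spectrum (truncated
#' Beta(0.10, 140) on (0, 0.5], giving ~98.6% of variants below 1% MAF),
#' Hardy-Weinberg genotypes, functional classes in roughly the proportions
#' seen in exome cohorts (31% synonymous / 64% missense / 5% LOF among the
#' three classes), two thirds of LOF variants affecting all transcripts,
#' and MAF-graded imputation noise.
#'
#' @param n_individuals,n_genes Cohort dimensions.
#' @param variants_per_gene List with `mean`: variants per gene are
#'   `1 + Poisson(mean - 1)`.
#' @param sfs_shape List with `alpha`, `beta` of the truncated Beta allele
#'   frequency distribution.
#' @param class_proportions Named probabilities over `synonymous`,
#'   `missense`, `lof`; must sum to 1.
#' @param lof_all_fraction Fraction of LOF variants that affect all
#'   transcripts of their gene.
#' @param rare_fraction_target Intended fraction of variants with MAF < 1%;
#'   checked for consistency with `sfs_shape`.
#' @param indel_fraction Fraction of variants simulated as indels.
#' @param imputation_noise MAF-bin R-squared targets, as
#'   [default_imputation_noise()].
#' @param burden_effects Data frame with columns `gene_id`, `trait`,
#'   `type` (`"binary"`/`"quantitative"`), `effect` (log odds ratio or SD
#'   shift) and, for binary traits, `prevalence`.
#' @param clinvar_config List with counts for
#'   [simulate_clinvar_annotations()].
#' @param survival_config List with `baseline_hazard` (events per year),
#'   `hazard_ratio` (carriers vs non-carriers) and `censoring_rate`.
#' @param keep_monomorphic Allow variants with zero minor alleles.
#' @param seed Integer; fixes all generator output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 5000,
                              n_genes = 100,
                              variants_per_gene = list(mean = 8),
                              sfs_shape = list(alpha = 0.10, beta = 140),
                              class_proportions = c(synonymous = 0.31,
                                                    missense = 0.64,
                                                    lof = 0.05),
                              lof_all_fraction = 2 / 3,
                              rare_fraction_target = 0.986,
                              indel_fraction = 0.045,
                              imputation_noise = default_imputation_noise(),
                              burden_effects = NULL,
                              clinvar_config = NULL,
                              survival_config = list(baseline_hazard = 0.001,
                                                     hazard_ratio = 4.31,
                                                     censoring_rate = 0.3),
                              keep_monomorphic = FALSE,
                              seed = 1L) {
  if (n_individuals < 1 || n_genes < 1) stop("counts must be positive")
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  if (any(class_proportions < 0)) stop("class_proportions must be non-negative")
  implied <- stats::pbeta(0.01, sfs_shape$alpha, sfs_shape$beta) /
    stats::pbeta(0.5, sfs_shape$alpha, sfs_shape$beta)
  if (abs(implied - rare_fraction_target) > 0.05) {
    stop(sprintf(paste0("rare_fraction_target %.3f infeasible for sfs_shape ",
                        "(implied rare fraction %.3f)"),
                 rare_fraction_target, implied))
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    variants_per_gene = variants_per_gene, sfs_shape = sfs_shape,
    class_proportions = class_proportions,
    lof_all_fraction = lof_all_fraction,
    rare_fraction_target = rare_fraction_target,
    indel_fraction = indel_fraction,
    imputation_noise = imputation_noise, burden_effects = burden_effects,
    clinvar_config = clinvar_config, survival_config = survival_config,
    keep_monomorphic = keep_monomorphic, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Draw allele frequencies from the truncated Beta SFS.
draw_allele_frequencies <- function(n, sfs_shape) {
  u <- stats::runif(n) * stats::pbeta(0.5, sfs_shape$alpha, sfs_shape$beta)
  stats::qbeta(u, sfs_shape$alpha, sfs_shape$beta)
}

#' Simulate a sequenced cohort
#'
#' Draws per-variant allele frequencies from the configured truncated-Beta
#' site frequency spectrum, genotypes under Hardy-Weinberg at the drawn
#' frequency, functional classes from `class_proportions`, and a
#' transcript-level annotation table consistent with the assigned classes
#' (LOF variants receive LOF consequences on all transcripts with
#' probability `lof_all_fraction`, otherwise on a proper subset). Unless
#' `keep_monomorphic`, a variant whose genotype draw is monomorphic is
#' redrawn (up to 50 attempts, i.e. conditioned on polymorphism); if the
#' frequency is too small for rejection to succeed, a single heterozygote
#' is planted, which approximates the polymorphism-conditional
#' distribution when `2nf << 1`.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulated_cohort` with elements `genotypes` (a
#'   [genotype_matrix()] with stats filled), `annotation` (long
#'   variant-transcript consequence table), `genes` (gene table with
#'   transcript counts) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_individuals
  individuals <- sprintf("IND%06d", seq_len(n))

  n_var_gene <- 1L + stats::rpois(config$n_genes,
                                  max(config$variants_per_gene$mean - 1, 0))
  genes <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
    chrom = as.character(sample(1:22, config$n_genes, replace = TRUE)),
    n_transcripts = sample(1:3, config$n_genes, replace = TRUE),
    n_variants = n_var_gene,
    stringsAsFactors = FALSE
  )
  n_var <- sum(n_var_gene)
  gene_of <- rep(seq_len(config$n_genes), n_var_gene)

  f <- draw_allele_frequencies(n_var, config$sfs_shape)
  cls <- sample(names(config$class_proportions), n_var, replace = TRUE,
                prob = config$class_proportions)
  ntx <- genes$n_transcripts[gene_of]
  # single-transcript genes force any-transcript LOF == all-transcript LOF
  lof_all <- cls == "lof" &
    (stats::runif(n_var) < config$lof_all_fraction | ntx == 1L)
  is_indel <- stats::runif(n_var) < config$indel_fraction
  # frameshift indels are LOF by definition; keep indel status consistent
  is_indel[cls == "lof" & is_indel] <- TRUE

  # Hardy-Weinberg genotypes: draw the total alternate-allele count A per
  # variant (zero-truncated binomial unless monomorphic sites are kept),
  # then place the A alleles uniformly among the 2n chromosomes -- the
  # exact allele-count-conditional law under random mating.
  two_n <- 2L * n
  if (config$keep_monomorphic) {
    A <- stats::rbinom(n_var, two_n, f)
  } else {
    p0 <- stats::pbinom(0, two_n, f)
    A <- stats::qbinom(p0 + stats::runif(n_var) * (1 - p0), two_n, f)
    # when 2nf is so small that (1 - p0) underflows, the quantile above is
    # meaningless; conditional on polymorphism such a variant is a single
    # allele copy to any realistic precision
    tiny <- p0 > 1 - 1e-9
    A[tiny] <- 1L
  }
  calls <- matrix(0L, nrow = n, ncol = n_var)
  for (j in seq_len(n_var)) {
    if (A[j] == 0L) next
    slots <- sample.int(two_n, A[j])
    calls[, j] <- tabulate((slots + 1L) %/% 2L, nbins = n)
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(seq_len(n_var), function(j) {
    a <- sample(setdiff(bases, ref[j]), 1L)
    if (is_indel[j]) paste0(ref[j], a) else a
  }, character(1))
  # non-overlapping per-gene windows within each chromosome keep the
  # (chrom, pos, ref, alt) keys unique and positions within integer range
  gene_rank <- stats::ave(seq_len(config$n_genes), genes$chrom,
                          FUN = seq_along)
  pos <- stats::ave(seq_len(n_var), gene_of,
                    FUN = function(ix) {
                      g <- gene_of[ix[1L]]
                      sort(sample.int(5e5, length(ix))) +
                        6e5 * (gene_rank[g] - 1)
                    })
  variants <- data.frame(
    chrom = genes$chrom[gene_of], pos = as.integer(pos), ref = ref, alt = alt,
    gene_id = genes$gene_id[gene_of],
    functional_class = cls,
    lof_any_transcript = cls == "lof",
    lof_all_transcripts = lof_all,
    true_frequency = f,
    is_indel = is_indel, is_multiallelic_site = FALSE,
    stringsAsFactors = FALSE
  )
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)

  annotation <- simulate_annotation(variants, genes, gene_of)
  gm <- compute_variant_stats(genotype_matrix(calls, variants, individuals))
  structure(list(genotypes = gm, annotation = annotation, genes = genes,
                 config = config),
            class = "simulated_cohort")
}

# Transcript-level consequence rows consistent with the assigned classes:
# a LOF variant gets its LOF term on all transcripts (all-transcript flag)
# or on a proper subset, non-LOF classes get their term on every transcript.
simulate_annotation <- function(variants, genes, gene_of) {
  lof_terms <- c("stop_gained", "frameshift_variant",
                 "splice_acceptor_variant", "splice_donor_variant",
                 "start_lost")
  n_var <- nrow(variants)
  ntx <- genes$n_transcripts[gene_of]
  cls <- variants$functional_class

  term <- character(n_var)
  term[cls == "synonymous"] <- "synonymous_variant"
  term[cls == "missense"] <- "missense_variant"
  lof_idx <- which(cls == "lof")
  term[lof_idx] <- ifelse(variants$is_indel[lof_idx], "frameshift_variant",
                          sample(lof_terms, length(lof_idx), replace = TRUE))
  # number of transcripts carrying the LOF term
  k_lof <- ntx
  part <- lof_idx[!variants$lof_all_transcripts[lof_idx]]
  k_lof[part] <- vapply(ntx[part] - 1L,
                        function(m) sample.int(m, 1L), integer(1))

  tx_index <- sequence(ntx)
  row_var <- rep(seq_len(n_var), ntx)
  cons <- term[row_var]
  cons[cls[row_var] == "lof" & tx_index > k_lof[row_var]] <-
    "synonymous_variant"
  data.frame(
    variant_id = variants$variant_id[row_var],
    transcript_id = sprintf("%s.T%d", variants$gene_id[row_var], tx_index),
    consequence = cons,
    stringsAsFactors = FALSE
  )
}

#' Simulate imputed dosages with MAF-graded accuracy
#'
#' Emulates the decline of imputation accuracy at rare frequencies through
#' a shrinkage/permutation channel: for a variant in a MAF bin with target
#' R-squared `r`, the dosage is `(1 - lambda) g + lambda g*`, where `g*`
#' is the variant's own genotype vector with individuals permuted and
#' `lambda = t / (1 + t)` with `t = sqrt((1 - r) / r)`. Since `g*` has
#' exactly the in-sample genotype distribution, the realized allele-count
#' R-squared is `r` per bin across the whole frequency range; dosages stay
#' in \[0, 2\] without clipping, and `r = 1` reduces to `dosage == call`
#' (R-squared 1).
#'
#' @param gm A [genotype_matrix()] of true hard calls.
#' @param imputation_noise Bin table as [default_imputation_noise()].
#' @param seed Integer seed.
#' @return A dosage matrix (see [genotype_matrix()]) with the same variant
#'   table.
#' @export
simulate_imputed_dosages <- function(gm,
                                     imputation_noise = default_imputation_noise(),
                                     seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(imputation_noise$r2 <= 0 | imputation_noise$r2 > 1)) {
    stop("bin R-squared targets must lie in (0, 1]")
  }
  if (anyNA(gm$variants$maf)) gm <- compute_variant_stats(gm)
  maf <- gm$variants$maf
  bin <- findInterval(maf, imputation_noise$lower, rightmost.closed = FALSE)
  if (any(bin < 1 | bin > nrow(imputation_noise))) {
    stop("noise scale undefined for some MAF values")
  }
  r2 <- imputation_noise$r2[bin]
  lam <- sqrt((1 - r2) / r2) / (1 + sqrt((1 - r2) / r2))

  set.seed(derive_seed(seed, "dosages"))
  n <- length(gm$individuals)
  dos <- matrix(NA_real_, n, ncol(gm$calls))
  for (j in seq_len(ncol(dos))) {
    g <- gm$calls[, j]
    # the contaminant is the true genotype vector with individuals
    # permuted: it has exactly the in-sample genotype distribution, so
    # the realized per-variant R-squared matches the bin target across
    # the whole frequency range (an independent binomial redraw is over-
    # or under-dispersed for singleton-scale variants)
    gstar <- g[sample.int(n)]
    dos[, j] <- (1 - lam[j]) * g + lam[j] * gstar
  }
  genotype_matrix(dos, gm$variants, gm$individuals, dosage = TRUE)
}

# Per-gene qualifying-LOF carrier indicator used by the phenotype and
# survival generators (mirrors the default burden mask rule).
gene_carrier_indicator <- function(gm, gene, tier = "lof_any_transcript",
                                   maf_cutoff = 0.01) {
  v <- gm$variants
  q <- which(v$gene_id %in% gene & v[[tier]] %in% TRUE & v$maf < maf_cutoff)
  if (length(q) == 0L) return(rep(0L, length(gm$individuals)))
  as.integer(rowSums(gm$calls[, q, drop = FALSE] >= 1L, na.rm = TRUE) >= 1L)
}

#' Simulate phenotypes with planted gene-burden effects
#'
#' Binary traits are drawn from a logistic model whose intercept targets
#' the configured prevalence, with the gene's qualifying-LOF carrier
#' indicator entering at the configured log odds ratio; quantitative
#' traits are standard normal plus the configured carrier shift in SD
#' units. Covariates (age, sex, and principal-component stand-ins) are
#' generated and enter both trait types with small configurable
#' coefficients.
#'
#' @param gm A [genotype_matrix()] with `maf` filled.
#' @param burden_effects Data frame with columns `gene_id`, `trait`, `type`
#'   (`"binary"`/`"quantitative"`), `effect` (log OR or SD shift) and
#'   `prevalence` (binary traits). Traits listed with `gene_id = NA` (or a
#'   gene with no qualifying variant) are pure-noise traits.
#' @param covariate_model List with `age_mean`, `age_sd`, `female_prob`,
#'   `n_pcs`, `age_beta`, `sex_beta` (used on both scales).
#' @param seed Integer seed.
#' @return A [phenotype_table()] with covariates `age`, `sex`,
#'   `PC1..PCk`.
#' @export
simulate_phenotypes <- function(gm, burden_effects,
                                covariate_model = list(age_mean = 58,
                                                       age_sd = 8,
                                                       female_prob = 0.545,
                                                       n_pcs = 4,
                                                       age_beta = 0.01,
                                                       sex_beta = 0.05),
                                seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  be <- as.data.frame(burden_effects, stringsAsFactors = FALSE)
  if (nrow(be) == 0L) stop("burden_effects must declare at least one trait")
  if (!all(c("gene_id", "trait", "type", "effect") %in% names(be))) {
    stop("burden_effects needs columns gene_id, trait, type, effect")
  }
  known_genes <- unique(gm$variants$gene_id)
  ref_genes <- stats::na.omit(unique(be$gene_id))
  if (length(setdiff(ref_genes, known_genes))) {
    stop("burden effect references unknown gene: ",
         setdiff(ref_genes, known_genes)[1L])
  }
  if (any(be$type == "binary")) {
    prev <- be$prevalence[be$type == "binary"]
    if (any(is.na(prev)) || any(prev <= 0 | prev >= 1)) {
      stop("binary traits need a prevalence in (0, 1)")
    }
  }
  set.seed(derive_seed(seed, "phenotypes"))
  n <- length(gm$individuals)
  cm <- covariate_model
  age <- stats::rnorm(n, cm$age_mean, cm$age_sd)
  sex <- stats::rbinom(n, 1L, cm$female_prob)  # 1 = female
  pcs <- matrix(stats::rnorm(n * cm$n_pcs), n,
                dimnames = list(NULL, paste0("PC", seq_len(cm$n_pcs))))
  age_z <- (age - mean(age)) / stats::sd(age)

  binary <- list(); quant <- list()
  for (i in seq_len(nrow(be))) {
    carrier <- if (is.na(be$gene_id[i])) rep(0L, n) else {
      gene_carrier_indicator(gm, be$gene_id[i])
    }
    covpart <- cm$age_beta * age_z + cm$sex_beta * (sex - mean(sex))
    if (be$type[i] == "binary") {
      eta <- stats::qlogis(be$prevalence[i]) + be$effect[i] * carrier + covpart
      binary[[be$trait[i]]] <- stats::rbinom(n, 1L, stats::plogis(eta))
    } else {
      quant[[be$trait[i]]] <- be$effect[i] * carrier + covpart +
        stats::rnorm(n)
    }
  }
  phenotype_table(
    gm$individuals,
    binary = if (length(binary)) as.data.frame(binary) else NULL,
    quantitative = if (length(quant)) as.data.frame(quant) else NULL,
    covariates = data.frame(age = age, sex = sex, pcs)
  )
}

#' Seed ClinVar-style annotations onto simulated variants
#'
#' Marks exactly the configured numbers of distinct variants as pathogenic
#' with 2 stars and no conflicts, and as pathogenic with conflicting
#' interpretations (1 star); remaining configured slots can mark benign
#' background records.
#'
#' @param variants Variant table of the cohort.
#' @param clinvar_config List with `n_pathogenic_2star`, `n_conflicted`,
#'   optional `n_benign` and `truncating_mechanism_genes` (character
#'   vector of gene ids where truncating variants cause disease).
#' @param seed Integer seed.
#' @return Data frame in the layout of [read_clinvar_table()] output.
#' @export
simulate_clinvar_annotations <- function(variants, clinvar_config, seed = 1L) {
  cc <- clinvar_config
  n_path <- cc$n_pathogenic_2star %||% 0L
  n_conf <- cc$n_conflicted %||% 0L
  n_ben <- cc$n_benign %||% 0L
  total <- n_path + n_conf + n_ben
  if (total > nrow(variants)) {
    stop("configured ", total, " ClinVar records but only ", nrow(variants),
         " variants available")
  }
  set.seed(derive_seed(seed, "clinvar"))
  # pathogenic assertions land on missense/LOF variants (the classes a
  # pathogenic-filter stage can qualify); other categories draw from the rest
  damaging <- which(variants$functional_class %in% c("missense", "lof"))
  if (length(damaging) < n_path + n_conf) {
    stop("configured ", n_path + n_conf, " pathogenic ClinVar records but only ",
         length(damaging), " missense/LOF variants available")
  }
  idx_path <- sample(damaging, n_path + n_conf)
  idx_rest <- sample(setdiff(seq_len(nrow(variants)), idx_path))
  idx <- c(idx_path, idx_rest)
  take <- function(k) {
    out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out
  }
  mk <- function(rows, significance, stars, conflicts) {
    if (length(rows) == 0L) return(NULL)
    v <- variants[rows, , drop = FALSE]
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               variant_id = v$variant_id, gene_id = v$gene_id,
               significance = significance, stars = stars,
               has_conflicts = conflicts,
               truncating_mechanism_gene =
                 v$gene_id %in% (cc$truncating_mechanism_genes %||% character()),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(take(n_path), "pathogenic", 2L, FALSE),
               mk(take(n_conf), "pathogenic", 1L, TRUE),
               mk(take(n_ben), "benign", 2L, FALSE))
  out[order(out$variant_id), , drop = FALSE]
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with hazard `baseline_hazard` for
#' non-carriers and `baseline_hazard * hazard_ratio` for carriers.
#' Censoring is independent exponential with rate chosen so the expected
#' censored fraction in non-carriers equals `censoring_rate`
#' (`censoring_rate = 0` disables censoring).
#'
#' @param carrier_status Logical or 0/1 vector.
#' @param survival_config List with `baseline_hazard`, `hazard_ratio`,
#'   `censoring_rate` (see [simulation_config()]).
#' @param seed Integer seed.
#' @param individuals Optional identifiers (default `IND...`).
#' @return Data frame of class `survival_table` with columns
#'   `individual_id`, `time` (years), `event` (0/1), `carrier`.
#' @export
simulate_survival_outcomes <- function(carrier_status, survival_config,
                                       seed = 1L, individuals = NULL) {
  sc <- survival_config
  if (sc$hazard_ratio <= 0) stop("hazard ratio must be positive")
  if (sc$censoring_rate < 0 || sc$censoring_rate >= 1) {
    stop("censoring rate must lie in [0, 1)")
  }
  carrier <- as.integer(carrier_status)
  n <- length(carrier)
  set.seed(derive_seed(seed, "survival"))
  rate <- sc$baseline_hazard * ifelse(carrier == 1L, sc$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  if (sc$censoring_rate > 0) {
    rate_c <- sc$baseline_hazard * sc$censoring_rate / (1 - sc$censoring_rate)
    t_cens <- stats::rexp(n, rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  out <- data.frame(
    individual_id = individuals %||% sprintf("IND%06d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    carrier = carrier,
    stringsAsFactors = FALSE
  )
  class(out) <- c("survival_table", class(out))
  out
}
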