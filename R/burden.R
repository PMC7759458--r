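#' Collapse a gene's qualifying LOF variants into a burden mask
#'
#' The mask records, per individual, the dominant-coded carrier indicator
#' (1 if at least one qualifying variant carries an alternate allele) and
#' the summed alternate-allele count over qualifying variants. Missing
#' genotypes count as non-carrying for the indicator; the number of
#' missing calls per individual is recorded so a drop-missing sensitivity
#' analysis can be run.
#'
#' @param gm A QC'd [genotype_matrix()] with `maf` filled.
#' @param gene Gene identifier.
#' @param rule A [carrier_rule()] selecting the LOF tier and MAF cutoff.
#' @return Object of class `burden_mask`: `gene_id`, `variant_ids`,
#'   `indicator` (named 0/1 vector), `allele_count`, `n_carriers`,
#'   `n_missing_calls`.
#' @export
collapse_gene_burden <- function(gm, gene, rule = carrier_rule()) {
  v <- gm$variants
  if (!gene %in% v$gene_id) stop("gene '", gene, "' absent from annotation")
  q <- which(v$gene_id == gene & v[[rule$tier]] %in% TRUE &
               !is.na(v$maf) & v$maf < rule$maf_cutoff)
  calls <- gm$calls[, q, drop = FALSE]
  indicator <- as.integer(rowSums(calls >= 1L, na.rm = TRUE) >= 1L)
  names(indicator) <- gm$individuals
  structure(list(
    gene_id = gene,
    variant_ids = v$variant_id[q],
    indicator = indicator,
    allele_count = rowSums(calls, na.rm = TRUE),
    n_carriers = sum(indicator),
    n_missing_calls = as.integer(rowSums(is.na(calls)))
  ), class = "burden_mask")
}

# Assemble response, main exposure and covariate design over the shared
# individuals of a mask/exposure vector and a phenotype table.
assemble_model_data <- function(exposure, phenotypes, trait,
                                covariates = NULL, extra = NULL) {
  ids <- intersect(names(exposure), phenotypes$individuals)
  if (length(ids) == 0L) stop("no shared individuals between mask and phenotypes")
  pidx <- match(ids, phenotypes$individuals)
  if (trait %in% names(phenotypes$binary)) {
    y <- phenotypes$binary[[trait]][pidx]
    type <- "binary"
  } else if (trait %in% names(phenotypes$quantitative)) {
    y <- phenotypes$quantitative[[trait]][pidx]
    type <- "quantitative"
  } else {
    stop("trait '", trait, "' not found in phenotype table")
  }
  covariates <- intersect(covariates %||% character(),
                          names(phenotypes$covariates))
  C <- if (length(covariates)) {
    as.matrix(phenotypes$covariates[pidx, covariates, drop = FALSE])
  } else NULL
  E <- if (!is.null(extra)) as.matrix(extra)[match(ids, rownames(as.matrix(extra))), ,
                                             drop = FALSE] else NULL
  keep <- !is.na(y)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (!is.null(E)) keep <- keep & stats::complete.cases(E)
  list(ids = ids[keep], y = y[keep], type = type,
       x = unname(exposure[ids][keep]),
       C = if (!is.null(C)) C[keep, , drop = FALSE] else NULL,
       E = if (!is.null(E)) E[keep, , drop = FALSE] else NULL)
}

# Shared test engine: Firth logistic for binary traits, OLS (optionally on
# rank-inverse-normal values) for quantitative traits.
run_trait_test <- function(md, transform = "rint", ci = "profile") {
  x <- md$x
  out <- list(effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p = NA_real_, testable = FALSE, n = length(md$y),
              ci_method = "none")
  if (length(unique(x)) < 2L) return(out)  # e.g. zero carriers
  X <- cbind(intercept = 1, exposure = x, md$C, md$E)
  if (md$type == "binary") {
    if (sum(md$y == 1L) < 1L || sum(md$y == 0L) < 1L) return(out)
    fit <- firth_logistic(X, md$y)
    inf <- firth_inference(X, md$y, idx = 2L, fit = fit, ci = ci)
    out <- list(effect = exp(inf$estimate), ci_low = exp(inf$ci_low),
                ci_high = exp(inf$ci_high), p = inf$p, testable = TRUE,
                n = length(md$y), ci_method = inf$ci_method,
                log_effect = inf$estimate, se = inf$se)
  } else {
    y <- if (transform == "rint") rank_inverse_normal(md$y) else md$y
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE]))),
                       error = function(e) NULL)
    if (is.null(XtXinv) || df <= 0) return(out)
    sigma2 <- rss / df
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    b <- unname(fit$coefficients[2L])
    tstat <- b / se
    p <- unname(2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
    z <- stats::qt(0.975, df)
    out <- list(effect = b, ci_low = b - z * se,
                ci_high = b + z * se, p = p, testable = TRUE,
                n = length(y), ci_method = "wald", se = se)
  }
  out
}

#' Gene-burden association test
#'
#' Tests the mask's carrier indicator against one trait. Binary traits use
#' Firth penalized logistic regression ([firth_logistic()]) with a
#' penalized-likelihood-ratio p-value and profile-penalized-likelihood
#' confidence interval (Wald fallback), reporting an odds ratio;
#' quantitative traits use ordinary least squares on the
#' rank-inverse-normal-transformed trait (set `transform = "none"` for the
#' raw scale), reporting the effect in trait SD units.
#'
#' @param mask A [collapse_gene_burden()] mask.
#' @param phenotypes A [phenotype_table()].
#' @param trait Trait name (binary or quantitative column).
#' @param covariates Covariate column names (subset of the phenotype
#'   table's covariate block).
#' @param transform `"rint"` or `"none"` (quantitative traits).
#' @param ci `"profile"`, `"wald"` or `"none"` (binary traits).
#' @param drop_missing Drop individuals with missing qualifying calls
#'   instead of treating them as non-carriers.
#' @return Object of class `association_result` with `gene_id`, `trait`,
#'   `trait_type`, `effect` (OR or beta), `ci_low`, `ci_high`, `p`,
#'   `n_carriers`, `testable`, and (binary) `genotype_counts` in
#'   RR|RA|AA form for cases and controls.
#' @export
burden_association_test <- function(mask, phenotypes, trait,
                                    covariates = NULL, transform = "rint",
                                    ci = "profile", drop_missing = FALSE) {
  stopifnot(inherits(mask, "burden_mask"))
  exposure <- mask$indicator
  if (drop_missing) exposure[mask$n_missing_calls > 0] <- NA_integer_
  exposure <- exposure[!is.na(exposure)]
  md <- assemble_model_data(exposure, phenotypes, trait, covariates)
  res <- run_trait_test(md, transform = transform, ci = ci)
  counts <- NULL
  if (md$type == "binary") {
    ac <- pmin(mask$allele_count[match(md$ids, names(mask$indicator))], 2)
    counts <- list(
      controls = table(factor(ac[md$y == 0L], levels = 0:2,
                              labels = c("RR", "RA", "AA"))),
      cases = table(factor(ac[md$y == 1L], levels = 0:2,
                           labels = c("RR", "RA", "AA")))
    )
  }
  structure(c(list(gene_id = mask$gene_id, trait = trait,
                   trait_type = md$type,
                   n_carriers = sum(md$x >= 1L),
                   genotype_counts = counts), res),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  lab <- if (x$trait_type == "binary") "OR" else "beta"
  cat(sprintf("<association_result> %s x %s (%s)\n", x$gene_id, x$trait,
              x$trait_type))
  if (!x$testable) {
    cat("  untestable (no carriers, or no case/control contrast)\n")
  } else {
    cat(sprintf("  %s = %.3g (95%% CI %.3g-%.3g), p = %s, carriers = %d, n = %d\n",
                lab, x$effect, x$ci_low, x$ci_high, format_pvalue(x$p),
                x$n_carriers, x$n))
  }
  invisible(x)
}

#' Single-variant association tests within a gene
#'
#' Tests each qualifying variant's carrier indicator with the same test
#' family as the burden test. Variants with minor allele count below
#' `mac_min` (default 4) are skipped and listed as untested; the smallest
#' tested p-value is reported as an attribute.
#'
#' @inheritParams burden_association_test
#' @param gm A QC'd [genotype_matrix()].
#' @param gene Gene identifier.
#' @param rule A [carrier_rule()].
#' @param mac_min Minimum minor allele count for testing.
#' @return Data frame (`variant_id`, `mac`, `tested`, `effect`, `ci_low`,
#'   `ci_high`, `p`) with attribute `lowest_p`.
#' @export
single_variant_tests <- function(gm, gene, phenotypes, trait,
                                 covariates = NULL, rule = carrier_rule(),
                                 mac_min = 4L, transform = "rint") {
  v <- gm$variants
  q <- which(v$gene_id == gene & v[[rule$tier]] %in% TRUE &
               !is.na(v$maf) & v$maf < rule$maf_cutoff)
  rows <- lapply(q, function(j) {
    mac <- v$mac[j]
    if (is.na(mac) || mac < mac_min) {
      return(data.frame(variant_id = v$variant_id[j], mac = mac,
                        tested = FALSE, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_))
    }
    exposure <- as.integer(gm$calls[, j] >= 1L)
    exposure[is.na(gm$calls[, j])] <- 0L
    names(exposure) <- gm$individuals
    md <- assemble_model_data(exposure, phenotypes, trait, covariates)
    res <- run_trait_test(md, transform = transform, ci = "wald")
    data.frame(variant_id = v$variant_id[j], mac = mac, tested = res$testable,
               effect = res$effect, ci_low = res$ci_low,
               ci_high = res$ci_high, p = res$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "lowest_p") <- if (any(out$tested)) min(out$p[out$tested]) else NA_real_
  out
}

#' Leave-one-out burden sensitivity analysis
#'
#' Re-collapses the burden without each qualifying variant in turn and
#' re-tests. The association is flagged single-variant-driven when exactly
#' one exclusion raises the p-value above `flag_threshold` while all other
#' exclusions stay below it.
#'
#' @inheritParams single_variant_tests
#' @param flag_threshold P-value above which an exclusion is considered to
#'   have destroyed the signal.
#' @return Data frame (`excluded_variant`, `n_carriers`, `effect`, `p`)
#'   with attributes `full_p` and `single_variant_driven`.
#' @export
leave_one_out_analysis <- function(gm, gene, phenotypes, trait,
                                   covariates = NULL, rule = carrier_rule(),
                                   transform = "rint",
                                   flag_threshold = 1e-4) {
  mask <- collapse_gene_burden(gm, gene, rule)
  if (length(mask$variant_ids) < 2L) {
    stop("leave-one-out needs at least 2 qualifying variants; ",
         "use single_variant_tests() for a single-variant gene")
  }
  full <- burden_association_test(mask, phenotypes, trait, covariates,
                                  transform = transform, ci = "none")
  v <- gm$variants
  rows <- lapply(mask$variant_ids, function(vid) {
    keep <- setdiff(mask$variant_ids, vid)
    cols <- match(keep, v$variant_id)
    calls <- gm$calls[, cols, drop = FALSE]
    indicator <- as.integer(rowSums(calls >= 1L, na.rm = TRUE) >= 1L)
    names(indicator) <- gm$individuals
    md <- assemble_model_data(indicator, phenotypes, trait, covariates)
    res <- run_trait_test(md, transform = transform, ci = "none")
    data.frame(excluded_variant = vid, n_carriers = sum(indicator),
               effect = res$effect, p = res$p)
  })
  out <- do.call(rbind, rows)
  above <- !is.na(out$p) & out$p > flag_threshold
  attr(out, "full_p") <- full$p
  attr(out, "single_variant_driven") <- sum(above) == 1L && all(above | (!is.na(out$p) & out$p <= flag_threshold))
  out
}

#' Forward stepwise selection of contributing variants
#'
#' Forward selection over the gene's qualifying single-variant carrier
#' indicators: at each step the candidate with the smallest conditional
#' p-value below `p_enter` is added. Ties are broken deterministically by
#' (p, then MAC descending, then position); candidates collinear with the
#' selected set are skipped.
#'
#' @inheritParams single_variant_tests
#' @param p_enter Entry threshold; defaults to `0.05 / m` where `m` is the
#'   number of qualifying variants.
#' @return Character vector of selected variant ids, with attribute
#'   `steps` (data frame of the selection path).
#' @export
stepwise_variant_selection <- function(gm, gene, phenotypes, trait,
                                       covariates = NULL,
                                       rule = carrier_rule(),
                                       p_enter = NULL, transform = "rint") {
  v <- gm$variants
  q <- which(v$gene_id == gene & v[[rule$tier]] %in% TRUE &
               !is.na(v$maf) & v$maf < rule$maf_cutoff)
  if (length(q) == 0L) stop("no qualifying variants in gene '", gene, "'")
  if (is.null(p_enter)) p_enter <- 0.05 / length(q)
  ind <- (!is.na(gm$calls[, q, drop = FALSE])) & gm$calls[, q, drop = FALSE] >= 1L
  storage.mode(ind) <- "integer"
  rownames(ind) <- gm$individuals
  colnames(ind) <- v$variant_id[q]
  mac <- v$mac[q]
  pos <- v$pos[q]

  selected <- integer(0)
  steps <- list()
  repeat {
    cand <- setdiff(seq_along(q), selected)
    if (!length(cand)) break
    pvals <- rep(NA_real_, length(cand))
    for (ci_ in seq_along(cand)) {
      j <- cand[ci_]
      sel_mat <- if (length(selected)) ind[, selected, drop = FALSE] else NULL
      # skip candidates collinear with [1, covariates, selected]
      base <- cbind(rep(1, nrow(ind)), sel_mat)
      resid <- stats::lm.fit(base, ind[, j])$residuals
      if (sum(resid^2) < 1e-10) next
      exposure <- stats::setNames(ind[, j], rownames(ind))
      md <- assemble_model_data(exposure, phenotypes, trait, covariates,
                                extra = sel_mat)
      res <- run_trait_test(md, transform = transform, ci = "none")
      pvals[ci_] <- res$p
    }
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= p_enter) break
    best_p <- min(pvals, na.rm = TRUE)
    tied <- cand[!is.na(pvals) & pvals <= best_p * (1 + 1e-9)]
    if (length(tied) > 1L) {
      tied <- tied[order(-mac[tied], pos[tied])]
    }
    pick <- tied[1L]
    selected <- c(selected, pick)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, variant_id = colnames(ind)[pick],
      p = best_p)
  }
  out <- colnames(ind)[selected]
  attr(out, "steps") <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), variant_id = character(), p = numeric())
  attr(out, "p_enter") <- p_enter
  out
}

#' Burden test conditional on known variants
#'
#' Re-tests the burden indicator with the supplied known genotype/dosage
#' vectors as additional covariates, reporting both the unconditional and
#' the conditional p-value. If the burden indicator is collinear with the
#' known set (perfect confounding) the burden term is reported fully
#' attenuated (p = 1) with a `collinear` flag.
#'
#' @inheritParams burden_association_test
#' @param known Matrix of known-variant genotype or dosage columns, rows
#'   named by individual.
#' @return List with `unconditional` and `conditional`
#'   association results and `collinear`.
#' @export
conditional_on_known_variants <- function(mask, phenotypes, trait, known,
                                          covariates = NULL,
                                          transform = "rint") {
  stopifnot(inherits(mask, "burden_mask"))
  uncond <- burden_association_test(mask, phenotypes, trait, covariates,
                                    transform = transform, ci = "none")
  if (is.null(known) || NCOL(known) == 0L) {
    return(list(unconditional = uncond, conditional = uncond,
                collinear = FALSE))
  }
  known <- as.matrix(known)
  if (is.null(rownames(known))) rownames(known) <- names(mask$indicator)
  md <- assemble_model_data(mask$indicator, phenotypes, trait, covariates,
                            extra = known)
  base <- cbind(rep(1, length(md$x)), md$C, md$E)
  resid <- stats::lm.fit(base, md$x)$residuals
  collinear <- sum(resid^2) < 1e-10
  if (collinear) {
    cond <- uncond
    cond$p <- 1
    cond$effect <- NA_real_
    cond$ci_low <- NA_real_
    cond$ci_high <- NA_real_
  } else {
    res <- run_trait_test(md, transform = transform, ci = "none")
    cond <- structure(c(list(gene_id = mask$gene_id, trait = trait,
                             trait_type = md$type,
                             n_carriers = sum(md$x >= 1L),
                             genotype_counts = NULL), res),
                      class = "association_result")
  }
  list(unconditional = uncond, conditional = cond, collinear = collinear)
}

#' Phenome-scan configuration
#'
#' @param min_carriers Genes require at least this many qualifying-LOF
#'   carriers (default 4).
#' @param min_cases Binary traits require at least this many cases
#'   (default 50).
#' @param alpha Exome-wide significance threshold (default 1e-7).
#' @param rule A [carrier_rule()].
#' @param covariates Covariate names used in every test.
#' @param transform Quantitative-trait transform.
#' @param decompose Attach single-variant / leave-one-out / stepwise
#'   decompositions to hits below `alpha`.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(min_carriers = 4L, min_cases = 50L, alpha = 1e-7,
                        rule = carrier_rule(), covariates = NULL,
                        transform = "rint", decompose = TRUE) {
  structure(list(min_carriers = min_carriers, min_cases = min_cases,
                 alpha = alpha, rule = rule, covariates = covariates,
                 transform = transform, decompose = decompose),
            class = "scan_config")
}

#' Gene x trait LOF burden phenome scan
#'
#' Runs the burden test over the Cartesian product of genes and traits
#' after applying the inclusion filters (genes with at least
#' `min_carriers` carriers; binary traits with at least `min_cases`
#' cases). Output ordering is deterministic (genes and traits sorted), so
#' the scan is invariant to input row order. Hits below `alpha` carry
#' their decompositions when `decompose` is set.
#'
#' @param gm A QC'd [genotype_matrix()].
#' @param phenotypes A [phenotype_table()].
#' @param config A [scan_config()].
#' @return Object of class `phenome_scan`: `results` (one row per tested
#'   gene x trait), `decompositions` (named list for hits),
#'   `expected_false_positives` (from [expected_false_positives()]), and
#'   `config`.
#' @export
run_phenome_scan <- function(gm, phenotypes, config = scan_config()) {
  genes <- sort(unique(stats::na.omit(gm$variants$gene_id)))
  masks <- lapply(genes, function(g) collapse_gene_burden(gm, g, config$rule))
  names(masks) <- genes
  keep_gene <- vapply(masks, function(m) m$n_carriers >= config$min_carriers,
                      logical(1))
  masks <- masks[keep_gene]

  btraits <- sort(names(phenotypes$binary))
  btraits <- btraits[vapply(btraits, function(tr) {
    sum(phenotypes$binary[[tr]] == 1L, na.rm = TRUE) >= config$min_cases
  }, logical(1))]
  qtraits <- sort(names(phenotypes$quantitative))
  traits <- c(btraits, qtraits)

  rows <- list()
  for (g in names(masks)) {
    for (tr in traits) {
      res <- burden_association_test(masks[[g]], phenotypes, tr,
                                     covariates = config$covariates,
                                     transform = config$transform,
                                     ci = "none")
      rows[[paste(g, tr, sep = "|")]] <- data.frame(
        gene_id = g, trait = tr, trait_type = res$trait_type,
        effect = res$effect, p = res$p, n_carriers = res$n_carriers,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), trait = character(),
               trait_type = character(), effect = numeric(), p = numeric(),
               n_carriers = integer(), n = integer())
  rownames(results) <- NULL
  results <- results[order(results$gene_id, results$trait), , drop = FALSE]

  decomp <- list()
  hits <- which(!is.na(results$p) & results$p < config$alpha)
  if (config$decompose) {
    for (i in hits) {
      g <- results$gene_id[i]; tr <- results$trait[i]
      mask <- masks[[g]]
      d <- list(
        single_variant = single_variant_tests(gm, g, phenotypes, tr,
                                              config$covariates,
                                              rule = config$rule,
                                              transform = config$transform),
        stepwise = stepwise_variant_selection(gm, g, phenotypes, tr,
                                              config$covariates,
                                              rule = config$rule,
                                              transform = config$transform)
      )
      if (length(mask$variant_ids) >= 2L) {
        d$leave_one_out <- leave_one_out_analysis(gm, g, phenotypes, tr,
                                                  config$covariates,
                                                  rule = config$rule,
                                                  transform = config$transform)
      }
      decomp[[paste(g, tr, sep = "|")]] <- d
    }
  }
  efp <- expected_false_positives(length(masks), length(traits),
                                  config$alpha, observed_hits = length(hits))
  structure(list(results = results, decompositions = decomp,
                 expected_false_positives = efp, config = config),
            class = "phenome_scan")
}

#' @export
print.phenome_scan <- function(x, ...) {
  cat(sprintf("<phenome_scan> %d gene x trait tests; %d hit(s) at p < %g\n",
              nrow(x$results),
              sum(!is.na(x$results$p) & x$results$p < x$config$alpha),
              x$config$alpha))
  cat(sprintf("  expected false positives: %.3g (implied FDR %s)\n",
              x$expected_false_positives$expected,
              ifelse(is.na(x$expected_false_positives$implied_fdr), "NA",
                     sprintf("%.1f%%",
                             100 * x$expected_false_positives$implied_fdr))))
  invisible(x)
}

#' Expected false positives and implied FDR of a scan
#'
#' Naive multiplicity accounting: the expected number of null gene x trait
#' pairs below `alpha` is `n_genes * n_traits * alpha`; the implied false
#' discovery rate divides this by the observed hit count.
#'
#' @param n_genes,n_traits Numbers of genes and traits scanned.
#' @param alpha Significance threshold.
#' @param observed_hits Observed hit count (optional).
#' @return List with `expected`, `observed_hits`, `implied_fdr`
#'   (`NA` with a flag when there are no hits).
#' @export
expected_false_positives <- function(n_genes, n_traits, alpha,
                                     observed_hits = NULL) {
  if (n_genes < 0 || n_traits < 0 || alpha < 0) stop("inputs must be non-negative")
  expected <- n_genes * n_traits * alpha
  fdr <- NA_real_
  undefined <- TRUE
  if (!is.null(observed_hits) && observed_hits > 0) {
    fdr <- expected / observed_hits
    undefined <- FALSE
  }
  list(expected = expected, observed_hits = observed_hits %||% NA_integer_,
       implied_fdr = fdr, fdr_undefined = undefined)
}
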