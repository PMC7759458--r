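#' In-memory cohort model
#'
#' A `genotype_matrix` holds hard calls (alternate-allele counts 0/1/2,
#' `NA` for missing) for `individuals x variants`; a `dosage_matrix` is the
#' same shape with continuous expected alternate-allele counts in \[0, 2\].
#' The companion variant table is a data frame with one row per (split)
#' alternate allele carrying the fields used downstream: `chrom`, `pos`,
#' `ref`, `alt`, `variant_id`, `gene_id`, `functional_class`
#' (`synonymous`/`missense`/`lof`/`other`), `lof_any_transcript`,
#' `lof_all_transcripts`, `maf`, `mac`, `call_rate`, `hwe_p`, `info_score`,
#' `is_indel`, `is_multiallelic_site`.
#'
#' @param calls Integer (or numeric, for dosages) matrix, individuals in
#'   rows, variants in columns. Missing calls are `NA`.
#' @param variants Variant table (data frame) with one row per column of
#'   `calls`; see Details. Missing annotation columns are filled with `NA`.
#' @param individuals Character vector of unique individual identifiers.
#' @param dosage Logical; `TRUE` marks a continuous dosage matrix.
#' @return An object of class `genotype_matrix` (additionally
#'   `dosage_matrix` when `dosage = TRUE`): a list with elements `calls`,
#'   `variants`, `individuals`.
#' @export
genotype_matrix <- function(calls, variants, individuals, dosage = FALSE) {
  calls <- as.matrix(calls)
  if (anyDuplicated(individuals)) {
    stop("duplicated individual identifier: ",
         individuals[duplicated(individuals)][1L])
  }
  if (nrow(calls) != length(individuals)) {
    stop("calls has ", nrow(calls), " rows but ", length(individuals),
         " individual identifiers")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (ncol(calls) != nrow(variants)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(variants),
         " variant records")
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variant table must contain columns ", paste(need, collapse = ", "))
  }
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                       variants$ref, variants$alt)
  }
  nv <- nrow(variants)
  for (col in c("gene_id", "functional_class")) {
    if (!col %in% names(variants)) variants[[col]] <- rep(NA_character_, nv)
  }
  for (col in c("lof_any_transcript", "lof_all_transcripts",
                "is_indel", "is_multiallelic_site")) {
    if (!col %in% names(variants)) variants[[col]] <- rep(FALSE, nv)
  }
  for (col in c("maf", "mac", "call_rate", "hwe_p", "info_score")) {
    if (!col %in% names(variants)) variants[[col]] <- rep(NA_real_, nv)
  }
  if (!dosage) {
    bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
    if (length(bad)) stop("hard calls must be 0, 1, 2 or NA; saw ", bad[1L])
    storage.mode(calls) <- "integer"
  } else {
    if (any(calls < 0 | calls > 2, na.rm = TRUE)) {
      stop("dosages must lie in [0, 2]")
    }
    storage.mode(calls) <- "double"
  }
  rownames(calls) <- individuals
  colnames(calls) <- variants$variant_id
  structure(
    list(calls = calls, variants = variants,
         individuals = as.character(individuals)),
    class = c(if (dosage) "dosage_matrix", "genotype_matrix")
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  kind <- if (inherits(x, "dosage_matrix")) "dosage_matrix" else "genotype_matrix"
  cat(sprintf("<%s> %d individuals x %d variants\n", kind,
              length(x$individuals), nrow(x$variants)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%; genes: %d\n", 100 * miss,
              length(unique(stats::na.omit(x$variants$gene_id)))))
  invisible(x)
}

#' Recompute per-variant sample statistics
#'
#' Fills `maf`, `mac` and `call_rate` in the variant table from the current
#' call matrix. The minor allele is defined within-sample: `maf = min(af,
#' 1 - af)` where `af` is the alternate-allele frequency among non-missing
#' calls, and `mac` is the matching allele count.
#'
#' @param gm A [genotype_matrix()].
#' @return `gm` with updated variant table.
#' @export
compute_variant_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  nonmiss <- colSums(!is.na(gm$calls))
  ac <- colSums(gm$calls, na.rm = TRUE)
  an <- 2 * nonmiss
  af <- ifelse(an > 0, ac / an, NA_real_)
  gm$variants$maf <- pmin(af, 1 - af)
  gm$variants$mac <- as.integer(pmin(ac, an - ac))
  gm$variants$call_rate <- nonmiss / length(gm$individuals)
  gm
}

# Subset a genotype/dosage matrix by individual index/names and/or variant
# column index, keeping calls and variant table in step.
subset_matrix <- function(gm, individuals = NULL, variants = NULL) {
  if (!is.null(individuals)) {
    gm$calls <- gm$calls[individuals, , drop = FALSE]
    gm$individuals <- rownames(gm$calls)
  }
  if (!is.null(variants)) {
    gm$calls <- gm$calls[, variants, drop = FALSE]
    gm$variants <- gm$variants[variants, , drop = FALSE]
    rownames(gm$variants) <- NULL
  }
  gm
}

#' Phenotype and covariate table
#'
#' @param individuals Unique individual identifiers.
#' @param binary Data frame of 0/1/`NA` case-control indicators (may have
#'   zero columns).
#' @param quantitative Data frame of numeric trait values.
#' @param covariates Data frame of numeric covariates (age, sex, principal
#'   components, ...).
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(individuals, binary = NULL, quantitative = NULL,
                            covariates = NULL) {
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) {
    stop("duplicated individual identifier: ",
         individuals[duplicated(individuals)][1L])
  }
  empty <- data.frame(row.names = seq_along(individuals))
  fix <- function(df) {
    if (is.null(df)) return(empty)
    df <- as.data.frame(df)
    if (nrow(df) != length(individuals)) {
      stop("phenotype block rows do not match individual count")
    }
    df
  }
  binary <- fix(binary)
  for (nm in names(binary)) {
    v <- binary[[nm]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("binary trait '", nm, "' contains values other than 0/1/NA")
    }
    binary[[nm]] <- as.integer(v)
  }
  structure(
    list(individuals = individuals, binary = binary,
         quantitative = fix(quantitative), covariates = fix(covariates)),
    class = "phenotype_table"
  )
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d individuals; %d binary, %d quantitative traits, %d covariates\n",
              length(x$individuals), ncol(x$binary), ncol(x$quantitative),
              ncol(x$covariates)))
  invisible(x)
}

#' Intersect genotype and phenotype inputs on individual identifiers
#'
#' Sample matching is by identifier and order-independent; individuals
#' absent from either input are dropped with a message reporting the count.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes A [phenotype_table()].
#' @param quiet Suppress the dropped-individual message.
#' @return List with the aligned `genotypes` and `phenotypes`.
#' @export
align_individuals <- function(gm, phenotypes, quiet = FALSE) {
  shared <- intersect(gm$individuals, phenotypes$individuals)
  dropped <- (length(gm$individuals) - length(shared)) +
    (length(phenotypes$individuals) - length(shared))
  if (dropped > 0 && !quiet) {
    message(dropped, " individual record(s) absent from one input dropped; ",
            length(shared), " individuals retained")
  }
  if (length(shared) == 0L) stop("no shared individuals between inputs")
  idx <- match(shared, phenotypes$individuals)
  ph <- phenotype_table(
    shared,
    binary = phenotypes$binary[idx, , drop = FALSE],
    quantitative = phenotypes$quantitative[idx, , drop = FALSE],
    covariates = phenotypes$covariates[idx, , drop = FALSE]
  )
  list(genotypes = compute_variant_stats(subset_matrix(gm, individuals = shared)),
       phenotypes = ph)
}
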