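#' Quality-control thresholds
#'
#' Defaults follow the standard exome-cohort filters: individual and
#' variant missingness below 10%, Hardy-Weinberg exact p above 1e-15,
#' imputation INFO above 0.3 and a 1% rare-variant MAF cutoff. The
#' missingness and HWE inequalities are strict, so boundary values fail.
#'
#' @param max_missingness Maximum tolerated missingness fraction
#'   (exclusive bound).
#' @param min_hwe_p Minimum HWE exact p-value (exclusive bound).
#' @param min_info Minimum imputation INFO score (exclusive bound).
#' @param maf_rare_cutoff MAF below which a variant counts as rare.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missingness = 0.10, min_hwe_p = 1e-15,
                          min_info = 0.3, maf_rare_cutoff = 0.01) {
  vals <- c(max_missingness, min_hwe_p, min_info, maf_rare_cutoff)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(max_missingness = max_missingness, min_hwe_p = min_hwe_p,
                 min_info = min_info, maf_rare_cutoff = maf_rare_cutoff),
            class = "qc_thresholds")
}

#' Apply variant and individual quality control
#'
#' Individuals with missingness at or above `max_missingness` are dropped
#' first; per-variant statistics (call rate, HWE p) are then recomputed on
#' the retained individuals and variants are kept only if missingness is
#' strictly below `max_missingness` and the HWE exact p strictly above
#' `min_hwe_p`. Variants failing both rules are counted under missingness.
#'
#' @param gm A [genotype_matrix()] of hard calls.
#' @param thresholds A [qc_thresholds()].
#' @return List of class `qc_result`: `matrix` (the filtered
#'   [genotype_matrix()] with refreshed `maf`/`mac`/`call_rate`/`hwe_p`) and
#'   `report` (individuals dropped, variants removed per rule, thresholds).
#' @export
apply_variant_qc <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  if (length(gm$individuals) == 0L || nrow(gm$variants) == 0L) {
    stop("empty genotype matrix")
  }
  ind_miss <- rowMeans(is.na(gm$calls))
  keep_ind <- ind_miss < thresholds$max_missingness
  gm2 <- subset_matrix(gm, individuals = which(keep_ind))
  if (length(gm2$individuals) == 0L) stop("all individuals fail the missingness filter")
  gm2 <- compute_variant_stats(gm2)
  gm2$variants$hwe_p <- compute_hwe_p(gm2)

  # computed directly (not as 1 - call_rate) so the strict boundary
  # comparison is exact for missingness fractions like 10/100
  var_miss <- colSums(is.na(gm2$calls)) / length(gm2$individuals)
  fail_miss <- !(var_miss < thresholds$max_missingness)
  fail_hwe <- !fail_miss & !(gm2$variants$hwe_p > thresholds$min_hwe_p)
  keep_var <- !fail_miss & !fail_hwe
  out <- subset_matrix(gm2, variants = which(keep_var))
  report <- list(
    n_individuals_in = length(gm$individuals),
    n_individuals_dropped = sum(!keep_ind),
    n_variants_in = nrow(gm$variants),
    n_removed_missingness = sum(fail_miss),
    n_removed_hwe = sum(fail_hwe),
    n_variants_retained = sum(keep_var),
    thresholds = thresholds
  )
  structure(list(matrix = out, report = report), class = "qc_result")
}

# Exact HWE p for every variant of a hard-call matrix.
compute_hwe_p <- function(gm) {
  n0 <- colSums(gm$calls == 0L, na.rm = TRUE)
  n1 <- colSums(gm$calls == 1L, na.rm = TRUE)
  n2 <- colSums(gm$calls == 2L, na.rm = TRUE)
  p <- rep(NA_real_, length(n0))
  ok <- (n0 + n1 + n2) >= 1
  p[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
  p
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("<qc_result>\n")
  cat(sprintf("  individuals: %d in, %d dropped (missingness >= %.2g)\n",
              r$n_individuals_in, r$n_individuals_dropped,
              r$thresholds$max_missingness))
  cat(sprintf("  variants: %d in, %d removed by missingness, %d by HWE (p <= %.2g), %d retained\n",
              r$n_variants_in, r$n_removed_missingness, r$n_removed_hwe,
              r$thresholds$min_hwe_p, r$n_variants_retained))
  invisible(x)
}

#' Default consequence vocabulary
#'
#' Maps Sequence Ontology consequence terms to functional classes. The LOF
#' set is the four-category definition: initiation-codon loss, premature
#' stop, essential splice site, frameshift. Users can pass an edited copy
#' to emulate stricter or looser definitions.
#'
#' @return Named list of character vectors (`lof`, `missense`,
#'   `synonymous`).
#' @export
consequence_vocabulary <- function() {
  list(
    lof = c("start_lost", "initiator_codon_variant", "stop_gained",
            "splice_acceptor_variant", "splice_donor_variant",
            "frameshift_variant", "frameshift"),
    missense = c("missense_variant", "missense"),
    synonymous = c("synonymous_variant", "synonymous", "stop_retained_variant")
  )
}

#' Classify one variant's functional class and LOF transcript flags
#'
#' A variant is LOF if any of its per-transcript consequences is in the
#' vocabulary's LOF set (`lof_any_transcript`), and all-transcript LOF if
#' every transcript of the gene carries a LOF consequence
#' (`lof_all_transcripts`). For mixed-transcript variants the class
#' priority is LOF > missense > synonymous; consequences matching no
#' vocabulary entry classify as `"other"` with a warning.
#'
#' @param consequences Data frame with columns `transcript_id` and
#'   `consequence` (one row per transcript annotation of the variant).
#' @param vocabulary A [consequence_vocabulary()] list.
#' @param gene_transcripts Optional character vector of all transcripts of
#'   the gene; defaults to the transcripts present in `consequences`.
#' @return List with `functional_class`, `lof_any_transcript`,
#'   `lof_all_transcripts`.
#' @export
classify_functional_class <- function(consequences,
                                      vocabulary = consequence_vocabulary(),
                                      gene_transcripts = NULL) {
  if (nrow(consequences) == 0L) stop("consequence set must be non-empty")
  term <- consequences$consequence
  known <- unlist(vocabulary, use.names = FALSE)
  if (any(!term %in% known)) {
    warning("unknown consequence term(s): ",
            paste(unique(setdiff(term, known)), collapse = ", "),
            "; contributing transcripts classified as 'other'")
  }
  is_lof <- term %in% vocabulary$lof
  lof_any <- any(is_lof)
  if (is.null(gene_transcripts)) {
    gene_transcripts <- unique(consequences$transcript_id)
  }
  lof_tx <- unique(consequences$transcript_id[is_lof])
  lof_all <- lof_any && all(gene_transcripts %in% lof_tx)
  cls <- if (lof_any) "lof"
  else if (any(term %in% vocabulary$missense)) "missense"
  else if (any(term %in% vocabulary$synonymous)) "synonymous"
  else "other"
  list(functional_class = cls, lof_any_transcript = lof_any,
       lof_all_transcripts = lof_all)
}

#' Classify an annotation table of variants
#'
#' Applies [classify_functional_class()] to every variant of a long-format
#' annotation table and writes `functional_class`, `lof_any_transcript`
#' and `lof_all_transcripts` into a variant table.
#'
#' @param variants Variant table (one row per variant, with `variant_id`).
#' @param annotation Data frame with columns `variant_id`, `transcript_id`,
#'   `consequence` (one row per variant-transcript pair).
#' @param vocabulary A [consequence_vocabulary()] list.
#' @param gene_transcripts Optional named list: gene transcript sets keyed
#'   by `variant_id`.
#' @return `variants` with the three classification columns filled.
#' @export
classify_variants <- function(variants, annotation,
                              vocabulary = consequence_vocabulary(),
                              gene_transcripts = NULL) {
  ann <- split(annotation, annotation$variant_id)
  for (i in seq_len(nrow(variants))) {
    vid <- variants$variant_id[i]
    cons <- ann[[vid]]
    if (is.null(cons)) next
    res <- classify_functional_class(cons, vocabulary,
                                     gene_transcripts[[vid]])
    variants$functional_class[i] <- res$functional_class
    variants$lof_any_transcript[i] <- res$lof_any_transcript
    variants$lof_all_transcripts[i] <- res$lof_all_transcripts
  }
  variants
}

#' Summarize variant counts by type and functional class
#'
#' Produces the per-class tallies of a characterization table: for each
#' class (total, SNV, indel, multiallelic, synonymous, missense, LOF
#' any-transcript, LOF all-transcripts) the number of variants, the number
#' with MAF below `rare_cutoff`, and the per-individual median and IQR of
#' carried variants. Per-individual counting is carrier-style: a variant
#' counts once for an individual with at least one non-missing alternate
#' allele (set `zygosity_weighted = TRUE` to count alleles instead).
#'
#' @param gm A QC'd [genotype_matrix()].
#' @param rare_cutoff MAF cutoff for the rare column (default 0.01).
#' @param zygosity_weighted Count alternate alleles rather than carriers.
#' @return Data frame of class `variant_class_summary`.
#' @export
summarize_variant_counts <- function(gm, rare_cutoff = 0.01,
                                     zygosity_weighted = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  if (anyNA(v$maf)) gm <- compute_variant_stats(gm)
  v <- gm$variants
  classes <- list(
    total = rep(TRUE, nrow(v)),
    snv = !v$is_indel,
    indel = v$is_indel,
    multiallelic = v$is_multiallelic_site,
    synonymous = v$functional_class %in% "synonymous",
    missense = v$functional_class %in% "missense",
    lof_any = v$lof_any_transcript %in% TRUE,
    lof_all = v$lof_all_transcripts %in% TRUE,
    other = v$functional_class %in% "other"
  )
  carried <- if (zygosity_weighted) {
    m <- gm$calls; m[is.na(m)] <- 0L; m
  } else {
    (!is.na(gm$calls)) & gm$calls >= 1L
  }
  rare <- v$maf < rare_cutoff
  rows <- lapply(names(classes), function(cl) {
    sel <- classes[[cl]]
    per_ind <- rowSums(carried[, sel, drop = FALSE])
    per_ind_rare <- rowSums(carried[, sel & rare, drop = FALSE])
    data.frame(
      class = cl,
      n_variants = sum(sel),
      n_rare = sum(sel & rare),
      median_per_individual = stats::median(per_ind),
      iqr_per_individual = stats::IQR(per_ind),
      median_per_individual_rare = stats::median(per_ind_rare),
      iqr_per_individual_rare = stats::IQR(per_ind_rare),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_class_summary", class(out))
  out
}

#' Compare variant yield between sequenced and imputed call sets
#'
#' Filters the imputed set to `info_score` strictly above `min_info`, then
#' reports per-class variant counts in each set, the fold increase
#' (sequenced / imputed) and the fraction of sequenced variants present in
#' the imputed set (matched on the (chrom, pos, ref, alt) key).
#'
#' @param wes_variants Variant table of the sequenced call set.
#' @param imputed_variants Variant table of the imputed call set (with
#'   `info_score`).
#' @param thresholds A [qc_thresholds()] (uses `min_info`).
#' @return Data frame of class `yield_report` with attributes
#'   `overlap_fraction` and `n_imputed_filtered`.
#' @export
compare_wes_imputed_yield <- function(wes_variants, imputed_variants,
                                      thresholds = qc_thresholds()) {
  keep <- is.na(imputed_variants$info_score) |
    imputed_variants$info_score > thresholds$min_info
  keep[is.na(imputed_variants$info_score)] <- FALSE
  imp <- imputed_variants[keep, , drop = FALSE]
  count_classes <- function(v) {
    c(total = nrow(v),
      snv = sum(!v$is_indel),
      indel = sum(v$is_indel),
      synonymous = sum(v$functional_class %in% "synonymous"),
      missense = sum(v$functional_class %in% "missense"),
      lof_any = sum(v$lof_any_transcript %in% TRUE),
      lof_all = sum(v$lof_all_transcripts %in% TRUE))
  }
  wes_n <- count_classes(wes_variants)
  imp_n <- count_classes(imp)
  out <- data.frame(
    class = names(wes_n),
    n_wes = as.integer(wes_n),
    n_imputed = as.integer(imp_n),
    fold_increase = ifelse(imp_n > 0, wes_n / imp_n, NA_real_),
    stringsAsFactors = FALSE
  )
  overlap <- if (nrow(wes_variants)) {
    mean(wes_variants$variant_id %in% imp$variant_id)
  } else NA_real_
  attr(out, "overlap_fraction") <- overlap
  attr(out, "n_imputed_filtered") <- sum(!keep)
  class(out) <- c("yield_report", class(out))
  out
}
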