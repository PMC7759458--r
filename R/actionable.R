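#' Actionable gene set
#'
#' A medically actionable gene panel (for example a 59-gene secondary
#' findings set): per-gene inheritance mode and a flag for genes in which
#' truncating variants are an established disease mechanism.
#'
#' @param gene_id Gene identifiers.
#' @param inheritance One of `"dominant"`, `"recessive"`, `"x_linked"` per
#'   gene.
#' @param truncating_mechanism Logical per gene.
#' @return Data frame of class `actionable_gene_set`.
#' @export
actionable_gene_set <- function(gene_id, inheritance, truncating_mechanism) {
  inheritance <- rep_len(inheritance, length(gene_id))
  truncating_mechanism <- rep_len(truncating_mechanism, length(gene_id))
  if (!all(inheritance %in% c("dominant", "recessive", "x_linked"))) {
    stop("inheritance must be dominant, recessive or x_linked")
  }
  if (anyNA(truncating_mechanism)) {
    stop("truncating_mechanism flag must be assigned for every gene")
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    inheritance = inheritance,
                    truncating_mechanism = as.logical(truncating_mechanism),
                    stringsAsFactors = FALSE)
  class(out) <- c("actionable_gene_set", class(out))
  out
}

#' Select strictly reported-pathogenic variants
#'
#' The 'strict' rule: ClinVar significance pathogenic, at least two review
#' stars, no conflicting interpretations, gene in the actionable set, and
#' functional class missense or LOF.
#'
#' @param clinvar ClinVar records ([read_clinvar_table()] layout).
#' @param variants Variant table providing `functional_class` per
#'   `variant_id`.
#' @param gene_set An [actionable_gene_set()].
#' @return Data frame of selected variants with `selection_reason =
#'   "reported_pathogenic"`.
#' @export
select_reported_pathogenic <- function(clinvar, variants, gene_set) {
  idx <- match(clinvar$variant_id, variants$variant_id)
  cls <- variants$functional_class[idx]
  is_lof <- variants$lof_any_transcript[idx] %in% TRUE
  sel <- clinvar$significance == "pathogenic" &
    clinvar$stars >= 2L &
    !clinvar$has_conflicts &
    clinvar$gene_id %in% gene_set$gene_id &
    (cls %in% "missense" | cls %in% "lof" | is_lof)
  out <- clinvar[which(sel), , drop = FALSE]
  out$selection_reason <- rep("reported_pathogenic", nrow(out))
  rownames(out) <- NULL
  out
}

#' Select likely-pathogenic LOF variants
#'
#' Rare LOF variants (any transcript) in genes for which truncating
#' variants are an established disease mechanism, excluding variants
#' already selected as reported pathogenic (precedence:
#' `reported_pathogenic`).
#'
#' @param variants Variant table with `lof_any_transcript`, `maf`,
#'   `gene_id`.
#' @param gene_set An [actionable_gene_set()].
#' @param already_selected Character vector of variant ids selected by
#'   [select_reported_pathogenic()].
#' @param maf_cutoff Rare-frequency cutoff (default 0.001).
#' @return Data frame of selected variants with `selection_reason =
#'   "likely_pathogenic_lof"`.
#' @export
select_likely_pathogenic_lof <- function(variants, gene_set,
                                         already_selected = character(),
                                         maf_cutoff = 0.001) {
  mech_genes <- gene_set$gene_id[gene_set$truncating_mechanism]
  sel <- variants$lof_any_transcript %in% TRUE &
    variants$gene_id %in% mech_genes &
    !is.na(variants$maf) & variants$maf < maf_cutoff &
    !(variants$variant_id %in% already_selected)
  out <- variants[which(sel),
                  c("chrom", "pos", "ref", "alt", "variant_id", "gene_id"),
                  drop = FALSE]
  out$selection_reason <- rep("likely_pathogenic_lof", nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize carriers of actionable pathogenic variants
#'
#' Given the selected variant set and the genotype matrix, reports the
#' distinct-carrier count and prevalence (an individual counts once even
#' with variants in several genes), per-gene variant and carrier counts
#' with zero-carrier panel genes included in the medians, the number of
#' individuals with variants in two or more genes, and the zygosity
#' breakdown (het / hom / hemizygous; hemizygosity requires reported male
#' sex and an X-chromosome variant). Heterozygous carriers of
#' recessive-mode genes are reported but flagged as not actionable-affected.
#'
#' @param selected Selected variant data frame (rows from
#'   [select_reported_pathogenic()] / [select_likely_pathogenic_lof()]).
#' @param gm A [genotype_matrix()].
#' @param gene_set An [actionable_gene_set()].
#' @param sex Optional per-individual sex (`"male"`/`"female"`, or 1 =
#'   female / 0 = male), aligned with `gm$individuals`.
#' @param n_total Denominator for prevalence (default: cohort size).
#' @return List of class `actionable_summary`.
#' @export
actionable_carrier_summary <- function(selected, gm, gene_set, sex = NULL,
                                       n_total = NULL) {
  n_total <- n_total %||% length(gm$individuals)
  male <- if (is.null(sex)) rep(FALSE, length(gm$individuals)) else {
    if (is.numeric(sex)) sex == 0 else tolower(as.character(sex)) == "male"
  }
  cols <- match(selected$variant_id, gm$variants$variant_id)
  ok <- !is.na(cols)
  sel <- selected[ok, , drop = FALSE]
  cols <- cols[ok]
  calls <- gm$calls[, cols, drop = FALSE]
  is_x <- gm$variants$chrom[cols] %in% c("X", "chrX", "23")

  carrier_any <- rowSums(calls >= 1L, na.rm = TRUE) >= 1L
  n_carriers <- sum(carrier_any)

  carrier_records <- NULL
  if (nrow(sel)) {
    hit <- which(!is.na(calls) & calls >= 1L, arr.ind = TRUE)
    if (nrow(hit)) {
      gcall <- calls[hit]
      zyg <- ifelse(gcall == 2L, "hom",
                    ifelse(is_x[hit[, 2L]] & male[hit[, 1L]], "hemi", "het"))
      gene <- sel$gene_id[hit[, 2L]]
      mode <- gene_set$inheritance[match(gene, gene_set$gene_id)]
      carrier_records <- data.frame(
        individual_id = gm$individuals[hit[, 1L]],
        variant_id = sel$variant_id[hit[, 2L]],
        gene_id = gene, zygosity = zyg, inheritance = mode,
        actionable_affected = (mode %in% c("dominant") & zyg %in% c("het", "hom")) |
          (mode == "recessive" & zyg == "hom") |
          (mode == "x_linked" & zyg %in% c("hemi", "hom")),
        stringsAsFactors = FALSE
      )
    }
  }

  per_gene <- data.frame(gene_id = gene_set$gene_id, stringsAsFactors = FALSE)
  per_gene$n_variants <- vapply(per_gene$gene_id, function(g) {
    sum(sel$gene_id == g)
  }, integer(1))
  per_gene$n_carriers <- vapply(per_gene$gene_id, function(g) {
    cc <- which(sel$gene_id == g)
    if (!length(cc)) return(0L)
    sum(rowSums(calls[, cc, drop = FALSE] >= 1L, na.rm = TRUE) >= 1L)
  }, integer(1))

  genes_per_ind <- if (!is.null(carrier_records)) {
    tapply(carrier_records$gene_id, carrier_records$individual_id,
           function(g) length(unique(g)))
  } else integer(0)

  structure(list(
    n_total = n_total,
    n_carriers = n_carriers,
    prevalence = n_carriers / n_total,
    n_multi_gene_carriers = sum(genes_per_ind >= 2),
    per_gene = per_gene,
    median_variants_per_gene = stats::median(per_gene$n_variants),
    median_carriers_per_gene = stats::median(per_gene$n_carriers),
    zygosity = if (!is.null(carrier_records)) {
      table(carrier_records$zygosity)
    } else table(character()),
    carrier_records = carrier_records
  ), class = "actionable_summary")
}

#' @export
print.actionable_summary <- function(x, ...) {
  cat(sprintf("<actionable_summary> %d distinct carriers / %d individuals (%.1f%%)\n",
              x$n_carriers, x$n_total, 100 * x$prevalence))
  cat(sprintf("  per-gene medians (zero-carrier genes included): %g variants, %g carriers\n",
              x$median_variants_per_gene, x$median_carriers_per_gene))
  cat(sprintf("  individuals with variants in >= 2 genes: %d\n",
              x$n_multi_gene_carriers))
  invisible(x)
}
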