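#' Read genotypes or dosages from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) and returns a
#' [genotype_matrix()] (FORMAT field `GT`) or dosage matrix (FORMAT field
#' `DS`). Multiallelic records are split into one variant record per
#' alternate allele, flagged `is_multiallelic_site`; for a split allele the
#' call is the number of chromosomes carrying that allele, so splitting
#' conserves the total alternate-allele count of the site. `./.` (or `.`)
#' maps to missing.
#'
#' @param path Path to the VCF.
#' @param field `"GT"` for hard calls or `"DS"` for imputed dosages.
#' @param info_key INFO key holding the imputation quality score
#'   (default `"INFO"`); stored as `info_score` when present.
#' @return A [genotype_matrix()] or dosage matrix with per-variant `maf`,
#'   `mac` and `call_rate` filled in.
#' @export
read_genotype_vcf <- function(path, field = c("GT", "DS"), info_key = "INFO") {
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  fmt <- vcf@gt[, 1L]
  if (!any(vapply(strsplit(fmt, ":"), function(f) field %in% f, logical(1)))) {
    stop("FORMAT field '", field, "' not present in VCF")
  }
  raw <- vcfR::extract.gt(vcf, element = field)  # variants x samples
  samples <- colnames(vcf@gt)[-1L]
  info <- suppressWarnings(vcfR::extract.info(vcf, element = info_key,
                                              as.numeric = TRUE))

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_row <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))

  n_samp <- length(samples)
  calls <- matrix(NA_real_, nrow = n_samp, ncol = length(rec_row))

  if (field == "GT") {
    for (i in seq_len(nrow(fix))) {
      toks <- strsplit(raw[i, ], "[/|]")
      cols <- which(rec_row == i)
      for (s in seq_len(n_samp)) {
        tk <- toks[[s]]
        if (is.null(tk) || length(tk) == 0L || any(is.na(tk)) || all(tk == ".")) next
        if (any(tk == ".")) next  # partial call treated as missing
        suppressWarnings(al <- as.integer(tk))
        if (any(is.na(al))) {
          stop("malformed GT token '", raw[i, s], "' at VCF record ", i)
        }
        for (j in seq_along(cols)) {
          calls[s, cols[j]] <- sum(al == alt_idx[cols[j]])
        }
      }
    }
  } else {
    for (i in seq_len(nrow(fix))) {
      parts <- strsplit(raw[i, ], ",", fixed = TRUE)
      cols <- which(rec_row == i)
      for (s in seq_len(n_samp)) {
        pk <- parts[[s]]
        if (is.null(pk) || length(pk) == 0L || any(is.na(pk)) || all(pk == ".")) next
        suppressWarnings(ds <- as.numeric(pk))
        if (any(is.na(ds))) {
          stop("malformed DS token '", raw[i, s], "' at VCF record ", i)
        }
        for (j in seq_along(cols)) {
          calls[s, cols[j]] <- ds[min(j, length(ds))]
        }
      }
    }
  }

  ref <- fix$REF[rec_row]
  alt <- unlist(alt_list)
  variants <- data.frame(
    chrom = fix$CHROM[rec_row],
    pos = as.integer(fix$POS[rec_row]),
    ref = ref, alt = alt,
    is_indel = nchar(ref) != nchar(alt),
    is_multiallelic_site = n_alt[rec_row] > 1L,
    info_score = if (all(is.na(info))) NA_real_ else as.numeric(info)[rec_row],
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, variants, samples, dosage = (field == "DS"))
  compute_variant_stats(gm)
}

#' Write hard calls to a VCF file
#'
#' Serializes a biallelic [genotype_matrix()] back to VCF (one record per
#' variant, GT field; written bgzipped when `path` ends in `.gz`).
#' Round-trips exactly through [read_genotype_vcf()].
#'
#' @param gm A [genotype_matrix()] of hard calls.
#' @param path Output path (`.vcf.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"), !inherits(gm, "dosage_matrix"))
  v <- gm$variants
  fix <- cbind(CHROM = as.character(v$chrom), POS = as.character(v$pos),
               ID = v$variant_id, REF = v$ref, ALT = v$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_body <- apply(gm$calls, 1L, function(cc) {
    out <- code[as.character(cc)]
    out[is.na(cc)] <- "./."
    out
  })
  gt_body <- matrix(gt_body, nrow = nrow(v),
                    dimnames = list(NULL, gm$individuals))
  gt <- cbind(FORMAT = "GT", gt_body)
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#'
#' The file must be tab-separated with a header; every non-identifier
#' column must be declared in `trait_dictionary` as `"binary"`,
#' `"quantitative"` or `"covariate"`. Unparseable numeric cells (including
#' `"NA"` in binary columns) become missing, with one warning reporting the
#' total count.
#'
#' @param path Path to the TSV.
#' @param trait_dictionary Named character vector mapping column names to
#'   `"binary"`, `"quantitative"` or `"covariate"`.
#' @param id_col Name of the individual-identifier column (default: first
#'   column of the file).
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, trait_dictionary, id_col = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (is.null(id_col)) id_col <- names(df)[1L]
  undeclared <- setdiff(names(df), c(id_col, names(trait_dictionary)))
  if (length(undeclared)) {
    stop("column(s) not declared in trait dictionary: ",
         paste(undeclared, collapse = ", "))
  }
  bad <- trait_dictionary[!trait_dictionary %in%
                            c("binary", "quantitative", "covariate")]
  if (length(bad)) stop("unknown trait type '", bad[1L], "'")
  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicated individual identifier: ", ids[duplicated(ids)][1L])
  }
  n_bad <- 0L
  parse_num <- function(x) {
    y <- suppressWarnings(as.numeric(x))
    n_bad <<- n_bad + sum(!is.na(x) & x != "" & x != "NA" & is.na(y))
    y
  }
  pick <- function(type) {
    cols <- names(trait_dictionary)[trait_dictionary == type]
    cols <- intersect(cols, names(df))
    out <- as.data.frame(lapply(df[cols], parse_num))
    names(out) <- cols
    out
  }
  binary <- pick("binary")
  for (nm in names(binary)) {
    v <- binary[[nm]]
    v[!is.na(v) & !(v %in% c(0, 1))] <- NA  # anything not 0/1 is missing
    binary[[nm]] <- v
  }
  quantitative <- pick("quantitative")
  covariates <- pick("covariate")
  if (n_bad > 0L) warning(n_bad, " unparseable numeric cell(s) set to missing")
  phenotype_table(ids, binary = binary, quantitative = quantitative,
                  covariates = covariates)
}

#' ClinVar review-status to star-rating lookup
#'
#' The public 0-4 star convention: no assertion = 0; single submitter or
#' conflicting interpretations = 1; multiple concordant submitters = 2;
#' expert panel = 3; practice guideline = 4.
#'
#' @return Named integer vector mapping review-status strings to stars.
#' @export
clinvar_star_map <- function() {
  c("no_assertion_provided" = 0L,
    "no_assertion_criteria_provided" = 0L,
    "no_interpretation_for_the_single_variant" = 0L,
    "criteria_provided,_single_submitter" = 1L,
    "criteria_provided,_conflicting_interpretations" = 1L,
    "criteria_provided,_multiple_submitters,_no_conflicts" = 2L,
    "reviewed_by_expert_panel" = 3L,
    "practice_guideline" = 4L)
}

#' Read a ClinVar-style annotation TSV
#'
#' Expected columns: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#' `significance`, `review_status`; optional `truncating_mechanism_gene`.
#' Review-status strings are mapped to star integers via `star_map`
#' (default [clinvar_star_map()], overridable); `has_conflicts` is true for
#' statuses mentioning conflicting interpretations. Rows with an unknown
#' significance term are skipped with a warning.
#'
#' @param path Path to the TSV.
#' @param star_map Named integer vector overriding [clinvar_star_map()].
#' @return Data frame of ClinVar records with `variant_id`, normalized
#'   `significance` (`pathogenic`, `likely_pathogenic`, `vus`,
#'   `likely_benign`, `benign`), `stars`, `has_conflicts`.
#' @export
read_clinvar_table <- function(path, star_map = clinvar_star_map()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene_id", "significance",
            "review_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ClinVar table missing column(s): ",
                         paste(miss, collapse = ", "))
  sig_map <- c(pathogenic = "pathogenic",
               likely_pathogenic = "likely_pathogenic",
               uncertain_significance = "vus", vus = "vus",
               likely_benign = "likely_benign", benign = "benign")
  sig_key <- gsub(" ", "_", tolower(df$significance))
  known <- sig_key %in% names(sig_map)
  if (any(!known)) {
    warning(sum(!known), " record(s) with unknown significance term skipped (e.g. '",
            df$significance[!known][1L], "')")
  }
  df <- df[known, , drop = FALSE]
  sig_key <- sig_key[known]
  status <- df$review_status
  stars <- unname(star_map[status])
  if (anyNA(stars)) {
    warning(sum(is.na(stars)), " unrecognized review-status string(s); stars set to 0")
    stars[is.na(stars)] <- 0L
  }
  data.frame(
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
    variant_id = variant_key(df$chrom, as.integer(df$pos), df$ref, df$alt),
    gene_id = df$gene_id,
    significance = unname(sig_map[sig_key]),
    stars = as.integer(stars),
    has_conflicts = grepl("conflicting", status, ignore.case = TRUE),
    truncating_mechanism_gene =
      if ("truncating_mechanism_gene" %in% names(df))
        as.logical(df$truncating_mechanism_gene) else NA,
    stringsAsFactors = FALSE
  )
}

#' Write a results table as TSV or JSON
#'
#' Column order is preserved as given (deterministic). Floating values are
#' serialized with 10 significant digits; p-value columns (named `p` or
#' ending in `_p`/`p_value`) follow the 2-significant-digit policy, e.g.
#' `3.2e-08`. The TSV round-trips losslessly at the serialized precision.
#'
#' @param results A data frame (any of the pipeline's tabular results).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  is_p <- grepl("(^|_)p(_value)?$", names(results))
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      digits <- if (is_p[j]) 2L else 10L
      out[[j]] <- ifelse(is.na(results[[j]]), NA_character_,
                         formatC(results[[j]], digits = digits, format = "g"))
    }
  }
  ok <- tryCatch({
    if (format == "tsv") {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", na = "string")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
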