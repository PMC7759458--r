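test_that("missingness filters are strict at the printed boundary", {
  set.seed(31)
  n <- 100
  # enough clean background variants that no individual crosses 10%
  calls <- matrix(rbinom(n * 63, 2, 0.3), n, 63)
  calls[1:11, 1] <- NA  # missingness 0.11 -> removed
  calls[1:10, 2] <- NA  # missingness 0.10 exactly -> removed (strict <)
  calls[1:9, 3] <- NA   # missingness 0.09 -> retained
  gm <- make_gm(calls)
  qc <- apply_variant_qc(gm)
  expect_identical(qc$report$n_individuals_dropped, 0L)
  kept <- qc$matrix$variants$variant_id
  expect_false(gm$variants$variant_id[1] %in% kept)
  expect_false(gm$variants$variant_id[2] %in% kept)
  expect_true(all(gm$variants$variant_id[3:4] %in% kept))
  expect_identical(qc$report$n_removed_missingness, 2L)
})

test_that("the HWE inequality is strict: p equal to the threshold fails", {
  set.seed(32)
  n <- 60
  calls <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  calls[, 1] <- rep(1L, n)  # all-het column: extreme HWE violation
  gm <- make_gm(calls)
  p_allhet <- hwe_exact_test(0, n, 0)
  # threshold exactly at the variant's p: strict ">" removes it
  qc_eq <- apply_variant_qc(gm, qc_thresholds(min_hwe_p = p_allhet))
  expect_false(gm$variants$variant_id[1] %in% qc_eq$matrix$variants$variant_id)
  # threshold just below: retained
  qc_lo <- apply_variant_qc(gm, qc_thresholds(min_hwe_p = p_allhet * 0.999))
  expect_true(gm$variants$variant_id[1] %in% qc_lo$matrix$variants$variant_id)
})

test_that("the QC report counts removals per rule on a constructed fixture", {
  set.seed(33)
  n <- 200L
  calls <- matrix(rbinom(n * 30, 2, 0.25), n, 30)
  calls[1:40, 1] <- NA            # missingness violation
  calls[1:25, 2] <- NA            # missingness violation
  calls[, 3] <- rep(1L, n)        # HWE violation (p ~ 1e-59)
  gm <- make_gm(calls)
  qc <- apply_variant_qc(gm)
  expect_identical(qc$report$n_removed_missingness, 2L)
  expect_identical(qc$report$n_removed_hwe, 1L)
  expect_identical(qc$report$n_variants_retained, 27L)
  expect_identical(nrow(qc$matrix$variants), 27L)

  # individuals failing missingness are dropped before variant filters
  calls2 <- calls
  calls2[5, ] <- NA
  qc2 <- apply_variant_qc(make_gm(calls2))
  expect_identical(qc2$report$n_individuals_dropped, 1L)
  expect_identical(length(qc2$matrix$individuals), n - 1L)

  # QC is idempotent
  qc3 <- apply_variant_qc(qc$matrix)
  expect_identical(qc3$report$n_removed_missingness, 0L)
  expect_identical(qc3$report$n_removed_hwe, 0L)
  expect_identical(qc3$matrix$variants$variant_id, qc$matrix$variants$variant_id)

  expect_error(apply_variant_qc(make_gm(matrix(integer(), 0, 0))), "empty")
})

test_that("functional classification honours the LOF definition and transcript tiers", {
  cons <- data.frame(transcript_id = c("T1", "T2", "T3"),
                     consequence = c("stop_gained", "synonymous_variant",
                                     "synonymous_variant"))
  r <- classify_functional_class(cons)
  expect_identical(r$functional_class, "lof")
  expect_true(r$lof_any_transcript)
  expect_false(r$lof_all_transcripts)

  cons2 <- data.frame(transcript_id = c("T1", "T2"),
                      consequence = c("frameshift_variant", "frameshift_variant"))
  r2 <- classify_functional_class(cons2)
  expect_true(r2$lof_all_transcripts)

  # class priority LOF > missense > synonymous for mixed annotations
  cons3 <- data.frame(transcript_id = c("T1", "T2"),
                      consequence = c("missense_variant", "synonymous_variant"))
  expect_identical(classify_functional_class(cons3)$functional_class, "missense")

  # unknown term classifies as other with a warning
  cons4 <- data.frame(transcript_id = "T1", consequence = "intergalactic")
  expect_warning(r4 <- classify_functional_class(cons4), "unknown consequence")
  expect_identical(r4$functional_class, "other")
  expect_error(classify_functional_class(cons4[0, ]), "non-empty")
})

test_that("lof_all implies lof_any over generated cohorts and the 2/3 tier ratio holds", {
  cfg <- simulation_config(n_individuals = 200, n_genes = 600,
                           class_proportions = c(synonymous = 0.2,
                                                 missense = 0.2, lof = 0.6),
                           seed = 34)
  coh <- simulate_cohort(cfg)
  v <- coh$genotypes$variants
  expect_true(all(v$lof_any_transcript[v$lof_all_transcripts]))
  cl <- classify_variants(v, coh$annotation)
  expect_true(all(cl$lof_any_transcript[cl$lof_all_transcripts]))
  expect_identical(cl$lof_all_transcripts, v$lof_all_transcripts)
  # configured all-transcript fraction is 2/3 (plus forced single-transcript
  # genes); the all-/any-transcript tally ratio reflects it
  ratio <- sum(v$lof_all_transcripts) / sum(v$lof_any_transcript)
  expect_gt(ratio, 0.60)
  expect_lt(ratio, 0.85)
})

test_that("variant class summaries partition and respect rare <= total", {
  calls <- matrix(c(1L, 1L, 1L), nrow = 1)
  gm <- make_gm(calls)
  gm$variants$functional_class <- "synonymous"
  s <- summarize_variant_counts(gm)
  expect_identical(s$n_variants[s$class == "synonymous"], 3L)
  expect_identical(s$median_per_individual[s$class == "synonymous"], 3)

  coh <- simulate_cohort(simulation_config(n_individuals = 150,
                                           n_genes = 80, seed = 35))
  s2 <- summarize_variant_counts(coh$genotypes)
  tot <- s2$n_variants[s2$class == "total"]
  parts <- s2$n_variants[s2$class %in% c("synonymous", "missense",
                                         "lof_any", "other")]
  expect_identical(sum(parts), tot)
  expect_true(all(s2$n_rare <= s2$n_variants))
  # independent recount of the rare fraction
  v <- coh$genotypes$variants
  expect_identical(s2$n_rare[s2$class == "missense"],
                   sum(v$functional_class == "missense" & v$maf < 0.01))
})

test_that("yield comparison applies the strict INFO filter and reports folds", {
  wes <- data.frame(variant_id = paste0("v", 1:6),
                    functional_class = c("lof", "lof", "missense",
                                         "missense", "synonymous", "synonymous"),
                    lof_any_transcript = c(TRUE, TRUE, rep(FALSE, 4)),
                    lof_all_transcripts = FALSE,
                    is_indel = FALSE, info_score = NA_real_)
  imp <- wes[c(1, 3, 5), ]
  imp$info_score <- c(0.9, 0.3, 0.8)  # 0.3 exactly -> excluded (strict >)
  y <- compare_wes_imputed_yield(wes, imp)
  expect_identical(y$n_imputed[y$class == "missense"], 0L)
  expect_identical(y$n_imputed[y$class == "lof_any"], 1L)
  expect_equal(y$fold_increase[y$class == "lof_any"], 2)
  expect_equal(attr(y, "overlap_fraction"), 2 / 6)

  # identical sets: all folds 1, overlap 100%
  imp2 <- wes
  imp2$info_score <- 1
  y2 <- compare_wes_imputed_yield(wes, imp2)
  expect_true(all(y2$fold_increase[y2$n_imputed > 0] == 1))
  expect_equal(attr(y2, "overlap_fraction"), 1)
})
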