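# A small helper: genotype matrix with planted LOF variants in one gene
# plus named carrier sets, used across the burden tests.
plant_burden_gm <- function(n, carrier_sets, maf = NULL) {
  nv <- length(carrier_sets)
  calls <- matrix(0L, n, nv)
  for (j in seq_len(nv)) calls[carrier_sets[[j]], j] <- 1L
  make_gm(calls, gene_id = rep("G1", nv),
          lof_any_transcript = TRUE, lof_all_transcripts = FALSE)
}

test_that("burden masks apply the carrier definition and the MAF cutoff", {
  n <- 2000
  gm <- plant_burden_gm(n, list(1:5, 3:10, 1:300))
  # variant 3 has MAF 7.5% and must not qualify
  expect_gt(gm$variants$maf[3], 0.01)
  mask <- collapse_gene_burden(gm, "G1")
  expect_identical(sort(mask$variant_ids),
                   sort(gm$variants$variant_id[1:2]))
  expect_identical(mask$n_carriers, 10L)
  expect_identical(unname(mask$indicator[1]), 1L)
  expect_identical(unname(mask$indicator[11]), 0L)
  expect_error(collapse_gene_burden(gm, "NOPE"), "absent")

  # planted fixture with 164 carriers is recovered exactly
  gm2 <- plant_burden_gm(46000, list(1:100, 101:164))
  expect_identical(collapse_gene_burden(gm2, "G1")$n_carriers, 164L)
})

test_that("missing genotypes count as non-carriers unless dropped", {
  calls <- matrix(c(1L, NA, 0L, 0L), 4, 1)
  gm <- make_gm(calls, gene_id = "G1", lof_any_transcript = TRUE)
  mask <- collapse_gene_burden(gm, "G1", carrier_rule(maf_cutoff = 0.51))
  expect_identical(unname(mask$indicator), c(1L, 0L, 0L, 0L))
  expect_identical(unname(mask$n_missing_calls), c(0L, 1L, 0L, 0L))
})

test_that("the Firth burden estimate tracks the sample odds ratio on 2x2 data", {
  # genotype-count fixture: cases 1,266 non-carriers / 20 carriers;
  # controls 43,189 / 142 (covariate-free)
  carrier <- c(rep(1L, 20 + 142), rep(0L, 1266 + 43189))
  y <- c(rep(1L, 20), rep(0L, 142), rep(1L, 1266), rep(0L, 43189))
  n <- length(y)
  gm <- make_gm(matrix(carrier, ncol = 1), gene_id = "G1",
                lof_any_transcript = TRUE)
  ph <- phenotype_table(gm$individuals, binary = data.frame(vv = y))
  mask <- collapse_gene_burden(gm, "G1")
  res <- burden_association_test(mask, ph, "vv")
  sample_or <- (20 * 43189) / (1266 * 142)
  expect_equal(sample_or, 4.805, tolerance = 1e-3)
  expect_lt(abs(res$effect / sample_or - 1), 0.10)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)
  expect_lt(res$p, 1e-6)
  # genotype-count breakdown reproduces the construction
  expect_identical(as.integer(res$genotype_counts$cases),
                   c(1266L, 20L, 0L))
  expect_identical(as.integer(res$genotype_counts$controls),
                   c(43189L, 142L, 0L))
})

test_that("a noiseless quantitative shift is recovered exactly in untransformed mode", {
  n <- 400
  gm <- plant_burden_gm(n, list(1:3, 4:6))
  carrier <- exocohort:::gene_carrier_indicator(gm, "G1")
  ph <- phenotype_table(gm$individuals,
                        quantitative = data.frame(q = -1.5 * carrier))
  mask <- collapse_gene_burden(gm, "G1")
  res <- burden_association_test(mask, ph, "q", transform = "none")
  expect_equal(res$effect, -1.5, tolerance = 1e-10)
})

test_that("zero-carrier masks are untestable, never a crash", {
  gm <- plant_burden_gm(100, list(1:4))
  gm$variants$lof_any_transcript <- FALSE
  ph <- phenotype_table(gm$individuals,
                        binary = data.frame(t = rbinom(100, 1, 0.3)))
  mask <- collapse_gene_burden(gm, "G1")
  expect_identical(mask$n_carriers, 0L)
  res <- burden_association_test(mask, ph, "t")
  expect_false(res$testable)
  expect_true(is.na(res$p))
})

test_that("single-variant tests respect the MAC threshold and the burden pattern", {
  set.seed(81)
  n <- 4000
  sets <- list(1:8, 9:16, 17:24, 25:26)  # last variant has MAC 2 < 4
  gm <- plant_burden_gm(n, sets)
  carrier <- exocohort:::gene_carrier_indicator(gm, "G1")
  y <- 0.9 * carrier + rnorm(n)
  ph <- phenotype_table(gm$individuals, quantitative = data.frame(q = y))
  sv <- single_variant_tests(gm, "G1", ph, "q")
  expect_identical(sv$tested, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(is.na(sv$p[4]))
  # a burden spread over several variants beats every single variant
  mask <- collapse_gene_burden(gm, "G1")
  burden <- burden_association_test(mask, ph, "q")
  expect_lt(burden$p, attr(sv, "lowest_p"))

  # single-causal-variant fixture: lowest single-variant p ~ burden p
  gm1 <- plant_burden_gm(n, list(1:20, 21:22))
  c1 <- as.integer(gm1$calls[, 1] >= 1)
  y1 <- 1.2 * c1 + rnorm(n)
  ph1 <- phenotype_table(gm1$individuals, quantitative = data.frame(q = y1))
  sv1 <- single_variant_tests(gm1, "G1", ph1, "q")
  b1 <- burden_association_test(collapse_gene_burden(gm1, "G1"), ph1, "q")
  expect_lt(abs(log10(attr(sv1, "lowest_p")) - log10(b1$p)), 2)
})

test_that("leave-one-out distinguishes distributed from single-variant signals", {
  set.seed(82)
  n <- 5000
  # distributed: three variants with similar carrier counts all carry signal
  gm <- plant_burden_gm(n, list(1:15, 16:30, 31:45))
  carrier <- exocohort:::gene_carrier_indicator(gm, "G1")
  ph <- phenotype_table(gm$individuals,
                        quantitative = data.frame(q = 1.6 * carrier + rnorm(n)))
  loo <- leave_one_out_analysis(gm, "G1", ph, "q", flag_threshold = 1e-4)
  expect_false(attr(loo, "single_variant_driven"))
  expect_true(all(loo$p < 1e-4))

  # concentrated: one of five variants carries the whole signal
  gm2 <- plant_burden_gm(n, list(1:30, 31:33, 34:36, 37:39, 40:42))
  c2 <- as.integer(gm2$calls[, 1] >= 1)
  ph2 <- phenotype_table(gm2$individuals,
                         quantitative = data.frame(q = 1.6 * c2 + rnorm(n)))
  loo2 <- leave_one_out_analysis(gm2, "G1", ph2, "q", flag_threshold = 1e-4)
  expect_true(attr(loo2, "single_variant_driven"))
  drop1 <- loo2$excluded_variant[loo2$p > 1e-4]
  expect_identical(drop1, gm2$variants$variant_id[1])
})

test_that("excluding a zero-carrier variant is an exact no-op", {
  set.seed(83)
  n <- 800
  calls <- cbind(rbinom(n, 1, 0.02), rbinom(n, 1, 0.02), 0L)
  gm <- make_gm(calls, gene_id = rep("G1", 3), lof_any_transcript = TRUE)
  ph <- phenotype_table(gm$individuals,
                        quantitative = data.frame(q = rnorm(n)))
  loo <- leave_one_out_analysis(gm, "G1", ph, "q")
  full <- burden_association_test(collapse_gene_burden(gm, "G1"), ph, "q")
  zero_row <- which(loo$excluded_variant == gm$variants$variant_id[3])
  expect_identical(loo$p[zero_row], full$p)
  expect_identical(loo$effect[zero_row], full$effect)

  gm1 <- make_gm(calls[, 1, drop = FALSE], gene_id = "G1",
                 lof_any_transcript = TRUE)
  expect_error(leave_one_out_analysis(gm1, "G1", ph, "q"),
               "single_variant_tests")
})

test_that("stepwise selection finds planted contributors and breaks ties deterministically", {
  set.seed(84)
  n <- 6000
  gm <- plant_burden_gm(n, list(1:25, 26:50, 51:75, 76:100, 101:125))
  x <- gm$calls >= 1
  y <- 1.2 * x[, 1] + 1.2 * x[, 3] + 1.2 * x[, 5] + rnorm(n)
  ph <- phenotype_table(gm$individuals, quantitative = data.frame(q = y))
  sel <- stepwise_variant_selection(gm, "G1", ph, "q")
  expect_identical(sort(unclass(sel)[1:3]),
                   sort(gm$variants$variant_id[c(1, 3, 5)]))
  expect_identical(length(sel), 3L)

  # null phenotype: empty selection (p_enter Bonferroni-scaled)
  ph0 <- phenotype_table(gm$individuals, quantitative = data.frame(q = rnorm(n)))
  sel0 <- stepwise_variant_selection(gm, "G1", ph0, "q")
  expect_identical(length(sel0), 0L)

  # a perfectly duplicated causal variant: exactly one of the pair selected,
  # tie broken by position (equal p, equal MAC)
  gm2 <- plant_burden_gm(n, list(1:40, 1:40))
  y2 <- 1.0 * (gm2$calls[, 1] >= 1) + rnorm(n)
  ph2 <- phenotype_table(gm2$individuals, quantitative = data.frame(q = y2))
  sel2 <- stepwise_variant_selection(gm2, "G1", ph2, "q")
  expect_identical(unclass(sel2)[1], gm2$variants$variant_id[1])
  expect_identical(length(sel2), 1L)
})

test_that("conditional analysis attenuates exactly under perfect confounding", {
  set.seed(85)
  n <- 3000
  gm <- plant_burden_gm(n, list(1:25))
  x <- as.integer(gm$calls[, 1] >= 1)
  y <- 1.3 * x + rnorm(n)
  ph <- phenotype_table(gm$individuals, quantitative = data.frame(q = y))
  mask <- collapse_gene_burden(gm, "G1")

  # empty known set: conditional equals unconditional
  r0 <- conditional_on_known_variants(mask, ph, "q", known = NULL)
  expect_identical(r0$conditional$p, r0$unconditional$p)

  # known variant identical to the only mask variant: fully attenuated
  known <- matrix(x, dimnames = list(gm$individuals, "rsX"))
  r1 <- conditional_on_known_variants(mask, ph, "q", known = known)
  expect_true(r1$collinear)
  expect_equal(r1$conditional$p, 1)

  # an independent common known variant barely moves the burden p
  set.seed(86)
  known2 <- matrix(rbinom(n, 2, 0.3), dimnames = list(gm$individuals, "rsY"))
  r2 <- conditional_on_known_variants(mask, ph, "q", known = known2)
  expect_false(r2$collinear)
  expect_lt(abs(log10(r2$conditional$p) - log10(r2$unconditional$p)), 1)
})

test_that("expected-false-positive accounting matches the arithmetic", {
  e <- expected_false_positives(16219, 1730, 1e-7, observed_hits = 26)
  expect_equal(e$expected, 16219 * 1730 * 1e-7, tolerance = 1e-12)
  expect_equal(e$expected, 2.806, tolerance = 0.001)
  # the printed "around 2.5" against 26 hits implies an FDR near 10%
  e2 <- expected_false_positives(1, 1, 2.5, observed_hits = 26)
  expect_equal(e2$implied_fdr, 2.5 / 26, tolerance = 1e-12)
  expect_equal(round(100 * e2$implied_fdr, 1), 9.6)
  expect_identical(expected_false_positives(10, 10, 0)$expected, 0)
  e3 <- expected_false_positives(10, 10, 0.01, observed_hits = 0)
  expect_true(e3$fdr_undefined)
})

test_that("the phenome scan filters, orders and decomposes deterministically", {
  set.seed(87)
  n <- 3000
  # G1: planted effect, 20 carriers; G2: exactly 3 carriers (excluded);
  # G3: null gene with carriers
  calls <- cbind(c(rep(1L, 20), rep(0L, n - 20)),
                 c(rep(1L, 3), rep(0L, n - 3)),
                 rbinom(n, 1, 0.004))
  gm <- make_gm(calls, gene_id = c("G1", "G2", "G3"),
                lof_any_transcript = TRUE)
  carrier <- as.integer(calls[, 1] >= 1)
  q <- 2.5 * carrier + rnorm(n)
  bin50 <- integer(n); bin50[sample.int(n, 50)] <- 1L   # exactly 50 cases
  bin49 <- integer(n); bin49[sample.int(n, 49)] <- 1L   # 49 cases: skipped
  ph <- phenotype_table(gm$individuals,
                        binary = data.frame(t50 = bin50, t49 = bin49),
                        quantitative = data.frame(q = q))
  scan <- run_phenome_scan(gm, ph, scan_config(alpha = 1e-7))
  expect_false("G2" %in% scan$results$gene_id)    # < 4 carriers
  expect_false("t49" %in% scan$results$trait)     # < 50 cases
  expect_true(all(c("t50", "q") %in% scan$results$trait))
  hit <- scan$results[scan$results$p < 1e-7 & !is.na(scan$results$p), ]
  expect_identical(hit$gene_id, "G1")
  expect_identical(hit$trait, "q")
  expect_true("G1|q" %in% names(scan$decompositions))

  # row-order invariance: permuting variants leaves results identical
  perm <- c(3, 1, 2)
  gmp <- make_gm(calls[, perm], gene_id = c("G1", "G2", "G3")[perm],
                 lof_any_transcript = TRUE)
  scanp <- run_phenome_scan(gmp, ph, scan_config(alpha = 1e-7))
  expect_equal(scanp$results, scan$results)
})
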