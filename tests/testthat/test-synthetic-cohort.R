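test_that("the generator is a pure function of its config", {
  cfg <- simulation_config(n_individuals = 120, n_genes = 25, seed = 41)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$annotation, b$annotation)
  da <- simulate_imputed_dosages(a$genotypes, seed = 41)
  db <- simulate_imputed_dosages(b$genotypes, seed = 41)
  expect_identical(da$calls, db$calls)
  dc <- simulate_imputed_dosages(a$genotypes, seed = 42)
  expect_false(identical(da$calls, dc$calls))
})

test_that("no monomorphic variants are emitted unless configured", {
  coh <- simulate_cohort(simulation_config(n_individuals = 80, n_genes = 60,
                                           seed = 43))
  expect_true(all(coh$genotypes$variants$mac >= 1L))
  coh2 <- simulate_cohort(simulation_config(n_individuals = 80, n_genes = 60,
                                            keep_monomorphic = TRUE, seed = 43))
  expect_true(any(coh2$genotypes$variants$mac == 0L))
})

test_that("an infeasible rare-fraction target is a configuration error", {
  expect_error(simulation_config(sfs_shape = list(alpha = 2, beta = 2)),
               "infeasible")
  expect_error(simulation_config(class_proportions = c(synonymous = 0.5,
                                                       missense = 0.5,
                                                       lof = 0.5)),
               "sum to 1")
})

test_that("in-sample MAF converges to the drawn frequency as n grows", {
  cfg <- simulation_config(n_individuals = 30000, n_genes = 4, seed = 44)
  coh <- simulate_cohort(cfg)
  v <- coh$genotypes$variants
  common <- v$true_frequency > 0.001
  af_in <- pmin(v$maf, 1 - v$maf)
  expect_true(any(common))
  expect_lt(max(abs(v$maf[common] - pmin(v$true_frequency, 1 - v$true_frequency)[common]) /
                  pmin(v$true_frequency, 1 - v$true_frequency)[common]), 0.35)
})

test_that("HWE exact p-values are null-uniform for common variants", {
  implied <- pbeta(0.01, 2, 8) / pbeta(0.5, 2, 8)
  cfg <- simulation_config(n_individuals = 1500, n_genes = 150,
                           sfs_shape = list(alpha = 2, beta = 8),
                           rare_fraction_target = implied, seed = 45)
  gm <- simulate_cohort(cfg)$genotypes
  keep <- gm$variants$mac >= 30
  p <- exocohort:::compute_hwe_p(gm)[keep]
  expect_gt(length(p), 500)
  # discreteness keeps the exact test slightly conservative; the p
  # distribution must still be close to uniform
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p), 0.62)
})

test_that("zero imputation noise reproduces the calls with R-squared 1", {
  coh <- simulate_cohort(simulation_config(n_individuals = 100, n_genes = 30,
                                           seed = 46))
  noise <- default_imputation_noise()
  noise$r2 <- 1
  dos <- simulate_imputed_dosages(coh$genotypes, noise, seed = 46)
  expect_equal(unname(dos$calls), unname(coh$genotypes$calls) + 0)
  r2 <- allele_count_r2(coh$genotypes$calls, dos$calls)
  expect_equal(r2[!is.na(r2)], rep(1, sum(!is.na(r2))), tolerance = 1e-12)
  noise$r2 <- -0.1
  expect_error(simulate_imputed_dosages(coh$genotypes, noise), "\\(0, 1\\]")
})

test_that("null phenotypes show no carrier-non-carrier contrast", {
  coh <- simulate_cohort(simulation_config(n_individuals = 4000, n_genes = 40,
                                           seed = 47))
  gm <- coh$genotypes
  g <- gm$variants$gene_id[which(gm$variants$lof_any_transcript)[1]]
  be <- data.frame(gene_id = NA_character_, trait = "null_trait",
                   type = "binary", effect = 0, prevalence = 0.2)
  ph <- simulate_phenotypes(gm, be, seed = 47)
  carrier <- exocohort:::gene_carrier_indicator(gm, g)
  rate_c <- mean(ph$binary$null_trait[carrier == 1])
  rate_n <- mean(ph$binary$null_trait[carrier == 0])
  se <- sqrt(0.2 * 0.8 * (1 / max(sum(carrier), 1) + 1 / sum(carrier == 0)))
  expect_lt(abs(rate_c - rate_n), 4 * se + 0.05)
  expect_error(simulate_phenotypes(gm, data.frame(gene_id = "NOPE",
                                                  trait = "t", type = "binary",
                                                  effect = 1, prevalence = 0.5)),
               "unknown gene")
  expect_error(simulate_phenotypes(gm, data.frame(gene_id = NA, trait = "t",
                                                  type = "binary", effect = 0,
                                                  prevalence = 1.2)),
               "prevalence")
})

test_that("ClinVar seeding plants exactly the configured categories", {
  coh <- simulate_cohort(simulation_config(n_individuals = 60, n_genes = 40,
                                           seed = 48))
  v <- coh$genotypes$variants
  cv <- simulate_clinvar_annotations(v, list(n_pathogenic_2star = 10,
                                             n_conflicted = 5), seed = 48)
  expect_identical(sum(cv$significance == "pathogenic" & cv$stars >= 2L &
                         !cv$has_conflicts), 10L)
  expect_identical(sum(cv$has_conflicts), 5L)
  expect_false(anyDuplicated(cv$variant_id) > 0)
  expect_error(simulate_clinvar_annotations(v[1:5, ],
                                            list(n_pathogenic_2star = 10)),
               "only 5 variants")
})

test_that("survival outcomes honour censoring and reproducibility", {
  sc <- list(baseline_hazard = 0.002, hazard_ratio = 4, censoring_rate = 0)
  st <- simulate_survival_outcomes(rep(c(1, 0), c(50, 450)), sc, seed = 49)
  expect_true(all(st$event == 1L))  # censoring rate 0: all events
  expect_true(all(st$time >= 0))
  sc$censoring_rate <- 0.4
  st2 <- simulate_survival_outcomes(rep(c(1, 0), c(50, 450)), sc, seed = 49)
  st3 <- simulate_survival_outcomes(rep(c(1, 0), c(50, 450)), sc, seed = 49)
  expect_identical(st2, st3)
  expect_true(mean(st2$event[st2$carrier == 0]) < 1)
  expect_error(simulate_survival_outcomes(1, list(baseline_hazard = 1,
                                                  hazard_ratio = -1,
                                                  censoring_rate = 0)),
               "positive")
})

test_that("a null hazard ratio gives uniform log-rank p-values across seeds", {
  sc <- list(baseline_hazard = 0.01, hazard_ratio = 1, censoring_rate = 0.2)
  ps <- vapply(1:40, function(s) {
    st <- simulate_survival_outcomes(rep(c(1, 0), c(100, 400)), sc, seed = s)
    sd <- survival::survdiff(survival::Surv(time, event) ~ carrier, data = st)
    1 - pchisq(sd$chisq, 1)
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.2)
})
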