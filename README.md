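# exocohort

Characterization of rare coding variation in large sequenced cohorts:
variant QC, loss-of-function (LOF) burden scans, carrier saturation, and
penetrance.

## The problem

Exome sequencing of population biobanks yields millions of coding
variants, almost all rare (MAF < 1%), and in particular predicted LOF
variants — initiation-codon loss, premature stops, essential-splice and
frameshift alleles — that array imputation largely misses. Turning that
variation into biology requires a pipeline of well-defined statistical
steps: exact Hardy–Weinberg QC, functional classification at
any-transcript vs all-transcript stringency, quantifying what sequencing
adds over imputation (yield folds and allele-count concordance *R²* by
MAF bin), counting per-gene LOF carriers and extrapolating carrier
saturation to larger cohorts, collapsing rare LOF variants into per-gene
burden tests against hundreds of traits, filtering reportable pathogenic
variants in actionable genes, and estimating penetrance in carriers.
`exocohort` implements each stage as a composable R function and ships a
synthetic-cohort generator with the statistical structure these analyses
assume, so everything runs — and is tested — without restricted data.

## The models at the core

* **HWE exact test.** Conditional on minor allele count *m* among 2*n*
  alleles, `P(h) = n! / (n_AA! h! n_aa!) · 2^h m! (2n−m)! / (2n)!`;
  two-sided p sums configurations no more probable than observed.
  QC keeps variants with missingness < 10% and HWE *P* > 1e−15
  (strict inequalities).
* **Burden test.** Dominant-coded carrier indicator per gene
  (qualifying = LOF tier + MAF < 1%); Firth-penalized logistic
  regression (penalized LRT p, profile-penalized-likelihood CI) for
  binary traits, OLS on rank-inverse-normal values for quantitative
  traits; single-variant (MAC ≥ 4), leave-one-out, stepwise and
  conditional decompositions.
* **Saturation model.** Per-gene carrier counts at size *n* follow a
  β-binomial mixture `P(c_g) = Σ_j π_j BB(c_g | n, α_j, β_j)` (EM fit,
  BIC selection, optional structural-zero component); extrapolation to
  *N* individuals is posterior-predictive, so predictions at *N = n*
  equal the observed counts exactly.
* **Penetrance.** 2×2 odds ratios with Woolf CIs and Fisher exact p;
  Kaplan–Meier disease-free curves; single-covariate Cox (Breslow ties).

## Worked example

```r
library(exocohort)

cfg    <- simulation_config(n_individuals = 8000, n_genes = 40, seed = 2024)
cohort <- simulate_cohort(cfg)
qc     <- apply_variant_qc(cohort$genotypes)
qc
#> <qc_result>
#>   individuals: 8000 in, 0 dropped (missingness >= 0.1)
#>   variants: 312 in, 0 removed by missingness, 0 by HWE (p <= 1e-15), 312 retained

gm     <- qc$matrix
counts <- gene_carrier_counts(gm)             # het LOF carriers per gene
fit    <- fit_betabinomial_mixture(counts, K = 1)
fit
#> <betabinom_mixture> K = 1, fitted at n = 8000 on 40 genes
#>   pi = 1.000  alpha = 0.09057  beta = 113.1  (mean q = 0.0008)
#>   loglik = -66.00, BIC = 139.38, converged in 3 iterations

predict_saturation(fit, counts, N = 50000, thresholds = c(1, 5, 10))
#>       N  k expected_genes observed_at_fit
#> 1 50000  1      17.952868              14
#> 2 50000  5      10.102787               4
#> 3 50000 10       6.501232               3
```

Of 40 simulated genes, 14 already have a heterozygous LOF carrier at
n = 8,000; the fitted mixture (mean carrier probability 8e−4) predicts
that sequencing 50,000 individuals would raise that to ~18 genes, with
~6.5 genes reaching ten carriers.

```r
# plant a known burden effect (OR = 4.9 for carriers) and recover it
gene    <- counts$gene_id[which.max(counts$carriers_het)]   # "GENE0015", 110 carriers
effects <- data.frame(gene_id = gene, trait = "varicose_veins",
                      type = "binary", effect = log(4.9), prevalence = 0.03)
ph   <- simulate_phenotypes(gm, effects, seed = 2024)
mask <- collapse_gene_burden(gm, gene)
burden_association_test(mask, ph, "varicose_veins", covariates = c("age", "sex"))
#> <association_result> GENE0015 x varicose_veins (binary)
#>   OR = 4.06 (95% CI 2.17-7.02), p = 6e-05, carriers = 111, n = 8000

# penetrance-style odds ratio from published marginals
odds_ratio_with_ci(reconstruct_two_by_two(224, 0.211, 3337, 46599))
#> <odds_ratio_result> OR = 3.77 (95% CI 2.73-5.21), Fisher p = 1.7e-12
```

The Firth estimate (OR 4.06, CI 2.17–7.02) brackets the planted truth
4.9 — a single 110-carrier replicate is noisy, which is exactly why the
test suite checks CI coverage over 100 replicate seeds rather than one
point estimate. The 2×2 reconstruction turns printed marginals (224
carriers, 21.1% carrier case prevalence, 3,337 cases, 46,599 controls)
into an odds ratio with a Woolf interval and Fisher p.

See `vignettes/exocohort-methods.Rmd` for the full account of the
models, generator design, numerical choices and limitations.

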