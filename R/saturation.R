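#' Beta-binomial probability mass function
#'
#' `P(X = x)` for `X ~ BetaBinomial(size, alpha, beta)`:
#' `choose(size, x) * B(x + alpha, size - x + beta) / B(alpha, beta)`.
#' With `size = 0` all mass is at 0.
#'
#' @param x Count(s).
#' @param size Number of trials.
#' @param alpha,beta Positive Beta shape parameters.
#' @param log Return log probability.
#' @return Numeric vector of (log-)probabilities.
#' @export
dbetabinom <- function(x, size, alpha, beta, log = FALSE) {
  lp <- lchoose(size, x) + lbeta(x + alpha, size - x + beta) -
    lbeta(alpha, beta)
  lp[x < 0 | x > size | x != round(x)] <- -Inf
  if (log) lp else exp(lp)
}

#' Carrier rule for qualifying LOF variants
#'
#' @param tier `"lof_any_transcript"` or `"lof_all_transcripts"`.
#' @param maf_cutoff Qualifying variants must have MAF strictly below this.
#' @return List of class `carrier_rule`.
#' @export
carrier_rule <- function(tier = c("lof_any_transcript", "lof_all_transcripts"),
                         maf_cutoff = 0.01) {
  structure(list(tier = match.arg(tier), maf_cutoff = maf_cutoff),
            class = "carrier_rule")
}

#' Per-gene qualifying-LOF carrier counts
#'
#' Counts, for every gene, the individuals carrying at least one
#' qualifying LOF variant (LOF tier and MAF cutoff set by `rule`)
#' heterozygously (`carriers_het`) and homozygously (`carriers_hom`). An
#' individual counts once per gene however many qualifying variants they
#' carry; genes with no qualifying variant remain present with count 0.
#'
#' @param gm A QC'd [genotype_matrix()] with `maf` filled.
#' @param rule A [carrier_rule()].
#' @param genes Gene universe (default: all genes in the variant table).
#' @return Data frame of class `carrier_count_table` (`gene_id`,
#'   `carriers_het`, `carriers_hom`) with attribute `n` (sample size).
#' @export
gene_carrier_counts <- function(gm, rule = carrier_rule(), genes = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  if (is.null(genes)) genes <- sort(unique(stats::na.omit(v$gene_id)))
  qual <- v[[rule$tier]] %in% TRUE & !is.na(v$maf) & v$maf < rule$maf_cutoff
  het <- hom <- integer(length(genes))
  idx_by_gene <- split(which(qual), v$gene_id[qual])
  for (k in seq_along(genes)) {
    cols <- idx_by_gene[[genes[k]]]
    if (is.null(cols)) next
    calls <- gm$calls[, cols, drop = FALSE]
    het[k] <- sum(rowSums(calls == 1L, na.rm = TRUE) >= 1L)
    hom[k] <- sum(rowSums(calls == 2L, na.rm = TRUE) >= 1L)
  }
  out <- data.frame(gene_id = genes, carriers_het = het, carriers_hom = hom,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- length(gm$individuals)
  class(out) <- c("carrier_count_table", class(out))
  out
}

#' Observed saturation curves by random downsampling
#'
#' For each requested sample size, individuals are drawn without
#' replacement `n_reps` times; for each carrier threshold `k`, the number
#' of genes with at least `k` heterozygous qualifying-LOF carriers is
#' averaged over replicates. Output is deterministic for a fixed seed.
#'
#' @param gm A QC'd [genotype_matrix()].
#' @param sizes Sample sizes (each at most the cohort size).
#' @param thresholds Carrier thresholds `k`.
#' @param n_reps Downsampling replicates per size.
#' @param seed Integer seed.
#' @param rule A [carrier_rule()].
#' @return Data frame (`size`, `k`, `mean_genes`) of class
#'   `saturation_curve`.
#' @export
downsample_saturation_curve <- function(gm, sizes,
                                        thresholds = c(1, 5, 10, 25, 50, 100),
                                        n_reps = 1L, seed = 1L,
                                        rule = carrier_rule()) {
  n <- length(gm$individuals)
  if (any(sizes > n)) stop("downsampling size exceeds cohort size")
  if (n_reps < 1L) stop("n_reps must be at least 1")
  set.seed(derive_seed(seed, "downsample"))
  res <- expand.grid(size = sizes, k = thresholds)
  acc <- matrix(0, nrow(res), 1)
  for (r in seq_len(n_reps)) {
    for (s in sizes) {
      sub <- if (s == n) gm else
        compute_variant_stats(subset_matrix(gm, individuals = sample.int(n, s)))
      ct <- gene_carrier_counts(sub, rule)
      for (k in thresholds) {
        row <- which(res$size == s & res$k == k)
        acc[row] <- acc[row] + sum(ct$carriers_het >= k)
      }
    }
  }
  res$mean_genes <- as.vector(acc) / n_reps
  res <- res[order(res$k, res$size), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("saturation_curve", class(res))
  res
}

# -- beta-binomial mixture fitting -------------------------------------------

# Weighted beta-binomial log likelihood on unique count values. Shapes are
# soft-bounded to [1e-8, 1e8]: beyond that lbeta() loses all precision to
# cancellation and the likelihood surface is numerically meaningless.
bb_wloglik <- function(logpar, u, w, n) {
  bound <- log(1e8)
  excess <- sum(pmax(abs(logpar) - bound, 0))
  if (excess > 0) return(-1e12 * (1 + excess))
  a <- exp(logpar[1]); b <- exp(logpar[2])
  sum(w * dbetabinom(u, n, a, b, log = TRUE))
}

# Method-of-moments shapes for counts c ~ BB(n, a, b).
bb_moment_start <- function(counts, n) {
  mu <- max(mean(counts) / n, 1e-8)
  vv <- max(stats::var(counts), mu * (1 - mu) * n * 1.0001)
  rho <- (vv / (n * mu * (1 - mu)) - 1) / (n - 1)
  rho <- min(max(rho, 1e-6), 0.99)
  s <- 1 / rho - 1
  c(alpha = mu * s, beta = (1 - mu) * s)
}

#' Fit a beta-binomial mixture to per-gene carrier counts
#'
#' Models the count of qualifying-LOF carriers per gene at sample size
#' `n_fit` as a mixture of beta-binomials: each gene's per-individual
#' carrier probability is drawn from a mixture of Beta distributions, so
#' \deqn{P(c_g) = \sum_j \pi_j \, \mathrm{BB}(c_g \mid n, \alpha_j, \beta_j).}
#' Fitting is by expectation-maximization with numeric (BFGS) shape
#' updates in the M-step, run from `n_starts` starts (the first is the
#' method-of-moments start); an optional structural-zero component (a
#' point mass at carrier probability 0, for LOF-depleted genes) and the
#' component count are selected by BIC when a range is supplied.
#'
#' @param counts Per-gene heterozygous carrier counts (zero-count genes
#'   included), or a `carrier_count_table` from [gene_carrier_counts()].
#' @param n_fit Sample size at which counts were observed (taken from the
#'   table attribute when `counts` is a `carrier_count_table`).
#' @param K Component count, or a range over which BIC selects.
#' @param zero_component `"bic"` (compare with and without), `"never"`,
#'   or `"always"`.
#' @param n_starts EM multistarts per candidate model.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_iter` iterations (non-convergence is flagged and
#'   the best iterate returned).
#' @param seed Integer seed for the multistart jitter.
#' @return Object of class `betabinom_mixture`: `K`, `weights`, `alpha`,
#'   `beta`, `zero_weight`, `n_fit`, `G`, `loglik`, `bic`, `converged`,
#'   `iterations`, `degenerate`, and `candidates` (BIC table).
#' @export
fit_betabinomial_mixture <- function(counts, n_fit = NULL, K = 1L,
                                     zero_component = c("never", "bic", "always"),
                                     n_starts = 5L, max_iter = 2000L,
                                     tol = 1e-8, seed = 1L) {
  zero_component <- match.arg(zero_component)
  if (inherits(counts, "carrier_count_table")) {
    n_fit <- n_fit %||% attr(counts, "n")
    counts <- counts$carriers_het
  }
  if (is.null(n_fit)) stop("n_fit required")
  counts <- as.integer(counts)
  G <- length(counts)
  if (all(counts == 0L)) {
    # likelihood maximized at carrier probability -> 0: degenerate
    fit <- structure(list(K = 1L, weights = 1, alpha = 1e-8, beta = 1e8,
                          zero_weight = 0, n_fit = n_fit, G = G,
                          loglik = 0, bic = 0, converged = TRUE,
                          iterations = 0L, degenerate = TRUE,
                          candidates = NULL),
                     class = "betabinom_mixture")
    warning("all carrier counts are zero; degenerate fit returned")
    return(fit)
  }
  tab <- table(counts)
  u <- as.integer(names(tab))
  w <- as.numeric(tab)
  zero_opts <- switch(zero_component, never = FALSE, always = TRUE,
                      bic = c(FALSE, TRUE))
  cand <- expand.grid(K = K, zero = zero_opts)
  fits <- vector("list", nrow(cand))
  set.seed(derive_seed(seed, "bbmix"))
  for (i in seq_len(nrow(cand))) {
    fits[[i]] <- bbmix_em_multistart(counts, u, w, n_fit, cand$K[i],
                                     cand$zero[i], n_starts, max_iter, tol)
  }
  npar <- (cand$K + as.integer(cand$zero) - 1L) + 2L * cand$K
  cand$loglik <- vapply(fits, `[[`, numeric(1), "loglik")
  cand$bic <- -2 * cand$loglik + npar * log(G)
  best <- which.min(cand$bic)
  fit <- fits[[best]]
  fit$bic <- cand$bic[best]
  fit$G <- G
  fit$n_fit <- n_fit
  fit$degenerate <- FALSE
  fit$candidates <- cand
  class(fit) <- "betabinom_mixture"
  fit
}

bbmix_em_multistart <- function(counts, u, w, n, K, zero, n_starts,
                                max_iter, tol) {
  mom <- bb_moment_start(counts, n)
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (K == 1L && s == 1L) {
      a0 <- mom["alpha"]; b0 <- mom["beta"]
    } else {
      # spread/jitter starts around the moment fit
      a0 <- mom["alpha"] * exp(stats::rnorm(1, 0, 0.7) + seq(-0.7, 0.7, length.out = K))
      b0 <- mom["beta"] * exp(stats::rnorm(1, 0, 0.7) + seq(0.7, -0.7, length.out = K))
    }
    alpha <- rep_len(pmax(a0, 1e-6), K)
    beta <- rep_len(pmax(b0, 1e-6), K)
    wt <- rep(1 / (K + zero), K + zero)
    fit <- bbmix_em(u, w, n, alpha, beta, wt, zero, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# EM on unique count values u with multiplicities w. When `zero` is TRUE
# the last mixture weight belongs to a point mass at carrier probability 0.
bbmix_em <- function(u, w, n, alpha, beta, wt, zero, max_iter, tol) {
  K <- length(alpha)
  G <- sum(w)
  ncomp <- K + zero
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  ldens <- matrix(-Inf, length(u), ncomp)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(K)) {
      ldens[, j] <- dbetabinom(u, n, alpha[j], beta[j], log = TRUE)
    }
    if (zero) ldens[, ncomp] <- ifelse(u == 0L, 0, -Inf)
    lw <- sweep(ldens, 2, log(pmax(wt, 1e-300)), `+`)
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(w * lse)
    resp <- exp(lw - lse)  # unique-value responsibilities
    # M-step
    wt <- colSums(w * resp) / G
    for (j in seq_len(K)) {
      wj <- w * resp[, j]
      if (sum(wj) < 1e-8) next  # vanished component: freeze its shapes
      opt <- stats::optim(log(c(alpha[j], beta[j])), bb_wloglik,
                          u = u, w = wj, n = n, method = "BFGS",
                          control = list(fnscale = -1, maxit = 50))
      alpha[j] <- min(max(exp(opt$par[1]), 1e-8), 1e8)
      beta[j] <- min(max(exp(opt$par[2]), 1e-8), 1e8)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(alpha / (alpha + beta))
  list(K = K, weights = wt[seq_len(K)][ord], alpha = alpha[ord],
       beta = beta[ord],
       zero_weight = if (zero) wt[ncomp] else 0,
       loglik = ll_old, converged = converged, iterations = iter)
}

#' @export
print.betabinom_mixture <- function(x, ...) {
  cat(sprintf("<betabinom_mixture> K = %d%s, fitted at n = %d on %d genes\n",
              x$K, if (x$zero_weight > 0) " + structural zero" else "",
              x$n_fit, x$G))
  for (j in seq_len(x$K)) {
    cat(sprintf("  pi = %.3f  alpha = %.4g  beta = %.4g  (mean q = %.3g)\n",
                x$weights[j], x$alpha[j], x$beta[j],
                x$alpha[j] / (x$alpha[j] + x$beta[j])))
  }
  if (x$zero_weight > 0) cat(sprintf("  pi0 = %.3f (point mass at q = 0)\n",
                                     x$zero_weight))
  cat(sprintf("  loglik = %.2f, BIC = %.2f, %sconverged in %d iterations\n",
              x$loglik, x$bic, if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Posterior-predictive saturation at a larger sample size
#'
#' Extrapolates the expected number of genes with at least `k`
#' heterozygous LOF carriers to sample size `N`, conditional on the
#' observed counts: gene `g`'s component posterior is
#' `w_gj \propto pi_j BB(c_g | n, alpha_j, beta_j)`, and its carriers
#' among the `N - n` new individuals follow
#' `BB(N - n, alpha_j + c_g, beta_j + n - c_g)`. The expected gene count
#' at threshold `k` is the sum over genes of `P(c_g + future >= k)`. At
#' `N = n` the prediction equals the observed count exactly.
#'
#' @param fit A [fit_betabinomial_mixture()] object.
#' @param counts Observed per-gene counts at `fit$n_fit` (vector or
#'   `carrier_count_table`).
#' @param N Target sample size(s), each at least `n_fit`.
#' @param thresholds Carrier thresholds `k`.
#' @return Data frame of class `saturation_prediction` (`N`, `k`,
#'   `expected_genes`, `observed_at_fit`).
#' @export
predict_saturation <- function(fit, counts, N,
                               thresholds = c(1, 5, 10, 25, 50, 100)) {
  stopifnot(inherits(fit, "betabinom_mixture"))
  if (inherits(counts, "carrier_count_table")) counts <- counts$carriers_het
  counts <- as.integer(counts)
  n <- fit$n_fit
  if (any(N < n)) stop("target sample size N must be at least n_fit")
  tab <- table(counts)
  u <- as.integer(names(tab))
  mult <- as.numeric(tab)
  K <- fit$K
  zero <- fit$zero_weight > 0
  ncomp <- K + zero
  ldens <- matrix(-Inf, length(u), ncomp)
  for (j in seq_len(K)) {
    ldens[, j] <- dbetabinom(u, n, fit$alpha[j], fit$beta[j], log = TRUE)
  }
  wts <- c(fit$weights, if (zero) fit$zero_weight)
  if (zero) ldens[, ncomp] <- ifelse(u == 0L, 0, -Inf)
  lw <- sweep(ldens, 2, log(pmax(wts, 1e-300)), `+`)
  m <- apply(lw, 1, max)
  post <- exp(lw - (m + log(rowSums(exp(lw - m)))))

  res <- expand.grid(N = sort(N), k = thresholds)
  res$expected_genes <- NA_real_
  for (Ni in unique(res$N)) {
    n_new <- Ni - n
    for (kk in thresholds) {
      # P(future >= k - c | component j), per unique observed count
      p_ge <- vapply(seq_along(u), function(i) {
        need <- kk - u[i]
        if (need <= 0) return(1)
        if (n_new == 0L) return(0)
        pj <- vapply(seq_len(K), function(j) {
          a <- fit$alpha[j] + u[i]
          b <- fit$beta[j] + n - u[i]
          if (need > n_new) return(0)
          max(0, 1 - sum(dbetabinom(0:(need - 1L), n_new, a, b)))
        }, numeric(1))
        pj <- c(pj, if (zero) 0)
        sum(post[i, ] * pj)
      }, numeric(1))
      res$expected_genes[res$N == Ni & res$k == kk] <- sum(mult * p_ge)
    }
  }
  res$observed_at_fit <- vapply(res$k, function(kk) sum(counts >= kk),
                                numeric(1))
  class(res) <- c("saturation_prediction", class(res))
  res
}
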