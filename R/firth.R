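#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log likelihood
#' `l*(beta) = l(beta) + 0.5 log det I(beta)` by Newton iteration on the
#' modified score `U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij`, where
#' `h_i` are hat-matrix diagonals. The penalty keeps estimates finite
#' under separation and sparse carrier counts, the situation in which
#' rare-variant burden tests for binary traits operate.
#'
#' @param X Design matrix (include an intercept column).
#' @param y 0/1 response vector.
#' @param offset Optional linear-predictor offset.
#' @param max_iter,tol Newton stopping rule (modified score below `tol`).
#' @return List of class `firth_fit`: `coefficients`, `vcov` (inverse
#'   Fisher information at the solution), `loglik_penalized`, `converged`,
#'   `iterations`.
#' @export
firth_logistic <- function(X, y, offset = NULL, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(offset)) offset <- rep(0, n)
  beta <- rep(0, p)
  ybar <- min(max(mean(y), 1 / (n + 1)), n / (n + 1))
  if (all(X[, 1L] == 1)) beta[1L] <- stats::qlogis(ybar)

  pen_ll <- function(beta) {
    eta <- drop(X %*% beta) + offset
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    W <- pr * (1 - pr)
    I <- crossprod(X * sqrt(W))
    ld <- determinant(I, logarithm = TRUE)
    sum(y * log(pr) + (1 - y) * log(1 - pr)) + 0.5 * as.numeric(ld$modulus)
  }

  ll <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    W <- pr * (1 - pr)
    XW <- X * W
    I <- crossprod(X, XW)
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) stop("Fisher information is singular (collinear design)")
    h <- rowSums((X %*% Iinv) * XW)
    U <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    delta <- drop(Iinv %*% U)
    # step-halving to guarantee penalized-likelihood ascent
    step <- 1
    repeat {
      ll_new <- pen_ll(beta + step * delta)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll <- pen_ll(beta)
  }
  eta <- drop(X %*% beta) + offset
  pr <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  I <- crossprod(X * sqrt(pr * (1 - pr)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = solve(I), loglik_penalized = ll,
                 converged = converged, iterations = iter),
            class = "firth_fit")
}

# Penalized profile likelihood with coefficient `idx` fixed at `value`:
# the fixed term moves to the offset, the Jeffreys penalty still uses the
# full-model information (all columns of X).
firth_profile_ll <- function(X, y, idx, value, offset = NULL,
                             max_iter = 100L, tol = 1e-8) {
  n <- nrow(X)
  if (is.null(offset)) offset <- rep(0, n)
  off <- offset + value * X[, idx]
  Xf <- X[, -idx, drop = FALSE]
  beta_f <- rep(0, ncol(Xf))
  pen_ll <- function(beta_f) {
    eta <- drop(Xf %*% beta_f) + off
    pr <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    I_full <- crossprod(X * sqrt(pr * (1 - pr)))
    ld <- determinant(I_full, logarithm = TRUE)
    sum(y * log(pr) + (1 - y) * log(1 - pr)) + 0.5 * as.numeric(ld$modulus)
  }
  ll <- pen_ll(beta_f)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xf %*% beta_f) + off
    pr <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    W <- pr * (1 - pr)
    I_full <- crossprod(X, X * W)
    Iinv_full <- tryCatch(solve(I_full), error = function(e) NULL)
    if (is.null(Iinv_full)) break
    h <- rowSums((X %*% Iinv_full) * (X * W))
    U <- drop(crossprod(Xf, y - pr + h * (0.5 - pr)))
    if (max(abs(U)) < tol) break
    If <- crossprod(Xf, Xf * W)
    delta <- tryCatch(drop(solve(If, U)), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      ll_new <- pen_ll(beta_f + step * delta)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta_f <- beta_f + step * delta
    ll <- pen_ll(beta_f)
  }
  ll
}

# Penalized-likelihood-ratio p-value and profile CI for one coefficient.
# Falls back to the Wald interval when profile root-finding fails.
firth_inference <- function(X, y, idx, fit = NULL, level = 0.95,
                            ci = c("profile", "wald", "none")) {
  ci <- match.arg(ci)
  if (is.null(fit)) fit <- firth_logistic(X, y)
  b <- fit$coefficients[idx]
  se <- sqrt(fit$vcov[idx, idx])
  ll_full <- fit$loglik_penalized
  ll_0 <- firth_profile_ll(X, y, idx, 0)
  lr <- max(0, 2 * (ll_full - ll_0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_lo <- b - z * se
  ci_hi <- b + z * se
  ci_method <- "wald"
  if (ci == "profile") {
    crit <- stats::qchisq(level, df = 1)
    f <- function(v) 2 * (ll_full - firth_profile_ll(X, y, idx, v)) - crit
    lo <- tryCatch({
      lower <- b - z * se
      tries <- 0L
      while (f(lower) < 0 && tries < 8L) {
        lower <- lower - 2 * se
        tries <- tries + 1L
      }
      if (f(lower) < 0) stop("no bracket")
      stats::uniroot(f, c(lower, b), tol = 1e-6)$root
    }, error = function(e) NA_real_)
    hi <- tryCatch({
      upper <- b + z * se
      tries <- 0L
      while (f(upper) < 0 && tries < 8L) {
        upper <- upper + 2 * se
        tries <- tries + 1L
      }
      if (f(upper) < 0) stop("no bracket")
      stats::uniroot(f, c(b, upper), tol = 1e-6)$root
    }, error = function(e) NA_real_)
    if (!is.na(lo) && !is.na(hi)) {
      ci_lo <- lo
      ci_hi <- hi
      ci_method <- "profile"
    }
  }
  list(estimate = unname(b), se = unname(se), ci_low = unname(ci_lo),
       ci_high = unname(ci_hi), p = p, ci_method = ci_method)
}
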