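#' Build a carrier-by-case 2x2 table
#'
#' Cross-tabulates carrier status against case status over the same
#' individuals; individuals with missing case status are dropped.
#'
#' @param carrier Logical or 0/1 carrier indicator.
#' @param case Logical or 0/1/`NA` case indicator.
#' @return Object of class `two_by_two`: `a` carrier cases, `b` carrier
#'   non-cases, `c` non-carrier cases, `d` non-carrier non-cases.
#' @export
build_two_by_two <- function(carrier, case) {
  if (length(carrier) != length(case)) stop("inputs must have equal length")
  keep <- !is.na(case) & !is.na(carrier)
  carrier <- as.integer(carrier[keep])
  case <- as.integer(case[keep])
  if (!length(carrier)) stop("no analyzable individuals")
  two_by_two(a = sum(carrier == 1L & case == 1L),
             b = sum(carrier == 1L & case == 0L),
             c = sum(carrier == 0L & case == 1L),
             d = sum(carrier == 0L & case == 0L))
}

#' @rdname build_two_by_two
#' @param a,b,c,d Non-negative integer cell counts.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "two_by_two")
}

#' Reconstruct a 2x2 table from printed marginals
#'
#' Published penetrance comparisons often print only the carrier count,
#' the case prevalence in carriers, and the case/control totals. The
#' reconstruction convention used here: carrier cases
#' `a = round(rate x n_carriers)`; analyzable carriers
#' `= round(a / rate)` (inverting the rounded prevalence, which absorbs
#' carriers with missing case status); `b = analyzable - a`; non-carrier
#' cells from the case/control margins (`c = cases - a`,
#' `d = controls - b`).
#'
#' @param n_carriers Listed carrier count.
#' @param carrier_case_rate Printed case prevalence among carriers (e.g.
#'   0.211).
#' @param n_cases,n_controls Printed case and control totals.
#' @return A [two_by_two()] table.
#' @export
reconstruct_two_by_two <- function(n_carriers, carrier_case_rate,
                                   n_cases, n_controls) {
  a <- round(carrier_case_rate * n_carriers)
  analyzable <- round(a / carrier_case_rate)
  b <- analyzable - a
  two_by_two(a = a, b = b, c = n_cases - a, d = n_controls - b)
}

# Two-sided Fisher exact p: sum of hypergeometric point probabilities not
# exceeding the observed one (with the conventional 1 + 1e-7 tie
# tolerance).
fisher_exact_p <- function(tbl) {
  a <- tbl$a; b <- tbl$b; c <- tbl$c; d <- tbl$d
  m <- a + b          # carriers (row 1 total)
  n <- c + d          # non-carriers
  k <- a + c          # cases (column total)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval and Fisher exact p
#'
#' The point estimate is the unconditional sample odds ratio
#' `OR = (a d) / (b c)` with the Woolf (log-scale normal) interval
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`; the p-value is the
#' two-sided Fisher exact test (sum of hypergeometric point probabilities
#' at most the observed one). Tables with a zero margin are flagged
#' undefined; tables with a zero cell report the Haldane-Anscombe
#' (add 0.5) estimate separately.
#'
#' @param tbl A [two_by_two()] table.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `odds_ratio_result`: `or`, `ci_low`, `ci_high`,
#'   `p`, `or_haldane`, `defined`.
#' @export
odds_ratio_with_ci <- function(tbl, conf_level = 0.95) {
  stopifnot(inherits(tbl, "two_by_two"))
  a <- tbl$a; b <- tbl$b; c <- tbl$c; d <- tbl$d
  defined <- all(c(a + b, c + d, a + c, b + d) > 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  if (!defined) {
    return(structure(list(or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          or_haldane = or_h, defined = FALSE, table = tbl),
                     class = "odds_ratio_result"))
  }
  p <- fisher_exact_p(tbl)
  if (any(c(a, b, c, d) == 0)) {
    or <- if (b == 0 || c == 0) Inf else 0
    return(structure(list(or = or, ci_low = NA_real_, ci_high = NA_real_,
                          p = p, or_haldane = or_h, defined = FALSE,
                          table = tbl),
                     class = "odds_ratio_result"))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(or = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p = p, or_haldane = or_h, defined = TRUE, table = tbl),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("<odds_ratio_result> OR = %.3g (95%% CI %.3g-%.3g), Fisher p = %s\n",
              x$or, x$ci_low, x$ci_high, format_pvalue(x$p)))
  invisible(x)
}

#' Kaplan-Meier disease-free survival curves per group
#'
#' Product-limit estimate per group (simultaneous-event tie convention).
#' The curve starts at 1 and is non-increasing.
#'
#' @param surv Data frame with columns `time`, `event` and the grouping
#'   column.
#' @param group Name of the grouping column (default `"carrier"`).
#' @return Data frame (`group`, `time`, `n_risk`, `n_event`, `surv`).
#' @export
km_curve <- function(surv, group = "carrier") {
  stopifnot(all(c("time", "event", group) %in% names(surv)))
  if (any(surv$time < 0)) stop("survival times must be non-negative")
  g <- factor(surv[[group]])
  if (any(table(g) < 1)) stop("each group needs at least one individual")
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = surv)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1L], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards ratio between carrier groups
#'
#' Single-covariate Cox partial-likelihood fit (Breslow tie handling by
#' default) with Wald confidence interval and p-value. A monotone partial
#' likelihood (e.g. no events in one group) is flagged and a
#' ridge-penalized estimate returned instead of a diverging one.
#'
#' @param surv Data frame with `time`, `event` and the grouping column.
#' @param group Grouping column name (default `"carrier"`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level.
#' @return List of class `hazard_ratio_result`: `hr`, `ci_low`, `ci_high`,
#'   `p`, `monotone` (flag), `n_events`.
#' @export
cox_hazard_ratio <- function(surv, group = "carrier", ties = "breslow",
                             conf_level = 0.95) {
  stopifnot(all(c("time", "event", group) %in% names(surv)))
  x <- as.numeric(surv[[group]])
  d <- data.frame(time = surv$time, event = surv$event, x = x)
  ev <- tapply(d$event, d$x, sum)
  monotone <- any(ev == 0) || length(ev) < 2L
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!monotone) {
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                           ties = ties,
                           control = survival::coxph.control(eps = 1e-10,
                                                             iter.max = 50))
    b <- unname(stats::coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    monotone <- !is.finite(b) || abs(b) > 15
  }
  if (monotone) {
    fit <- survival::coxph(survival::Surv(time, event) ~
                             survival::ridge(x, theta = 1), data = d,
                           ties = ties)
    b <- unname(stats::coef(fit)[1])
    se <- sqrt(unname(fit$var[1, 1]))
  }
  structure(list(hr = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se),
                 p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
                 monotone = monotone, n_events = sum(d$event)),
            class = "hazard_ratio_result")
}

#' @export
print.hazard_ratio_result <- function(x, ...) {
  cat(sprintf("<hazard_ratio_result> HR = %.3g (95%% CI %.3g-%.3g), p = %s%s\n",
              x$hr, x$ci_low, x$ci_high, format_pvalue(x$p),
              if (x$monotone) " [monotone likelihood; penalized]" else ""))
  invisible(x)
}
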