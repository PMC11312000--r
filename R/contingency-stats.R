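#' Laplace smoothing of a contingency table
#'
#' When a table has a row (or, symmetrically, a column) of zero
#' frequencies, add-one smoothing is applied to every cell before
#' hypothesis testing; otherwise the table is returned unchanged. The
#' `smoothed` attribute records whether smoothing fired.
#'
#' @param tab Integer matrix of non-negative counts.
#' @return The (possibly smoothed) matrix with attribute `smoothed`.
#' @export
#' @examples
#' laplace_smooth(rbind(c(0, 0, 0), c(5, 3, 2)))
laplace_smooth <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0))
  fire <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  out <- if (fire) tab + 1 else tab
  attr(out, "smoothed") <- fire
  out
}

# Shared validation for 2xK tables of counts.
check_2xk <- function(tab, max_k = 4) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("table must have exactly 2 rows", call. = FALSE)
  if (ncol(tab) > max_k) {
    stop("table has more than ", max_k,
         " columns; exact enumeration is limited to 2x", max_k,
         " tables", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  tab
}

#' Fisher's exact test for a 2xK table by full enumeration
#'
#' Computes the two-sided p-value under the minimum-likelihood criterion:
#' all tables with the observed margins are enumerated, and the p-value is
#' the sum of (multivariate) hypergeometric probabilities of every table no
#' more probable than the observed one. Probabilities are accumulated in
#' log space from `lchoose`, giving relative accuracy far below 1e-10 for
#' tables of the sizes handled here.
#'
#' @param tab 2xK matrix of non-negative integer counts, K <= 4.
#' @param rel_tol Relative tie tolerance when comparing table probabilities
#'   to the observed probability (guards against floating-point ties).
#' @return List with `p_value`, `n_tables` (number of margin-consistent
#'   tables enumerated) and `log_p_observed`.
#' @export
#' @examples
#' fisher_exact_2xk(rbind(c(12, 14, 3), c(137, 30, 1)))$p_value
fisher_exact_2xk <- function(tab, rel_tol = 1e-7) {
  tab <- check_2xk(tab)
  cs <- colSums(tab)
  r1 <- sum(tab[1L, ])
  n <- sum(tab)
  if (n == 0) stop("empty table", call. = FALSE)
  if (prod(cs + 1) > 5e6) {
    stop("margins too large for full enumeration (",
         format(prod(cs + 1), big.mark = ","),
         " candidate first rows)", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(lapply(cs, function(m) 0:m),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  logp <- -lchoose(n, r1)
  for (j in seq_along(cs)) {
    logp <- logp + lchoose(cs[j], grid[, j])
  }
  logp_obs <- sum(lchoose(cs, tab[1L, ])) - lchoose(n, r1)
  p <- sum(exp(logp[logp <= logp_obs + log1p(rel_tol)]))
  list(p_value = min(p, 1), n_tables = nrow(grid),
       log_p_observed = logp_obs)
}

# Pearson chi-square statistic without continuity correction.
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row/column margin; apply laplace_smooth() first",
         call. = FALSE)
  }
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

#' Cramer's V effect size
#'
#' `V = sqrt(chi^2 / (n * min(r - 1, c - 1)))` with the Pearson chi-square
#' statistic (no continuity correction).
#'
#' @param tab Matrix of non-negative counts with positive margins (apply
#'   [laplace_smooth()] first if a margin is zero).
#' @return V in `[0, 1]`.
#' @export
#' @examples
#' cramers_v(rbind(c(12, 14, 3), c(137, 30, 1)))
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  m <- min(nrow(tab) - 1L, ncol(tab) - 1L)
  sqrt(chisq_stat(tab) / (n * m))
}

#' Confidence interval for Cramer's V by noncentral chi-square inversion
#'
#' The noncentrality parameter of the chi-square distribution is inverted
#' at the observed statistic: `lambda_hi` solves
#' `P(X_{df, lambda} <= chi2_obs) = (1 - level) / 2` and `lambda_lo` solves
#' `P(X_{df, lambda} <= chi2_obs) = (1 + level) / 2`, with `lambda_lo`
#' clamped at zero when the observed statistic is small. With the default
#' `adjust = TRUE` the bounds are mapped through
#' `sqrt((lambda + df) / (n * min(r - 1, c - 1)))` (the adjusted
#' noncentral convention); `adjust = FALSE` uses `lambda` alone, so the
#' lower bound is exactly zero at independence.
#'
#' @param tab Matrix of counts with positive margins.
#' @param level Confidence level (default 0.95).
#' @param adjust Use the `lambda + df` mapping (default `TRUE`).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' cramers_v_ci(rbind(c(12, 14, 3), c(137, 30, 1)))
cramers_v_ci <- function(tab, level = 0.95, adjust = TRUE) {
  tab <- as.matrix(tab)
  chi2 <- chisq_stat(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  n <- sum(tab)
  m <- min(nrow(tab) - 1L, ncol(tab) - 1L)
  alpha <- 1 - level

  solve_ncp <- function(target) {
    # find lambda with pchisq(chi2, df, ncp = lambda) == target;
    # pchisq is decreasing in lambda
    f <- function(l) stats::pchisq(chi2, df, ncp = l) - target
    if (f(0) <= 0) return(0)
    hi <- max(chi2, 1)
    it <- 0L
    while (f(hi) > 0) {
      hi <- hi * 2
      it <- it + 1L
      if (it > 60L) {
        stop("noncentrality root search failed to bracket (chi2 = ",
             format(chi2), ", target = ", target, ")", call. = FALSE)
      }
    }
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }

  lambda_lo <- solve_ncp(1 - alpha / 2)
  lambda_hi <- solve_ncp(alpha / 2)
  off <- if (adjust) df else 0
  c(lower = sqrt((lambda_lo + off) / (n * m)),
    upper = sqrt((lambda_hi + off) / (n * m)))
}

#' Full association analysis of a 2xK contingency table
#'
#' Applies the Laplace smoothing policy, Fisher's exact test by full
#' enumeration, the Pearson chi-square statistic, Cramer's V and its
#' noncentral chi-square confidence interval.
#'
#' @param tab 2xK matrix of counts.
#' @param level Confidence level for the V interval.
#' @return Object of class `association_result`: list with `table`,
#'   `smoothed`, `p_value`, `chi_square`, `df`, `cramers_v`, `v_ci`,
#'   `level`, `n`.
#' @export
association_test <- function(tab, level = 0.95) {
  tab <- check_2xk(tab)
  sm <- laplace_smooth(tab)
  smoothed <- attr(sm, "smoothed")
  attr(sm, "smoothed") <- NULL
  structure(list(
    table = sm,
    smoothed = smoothed,
    p_value = fisher_exact_2xk(sm)$p_value,
    chi_square = chisq_stat(sm),
    df = (nrow(sm) - 1L) * (ncol(sm) - 1L),
    cramers_v = cramers_v(sm),
    v_ci = cramers_v_ci(sm, level = level),
    level = level,
    n = sum(sm)
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Association test (2x", ncol(x$table), " table, n = ", x$n, ")\n",
      sep = "")
  if (x$smoothed) cat("  Laplace add-one smoothing applied\n")
  cat(sprintf("  Fisher exact p = %.3g\n", x$p_value))
  cat(sprintf("  chi-square = %.3f (df = %d)\n", x$chi_square, x$df))
  cat(sprintf("  Cramer's V = %.3f, %g%% CI (%.3f, %.3f)\n",
              x$cramers_v, 100 * x$level, x$v_ci[["lower"]],
              x$v_ci[["upper"]]))
  invisible(x)
}

#' Build the concordance-by-pattern-count contingency table
#'
#' Cross-tabulates sample group (discordant / concordant) against the
#' number of derived pattern classes (1, 2 or 3). Samples with an empty
#' pattern set are excluded with a message.
#'
#' @param samples Data frame with columns `group` (`"discordant"` /
#'   `"concordant"`) and `n_patterns` (integer 0-3).
#' @return 2x3 integer matrix, rows `discordant`, `concordant`; columns
#'   `"1"`, `"2"`, `"3"`.
#' @export
build_pattern_table <- function(samples) {
  stopifnot(all(c("group", "n_patterns") %in% names(samples)))
  stopifnot(all(samples$group %in% c("discordant", "concordant")))
  drop <- samples$n_patterns == 0L
  if (any(drop)) {
    message(sum(drop), " sample(s) with an empty pattern set excluded ",
            "from the pattern table")
    samples <- samples[!drop, , drop = FALSE]
  }
  stopifnot(all(samples$n_patterns %in% 1:3))
  tab <- table(factor(samples$group, levels = c("discordant", "concordant")),
               factor(samples$n_patterns, levels = 1:3))
  mat <- matrix(as.integer(tab), nrow = 2,
                dimnames = list(c("discordant", "concordant"),
                                c("1", "2", "3")))
  mat
}
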