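# Nonparametric univariable battery: Shapiro-Wilk screen, Spearman rank
# correlation, Mann-Whitney U, Kruskal-Wallis. Rank statistics are computed
# directly (average ranks, tie-corrected variances) so the exact and
# asymptotic branches are both under this package's control; base R's
# cor.test / wilcox.test / kruskal.test serve as independent oracles in the
# test suite only.

univariable_result <- function(test, statistic, p_value, estimate = NA_real_,
                               n = NA_integer_, groups = NULL, flagged = NA,
                               alpha = 0.05) {
  if (is.na(flagged)) flagged <- is.finite(p_value) && p_value < alpha
  structure(list(test = test, statistic = statistic, estimate = estimate,
                 p_value = p_value, n = n, groups = groups,
                 significant = flagged, alpha = alpha),
            class = "univariable_result")
}

#' @export
print.univariable_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g%s (n = %s)\n", x$test,
              x$statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else "", x$n))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Wraps the Shapiro-Wilk test as a distribution screen: the result flags
#' the sample as non-normal at `p < alpha`.
#'
#' @param values Numeric vector, `3 <= n <= 5000`, not constant.
#' @param alpha Flagging level.
#' @return A `univariable_result`; `significant` means non-normal.
#' @export
shapiro_screen <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) ts_stats_error("Shapiro-Wilk requires at least 3 values")
  if (n > 5000L) {
    ts_stats_error("Shapiro-Wilk is limited to n <= 5000; subsample first")
  }
  if (diff(range(values)) == 0) {
    ts_stats_error("Shapiro-Wilk is undefined for constant input")
  }
  sw <- stats::shapiro.test(values)
  univariable_result("shapiro_wilk", unname(sw$statistic), sw$p.value,
                     n = n, alpha = alpha)
}

avg_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks with a two-sided t-approximation
#' p-value (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @param alpha Flagging level.
#' @return A `univariable_result` with `estimate` = rho.
#' @export
spearman_rank <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    ts_stats_error("'x' and 'y' must have equal length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) ts_stats_error("Spearman requires at least 3 complete pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    ts_stats_error("Spearman is undefined for constant input")
  }
  rho <- stats::cor(avg_rank(x), avg_rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  univariable_result("spearman", rho, p, estimate = rho, n = n, alpha = alpha)
}

group_summary <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(values), q1 = q[1], median = q[2], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' `U` counts pairs `(a, b)` with `a > b` plus half the ties. The p-value is
#' exact (full enumeration of rank assignments, two-sided as twice the
#' smaller tail) when both groups have at most `exact_limit` observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. Group medians and
#' quartiles are reported.
#'
#' @param a,b Nonempty numeric vectors.
#' @param exact_limit Largest per-group n for the exact branch.
#' @param exact `NULL` for automatic branch choice, or TRUE/FALSE to force.
#' @param alpha Flagging level.
#' @return A `univariable_result` with `statistic` = U (for `a` over `b`).
#' @export
mann_whitney <- function(a, b, exact_limit = 8L, exact = NULL, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) ts_stats_error("both groups must be nonempty")
  pooled <- c(a, b)
  r <- avg_rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- if (is.null(exact)) (n1 <= exact_limit && n2 <= exact_limit && !ties) else exact
  if (use_exact && ties) {
    ts_stats_error("exact Mann-Whitney enumeration requires untied data")
  }
  if (use_exact) {
    # enumerate all C(n1+n2, n1) rank assignments for group a
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
  } else {
    N <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  univariable_result("mann_whitney", U, p, n = n1 + n2,
                     groups = rbind(a = group_summary(a), b = group_summary(b)),
                     alpha = alpha)
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction, p from the chi-square distribution on
#' `k - 1` degrees of freedom.
#'
#' @param groups List of at least two nonempty numeric vectors.
#' @param alpha Flagging level.
#' @return A `univariable_result` with per-group medians/quartiles.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2L) ts_stats_error("Kruskal-Wallis requires at least 2 nonempty groups")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- avg_rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  Rj <- tapply(r, idx, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie_tab <- table(pooled)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) H <- H / corr
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  gs <- do.call(rbind, lapply(groups, group_summary))
  rownames(gs) <- names(groups) %||% paste0("g", seq_len(k))
  univariable_result("kruskal_wallis", H, p, n = N, groups = gs, alpha = alpha)
}
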