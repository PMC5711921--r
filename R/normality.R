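#' D'Agostino-Pearson omnibus normality test
#'
#' Combines D'Agostino's skewness Z and the Anscombe-Glynn kurtosis Z
#' into the omnibus statistic `K2 = Zs^2 + Zk^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Sample skewness
#' and kurtosis are the moment estimators `g1 = m3 / m2^(3/2)` and
#' `b2 = m4 / m2^2` (kurtosis not excess-centred).
#'
#' @param values Numeric vector, at least 20 non-missing values.
#' @param alpha Significance level for the `pass` flag (default 0.01:
#'   the sample is called normal when `p > alpha`).
#' @return A `normality_report` list: `n`, `skewness`, `kurtosis`,
#'   `z_skewness`, `z_kurtosis`, `k2`, `p`, `pass`.
#' @export
#' @examples
#' dagostino_pearson(rnorm(100))$pass
dagostino_pearson <- function(values, alpha = 0.01) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 20) stop("need at least 20 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness Z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha_s <- sqrt(2 / (W2 - 1))
  zs <- if (y == 0) 0 else delta * asinh(y / alpha_s)
  # kurtosis Z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term <- sign(denom) * abs((1 - 2 / A) / denom)^(1 / 3)
  zk <- ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))
  k2 <- zs^2 + zk^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  structure(list(n = n, skewness = g1, kurtosis = b2, z_skewness = zs,
                 z_kurtosis = zk, k2 = k2, p = p, pass = p > alpha,
                 alpha = alpha),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf(paste0("D'Agostino-Pearson omnibus test (n = %d): ",
                     "K2 = %.3f, p = %.4g\n"), x$n, x$k2, x$p))
  cat(sprintf("  skewness %.3f (Z = %.2f), kurtosis %.3f (Z = %.2f); %s\n",
              x$skewness, x$z_skewness, x$kurtosis, x$z_kurtosis,
              if (x$pass) "consistent with normality" else
                "normality rejected"))
  invisible(x)
}

#' One-way ANOVA and pairwise t-tests across bone-status groups
#'
#' @param values Numeric vector (e.g. marker expression or DANN scores).
#' @param groups Factor of group memberships (at least 2 groups, each
#'   with at least 2 members).
#' @return A `group_comparison` list with `anova_p`, the `aov` fit, and
#'   a tibble `pairwise` of two-sided Welch t-test p-values per group
#'   pair.
#' @export
group_compare <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    tt <- stats::t.test(values[groups == pr[1]], values[groups == pr[2]])
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   t = unname(tt$statistic), p = tt$p.value)
  })
  structure(list(anova_p = anova_p, fit = fit, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA p = %.4g\n", x$anova_p))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: p = %.4g\n", x$pairwise$group1[i],
                x$pairwise$group2[i], x$pairwise$p[i]))
  }
  invisible(x)
}
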