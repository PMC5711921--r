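#' Spearman correlation test
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, adequate for the cohort sizes screened
#' here. An exact-style permutation mode is available for small samples.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   in either are dropped (pairwise-complete).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return A list with `rho`, `p`, and `n` (pairs used).
#' @export
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))$rho
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    p <- withr::with_seed(seed, {
      null_rho <- replicate(n_perm, stats::cor(rx, sample(ry)))
      (sum(abs(null_rho) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
    })
  }
  list(rho = rho, p = p, n = n)
}

#' Band the strength of a Spearman correlation
#'
#' Cut-points on `|rho|`: `[0, 0.1)` none, `[0.1, 0.2)` extremely weak,
#' `[0.2, 0.4)` weak, `[0.4, 0.7)` moderate, `[0.7, 1]` strong.
#'
#' @param rho Numeric vector, `|rho| <= 1`.
#' @param cuts Interior cut-points, ascending.
#' @return Ordered factor of band labels.
#' @export
#' @examples
#' band_of(c(0.05, -0.365, 0.649))
band_of <- function(rho, cuts = c(0.1, 0.2, 0.4, 0.7)) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must be <= 1", call. = FALSE)
  labs <- c("none", "extremely-weak", "weak", "moderate", "strong")
  cut(abs(rho), breaks = c(-Inf, cuts, Inf), labels = labs, right = FALSE,
      ordered_result = TRUE)
}

#' Screen examination items for BMD correlation
#'
#' Tests the marker and every examination item against spine BMD with
#' [spearman_test()]. An item is flagged BMD-correlated when `|rho|`
#' exceeds `rho_threshold` and `p` is below `p_threshold` (defaults 0.1
#' and 0.01; no multiple-testing correction, a fixed per-item rule).
#' Items whose correlation is undefined (constant, or too few complete
#' pairs) get `valid = FALSE` and band `none`.
#'
#' @param cohort A cohort tibble with complete `bmd`.
#' @param items Item columns to screen; defaults to `mir194` plus every
#'   examination-item column present.
#' @param rho_threshold,p_threshold Flagging rule thresholds.
#' @return A `screening_result` tibble: `item`, `rho`, `p`, `n`, `band`,
#'   `bmd_correlated`, `valid`, in deterministic (registry) item order.
#' @export
screen_items <- function(cohort, items = NULL, rho_threshold = 0.1,
                         p_threshold = 0.01) {
  validate_cohort(cohort)
  if (is.null(items)) items <- c("mir194", cohort_ei_columns(cohort))
  res <- purrr::map_dfr(items, function(it) {
    out <- tryCatch(spearman_test(cohort[[it]], cohort$bmd),
                    error = function(e) NULL)
    if (is.null(out)) {
      tibble::tibble(item = it, rho = NA_real_, p = NA_real_,
                     n = sum(!is.na(cohort[[it]])), valid = FALSE)
    } else {
      tibble::tibble(item = it, rho = out$rho, p = out$p, n = out$n,
                     valid = TRUE)
    }
  })
  res$band <- band_of(ifelse(res$valid, res$rho, 0))
  res$bmd_correlated <- res$valid & abs(res$rho) > rho_threshold &
    res$p < p_threshold
  res <- res[, c("item", "rho", "p", "n", "band", "bmd_correlated", "valid")]
  class(res) <- c("screening_result", class(res))
  res
}

#' Pairwise collinearity matrix
#'
#' Absolute pairwise Spearman correlations among candidate model inputs;
#' a pair is flagged collinear when `|rho|` exceeds the threshold
#' (default 0.3).
#'
#' @param cohort A cohort tibble.
#' @param items Character vector of at least two column names.
#' @param threshold Collinearity flag threshold on `|rho|`.
#' @return A `collinearity_matrix` list with `abs_rho` (symmetric matrix,
#'   unit diagonal), `flagged` (logical matrix), and `threshold`.
#' @export
collinearity_matrix <- function(cohort, items, threshold = 0.3) {
  stopifnot(length(items) >= 2)
  k <- length(items)
  m <- diag(k)
  dimnames(m) <- list(items, items)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- tryCatch(
        spearman_test(cohort[[items[i]]], cohort[[items[j]]])$rho,
        error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- abs(r)
    }
  }
  flagged <- !is.na(m) & m > threshold
  diag(flagged) <- FALSE
  structure(list(abs_rho = m, flagged = flagged, threshold = threshold),
            class = "collinearity_matrix")
}

#' Select model input features from screening results
#'
#' Ranks the BMD-correlated examination items by `|rho|` descending
#' (ties broken by screening order, i.e. registry order) and keeps the
#' top `n_ei`. In `"noncollinear"` mode the lower-ranked member of any
#' flagged collinear pair is dropped before the top-`n_ei` cut, so e.g.
#' of the collinear LVDS-LVEDD echocardiography pair only the stronger
#' one enters the model. The marker is always included, first.
#'
#' @param screening A `screening_result` from [screen_items()].
#' @param collinearity A `collinearity_matrix`, required for
#'   `"noncollinear"` mode.
#' @param mode `"noncollinear"` (default) or `"collinear"`.
#' @param n_ei Maximum number of examination items to keep.
#' @param marker Marker column name, always placed first.
#' @return Ordered character vector of feature names.
#' @export
select_model_inputs <- function(screening, collinearity = NULL,
                                mode = c("noncollinear", "collinear"),
                                n_ei = 5, marker = "mir194") {
  mode <- match.arg(mode)
  cand <- screening[screening$bmd_correlated & screening$item != marker, ]
  if (nrow(cand) == 0L) {
    warning("no BMD-correlated examination item; marker-only model",
            call. = FALSE)
    return(marker)
  }
  cand <- cand[order(-abs(cand$rho)), ]
  kept <- character(0)
  for (it in cand$item) {
    if (mode == "noncollinear" && !is.null(collinearity)) {
      prev <- intersect(c(marker, kept), rownames(collinearity$flagged))
      if (it %in% colnames(collinearity$flagged) &&
          any(collinearity$flagged[prev, it])) next
    }
    kept <- c(kept, it)
    if (length(kept) >= n_ei) break
  }
  c(marker, kept)
}
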