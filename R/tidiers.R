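#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy method for screening results
#'
#' @param x A `screening_result` from [screen_items()].
#' @param ... Unused.
#' @return The underlying tibble of per-item correlation records.
#' @export
tidy.screening_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "screening_result")
  out
}

#' Tidy a collinearity matrix into long form
#'
#' @param x A `collinearity_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered item pair: `item1`,
#'   `item2`, `abs_rho`, `collinear`.
#' @export
tidy.collinearity_matrix <- function(x, ...) {
  items <- rownames(x$abs_rho)
  pairs <- which(upper.tri(x$abs_rho), arr.ind = TRUE)
  tibble::tibble(item1 = items[pairs[, 1]], item2 = items[pairs[, 2]],
                 abs_rho = x$abs_rho[pairs],
                 collinear = x$flagged[pairs])
}

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  opt <- optimal_cutoff(x)
  tibble::tibble(auc = x$auc, threshold = opt$threshold, se_optimal = opt$se,
                 sp_optimal = opt$sp, youden = opt$youden,
                 se_at_sp90 = se_at_fixed_sp(x, 0.9),
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy and glance methods for ROC results
#'
#' `tidy()` returns the operating points; `glance()` the one-row summary
#' (AUC, Youden-optimal cut-off triple, sensitivity at specificity 0.9).
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.dann_model
#' @export
glance.dann_model <- function(x, ...) {
  tibble::tibble(m = x$m, d_index = x$d_index, rho = x$rho_full,
                 ann1_r_train = x$ann1$r_train, ann1_r_test = x$ann1$r_test,
                 ann2_r_train = x$r_train, ann2_r_test = x$r_test,
                 threshold = x$threshold)
}

#' Tidy and glance methods for DANN models
#'
#' `tidy()` returns the `(m, d_index, rho_verify)` division-search grid;
#' `glance()` the one-row model summary.
#'
#' @param x A `dann_model`.
#' @param ... Unused.
#' @export
tidy.dann_model <- function(x, ...) x$grid

#' @export
glance.ann1_model <- function(x, ...) {
  tibble::tibble(k = x$network$k, r_train = x$r_train,
                 r_verify = x$r_verify, r_test = x$r_test)
}

#' @export
tidy.ann1_model <- function(x, ...) x$network$grid

#' @export
glance.delong_comparison <- function(x, ...) {
  tibble::tibble(auc1 = x$auc1, auc2 = x$auc2, delta = x$delta,
                 variance = x$variance, z = x$z, p = x$p)
}

#' @export
glance.normality_report <- function(x, ...) {
  tibble::tibble(n = x$n, skewness = x$skewness, kurtosis = x$kurtosis,
                 z_skewness = x$z_skewness, z_kurtosis = x$z_kurtosis,
                 k2 = x$k2, p = x$p, pass = x$pass)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(k = x$k, rho = x$rho,
                 auc = if (!is.null(x$roc)) x$roc$auc else NA_real_)
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = x$fold, score = x$scores)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise
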