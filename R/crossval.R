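#' Ten-fold cross-validation of the full DANN pipeline
#'
#' Randomly partitions the cohort into `k` mutually exclusive folds of
#' nearly equal size (largest-remainder). For each fold, the *entire*
#' training pipeline -- min-max normalization, ANN I, and the
#' `(m, d_index)` division search for ANN II -- is re-run on the other
#' `k - 1` folds, and the held-out fold is scored against that training
#' reference only, so no held-out participant leaks into normalization,
#' network fitting, hyperparameter selection, or the derivative-feature
#' reference. After the inner architecture search each fold's networks
#' are refitted on the whole training fold (`refit_full`). Out-of-fold
#' scores are pooled.
#'
#' @param cohort Cohort tibble.
#' @param features Model input columns.
#' @param k Number of folds (default 10); requires `n >= 2k`.
#' @param seed Integer seed (fold assignment and per-fold fits).
#' @param m_range,k_grid,lambda Passed to [fit_dann()].
#' @return A `cv_result` with pooled `scores` (cohort order), `fold`
#'   assignments, pooled Spearman `rho` against BMD, the pooled
#'   `roc_result`, and per-fold selected `(m, d_index)`.
#' @export
kfold_cv <- function(cohort, features, k = 10, seed = 1, m_range = 2:10,
                     k_grid = NULL, lambda = 1e-3) {
  kfold_cv_impl(cohort, features, k, seed, m_range, k_grid, lambda)
}

# Two-way 2:1 split used inside cross-validation folds.
split_2_1 <- function(n, seed) {
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- ceiling(2 * n / 3)
  structure(list(train = sort(idx[seq_len(n_train)]),
                 verify = sort(idx[(n_train + 1):n]),
                 test = integer(0), seed = seed),
            class = "holdout_split")
}

kfold_cv_impl <- function(cohort, features, k = 10, seed = 1,
                          m_range = 2:10,
                     k_grid = NULL, lambda = 1e-3) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (n < 2 * k) stop("need at least 2k rows for k-fold CV", call. = FALSE)
  sizes <- largest_remainder_first(n, k)
  fold <- withr::with_seed(seed, sample(rep(seq_len(k), sizes)))
  scores <- rep(NA_real_, n)
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(fold == f)
    train <- cohort[-hold, , drop = FALSE]
    # inside a fold there is no holdout report to produce, so the
    # training fold is split 2:1 (train:verify) only -- no idle third
    inner <- split_2_1(nrow(train), seed = seed + f)
    ann1 <- fit_ann1(train, features, seed = seed + f, split = inner,
                     k_grid = k_grid, lambda = lambda)
    model <- fit_dann(train, features, seed = seed + f, m_range = m_range,
                      ann1 = ann1, refit_full = TRUE, k_grid = k_grid,
                      lambda = lambda)
    scores[hold] <- predict(model, cohort[hold, , drop = FALSE])
    selected[[f]] <- tibble::tibble(fold = f, m = model$m,
                                    d_index = model$d_index)
  }
  roc <- tryCatch(roc_curve(scores, cohort$status, direction = "low"),
                  error = function(e) NULL)
  structure(list(scores = scores, fold = fold,
                 rho = safe_cor(scores, cohort$bmd, method = "spearman"),
                 roc = roc, selected = dplyr::bind_rows(selected),
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of DANN\n", x$k))
  cat(sprintf("  pooled Spearman rho(score, BMD) = %.3f\n", x$rho))
  if (!is.null(x$roc)) cat(sprintf("  pooled AUC = %.3f\n", x$roc$auc))
  invisible(x)
}
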