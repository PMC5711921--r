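#' Split a cohort into training, verification and testing sets (2:1:1)
#'
#' Seeded uniform shuffle, then contiguous blocks of sizes
#' `ceiling(n / 2)` for training with the remainder split evenly between
#' verification and testing (the extra row, if any, to verification).
#' One quarter of the cohort therefore never touches model building.
#'
#' @param n Number of rows (`n >= 8`).
#' @param seed Integer seed; the same seed always gives the same split.
#' @return A `holdout_split` list with integer index vectors `train`,
#'   `verify`, `test`, and the `seed`.
#' @export
#' @examples
#' lengths(split_2_1_1(230, seed = 1)[1:3])
split_2_1_1 <- function(n, seed) {
  if (n < 8) stop("need at least 8 rows for a 2:1:1 split", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- ceiling(n / 2)
  rest <- n - n_train
  n_verify <- ceiling(rest / 2)
  structure(list(train = sort(idx[seq_len(n_train)]),
                 verify = sort(idx[n_train + seq_len(n_verify)]),
                 test = sort(idx[(n_train + n_verify + 1):n]),
                 seed = seed),
            class = "holdout_split")
}

# Squared Euclidean distances between rows of two matrices.
sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# Fit one RBF network of k centres: seeded k-means centres, widths by a
# scaled mean distance to the nearest other centres (the scale > 1 makes
# neighbouring kernels overlap, which matters in the unit box where
# centres sit close together), ridge least squares for the linear output
# layer. Returns NULL if k-means degenerates even after retries.
rbf_fit_k <- function(X, y, k, seed, lambda, width_neighbors = 4,
                      width_scale = 3) {
  km <- NULL
  for (attempt in 0:2) {
    km <- withr::with_seed(seed + 1000L * attempt, {
      tryCatch(stats::kmeans(X, centers = k, iter.max = 30, nstart = 1),
               error = function(e) NULL)
    })
    if (!is.null(km) && nrow(km$centers) == k) break
  }
  if (is.null(km)) return(NULL)
  centers <- km$centers
  dc <- sqrt(sqdist(centers, centers))
  widths <- vapply(seq_len(k), function(j) {
    others <- sort(dc[j, -j])
    mean(others[seq_len(min(width_neighbors, length(others)))])
  }, numeric(1))
  pos <- widths[widths > 0]
  fallback <- if (length(pos)) stats::median(pos) else 0.5
  widths[!is.finite(widths) | widths <= 0] <- fallback
  widths <- widths * width_scale
  Phi <- exp(-sqdist(X, centers) / (2 * matrix(widths^2, nrow(X), k,
                                               byrow = TRUE)))
  A <- cbind(Phi, 1)
  G <- crossprod(A) + lambda * diag(k + 1)
  w <- tryCatch(solve(G, crossprod(A, y)), error = function(e) NULL)
  if (is.null(w)) {
    w <- solve(crossprod(A) + 1e-3 * diag(k + 1), crossprod(A, y))
  }
  list(centers = centers, widths = widths, weights = drop(w))
}

rbf_eval <- function(net, X) {
  k <- length(net$widths)
  Phi <- exp(-sqdist(X, net$centers) /
               (2 * matrix(net$widths^2, nrow(X), k, byrow = TRUE)))
  raw <- drop(cbind(Phi, 1) %*% net$weights)
  pmin(pmax(raw, 0), 1)
}

safe_cor <- function(a, b, method = "pearson") {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b, method = method)
}

#' Fit a radial-basis-function network regression
#'
#' Regresses a `[0, 1]` target (normalized spine BMD) on normalized
#' inputs. The architecture search mimics an automated problem solver:
#' for each candidate centre count `k` in `k_grid`, centres are placed by
#' seeded k-means on the training inputs, per-centre Gaussian widths by
#' three times the mean distance to the four nearest other centres (so
#' neighbouring kernels overlap), and the linear output layer by
#' ridge-regularized least squares. The
#' candidate maximizing the Pearson correlation between network output
#' and target on the verification set is kept. Predictions are clipped
#' to `[0, 1]`.
#'
#' @param X_train,y_train Training inputs (matrix or data frame, columns
#'   in `[0, 1]`) and target.
#' @param X_verify,y_verify Verification set used only for selecting `k`.
#' @param seed Integer seed for the k-means placements.
#' @param k_grid Candidate centre counts; default
#'   `2:min(20, floor(nrow(X_train) / 5))`.
#' @param lambda Ridge penalty for the output weights (default 1e-3;
#'   a mild penalty stabilizes the wide-kernel design matrix).
#' @return An `rbf_network` object with elements `centers`, `widths`,
#'   `weights`, `features`, `k`, `r_train`, `r_verify`, and `grid` (the
#'   per-k selection trace).
#' @export
fit_rbf <- function(X_train, y_train, X_verify, y_verify, seed,
                    k_grid = NULL, lambda = 1e-3) {
  X_train <- as.matrix(X_train); X_verify <- as.matrix(X_verify)
  stopifnot(nrow(X_train) == length(y_train),
            nrow(X_verify) == length(y_verify))
  if (is.null(k_grid)) {
    k_max <- max(2, min(20, floor(nrow(X_train) / 5)))
    k_grid <- 2:k_max
  }
  k_grid <- k_grid[k_grid < nrow(X_train) & k_grid >= 1]
  if (length(k_grid) == 0L) stop("no admissible centre count", call. = FALSE)
  best <- NULL; best_score <- -Inf
  trace <- purrr::map_dfr(k_grid, function(k) {
    net <- rbf_fit_k(X_train, y_train, k, seed, lambda)
    if (is.null(net)) {
      return(tibble::tibble(k = k, r_verify = NA_real_))
    }
    score <- safe_cor(rbf_eval(net, X_verify), y_verify)
    if (score > best_score) {
      best_score <<- score; best <<- c(net, list(k = k))
    }
    tibble::tibble(k = k, r_verify = score)
  })
  if (is.null(best)) stop("RBF fitting failed for every centre count",
                          call. = FALSE)
  feats <- colnames(X_train)
  if (is.null(feats)) feats <- paste0("x", seq_len(ncol(X_train)))
  structure(list(centers = best$centers, widths = best$widths,
                 weights = best$weights, features = feats, k = best$k,
                 r_train = safe_cor(rbf_eval(best[1:3], X_train), y_train),
                 r_verify = best_score, grid = trace, seed = seed,
                 lambda = lambda),
            class = "rbf_network")
}

#' Predict from a fitted RBF network
#'
#' @param object An `rbf_network`.
#' @param newdata Data frame or matrix containing every model feature
#'   (extra columns ignored; column order irrelevant).
#' @param ... Unused.
#' @return Numeric scores clipped to `[0, 1]`.
#' @export
predict.rbf_network <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f) > 0L) {
    stop("missing model feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  rbf_eval(object, as.matrix(newdata[object$features]))
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("RBF network:", x$k, "centres over",
      length(x$features), "inputs\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  r_train = %.3f, r_verify = %.3f\n", x$r_train, x$r_verify))
  invisible(x)
}

#' Fit ANN I: RBF regression of normalized BMD on marker + items
#'
#' Convenience wrapper around [fit_rbf()] working directly on a cohort
#' tibble: fits min-max normalization for the features and BMD on the
#' full reference cohort, applies the 2:1:1 holdout split, fits the
#' network on the training set with `k` selected on the verification
#' set, and reports the holdout generalization pair `R_Tr` / `R_Te`
#' (Pearson correlation of network output with normalized BMD on the
#' training and testing sets).
#'
#' @param cohort A cohort tibble.
#' @param features Model input columns (e.g. from
#'   [select_model_inputs()]).
#' @param seed Integer seed (split and k-means).
#' @param normalization Optional pre-fitted `minmax_params` covering the
#'   features and `bmd`; fitted on `cohort` when `NULL`.
#' @param split Optional `holdout_split`; computed from `seed` when
#'   `NULL`.
#' @inheritParams fit_rbf
#' @return An `ann1_model` containing the `rbf_network`, the
#'   normalization parameters, the split, and `r_train` / `r_test`.
#' @export
fit_ann1 <- function(cohort, features, seed, normalization = NULL,
                     split = NULL, k_grid = NULL, lambda = 1e-3) {
  validate_cohort(cohort)
  if (is.null(normalization)) {
    normalization <- fit_minmax(cohort, c(features, "bmd"))
  }
  n <- nrow(cohort)
  if (is.null(split)) split <- split_2_1_1(n, seed)
  Xn <- normalize_features(normalization, cohort, features)
  yn <- apply_minmax(normalization, cohort$bmd, "bmd")
  net <- fit_rbf(Xn[split$train, , drop = FALSE], yn[split$train],
                 Xn[split$verify, , drop = FALSE], yn[split$verify],
                 seed = seed, k_grid = k_grid, lambda = lambda)
  r_test <- if (length(split$test) > 1) {
    safe_cor(rbf_eval(net, as.matrix(Xn[split$test, , drop = FALSE])),
             yn[split$test])
  } else NA_real_
  structure(list(network = net, normalization = normalization,
                 features = features, split = split, seed = seed,
                 r_train = net$r_train, r_verify = net$r_verify,
                 r_test = r_test),
            class = "ann1_model")
}

#' Predict normalized-BMD scores from an ANN I model
#'
#' @param object An `ann1_model`.
#' @param newdata Cohort-like data frame with the raw (unnormalized)
#'   model features.
#' @param ... Unused.
#' @return Scores in `[0, 1]`; higher tracks higher BMD.
#' @export
predict.ann1_model <- function(object, newdata, ...) {
  Xn <- normalize_features(object$normalization, newdata, object$features)
  predict(object$network, Xn)
}

#' @export
print.ann1_model <- function(x, ...) {
  cat("ANN I (RBF regression of normalized BMD)\n")
  print(x$network)
  cat(sprintf("  holdout R_Tr = %.3f, R_Te = %.3f\n", x$r_train, x$r_test))
  invisible(x)
}

#' Multiple linear regression baseline
#'
#' Ordinary least squares of normalized BMD on the normalized model
#' inputs, fitted on the training split, for comparison against the RBF
#' network. Reported `rho` values are Spearman correlations between the
#' fitted output and normalized BMD. A logistic variant on the binary
#' osteoporosis label is available via `family = "logistic"`.
#'
#' @inheritParams fit_ann1
#' @param family `"linear"` (default) or `"logistic"`.
#' @return An `mlr_baseline` with the `stats::lm`/`glm` fit, `rho_train`,
#'   `rho_test`, and the split.
#' @export
fit_mlr <- function(cohort, features, seed, normalization = NULL,
                    split = NULL, family = c("linear", "logistic")) {
  family <- match.arg(family)
  validate_cohort(cohort)
  if (length(features) == 0L) stop("no model features", call. = FALSE)
  if (is.null(normalization)) {
    normalization <- fit_minmax(cohort, c(features, "bmd"))
  }
  if (is.null(split)) split <- split_2_1_1(nrow(cohort), seed)
  Xn <- normalize_features(normalization, cohort, features)
  yn <- apply_minmax(normalization, cohort$bmd, "bmd")
  df <- cbind(Xn, .target = if (family == "linear") yn else
    as.numeric(is_osteoporosis(cohort$status)))
  fit <- if (family == "linear") {
    stats::lm(.target ~ ., data = df[split$train, ])
  } else {
    stats::glm(.target ~ ., data = df[split$train, ],
               family = stats::binomial())
  }
  pred <- function(idx) {
    stats::predict(fit, newdata = df[idx, ], type = "response")
  }
  structure(list(fit = fit, normalization = normalization,
                 features = features, split = split, family = family,
                 rho_train = safe_cor(pred(split$train), yn[split$train],
                                      method = "spearman"),
                 rho_test = safe_cor(pred(split$test), yn[split$test],
                                     method = "spearman")),
            class = "mlr_baseline")
}

#' @export
predict.mlr_baseline <- function(object, newdata, ...) {
  Xn <- normalize_features(object$normalization, newdata, object$features)
  unname(stats::predict(object$fit, newdata = Xn, type = "response"))
}
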