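#' Euclidean distance between normalized feature vectors
#'
#' Participants are compared in the d-dimensional unit box spanned by
#' the normalized model inputs (d = 6 for the marker plus five
#' examination items), so distances lie in `[0, sqrt(d)]`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Euclidean distance.
#' @export
#' @examples
#' euclidean(rep(0, 6), rep(1, 6)) # sqrt(6)
euclidean <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Partition reference participants into distance-ranked divisions
#'
#' Sorts the reference participants by their distance to the focal
#' participant (ascending, ties broken by id order) and cuts the sorted
#' sequence into `m` contiguous, mutually exclusive divisions of nearly
#' equal size: block sizes differ by at most one, with the remainder
#' assigned to the nearest blocks first. Division 1 therefore holds the
#' nearest participants.
#'
#' @param distances Numeric vector of distances from the focal
#'   participant to each reference participant.
#' @param m Number of divisions, between 2 and 10.
#' @param ids Optional ids used for deterministic tie-breaking; defaults
#'   to the element order.
#' @return A list of `m` integer index vectors into `distances`.
#' @export
#' @examples
#' lengths(make_divisions(runif(229), m = 4)) # 58 57 57 57
make_divisions <- function(distances, m, ids = seq_along(distances)) {
  n <- length(distances)
  if (m < 2 || m > 10) stop("division size m must be in [2, 10]",
                            call. = FALSE)
  if (m > n) stop("more divisions than reference participants",
                  call. = FALSE)
  ord <- order(distances, ids)
  sizes <- largest_remainder_first(n, m)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  purrr::map2(starts, ends, function(s, e) ord[s:e])
}

# n = m*q + r: the first r blocks get the extra element.
largest_remainder_first <- function(n, m) {
  q <- n %/% m; r <- n %% m
  rep(c(q + 1L, q), c(r, m - r))
}

#' Derivative information for one participant
#'
#' The four derivative features computed from a selected
#' distance-ranked division of the reference cohort: the participant's
#' own ANN I output; the mean ANN I output over the division; the mean
#' Euclidean distance to the division's members; and the observed
#' proportion of osteoporosis among the division's members. The focal
#' participant's own label is never used.
#'
#' @param distances Distances from the focal participant to each
#'   reference participant (self excluded).
#' @param ann1_self The focal participant's ANN I output.
#' @param ref_outputs ANN I outputs of the reference participants.
#' @param ref_op Logical osteoporosis labels of the reference
#'   participants.
#' @param m Number of divisions.
#' @param d_index Which division to use (1 = nearest).
#' @param ids Optional tie-breaking ids, as in [make_divisions()].
#' @return A named numeric vector `ann1_self`, `div_mean_output`,
#'   `div_mean_dist`, `div_op_prop`.
#' @export
derivative_features <- function(distances, ann1_self, ref_outputs, ref_op,
                                m, d_index, ids = seq_along(distances)) {
  if (d_index < 1 || d_index > m) stop("d_index must be in 1..m",
                                       call. = FALSE)
  div <- make_divisions(distances, m, ids)[[d_index]]
  c(ann1_self = ann1_self,
    div_mean_output = mean(ref_outputs[div]),
    div_mean_dist = mean(distances[div]),
    div_op_prop = mean(ref_op[div]))
}

# Derivative-feature table for many focal rows against one reference.
# dist_mat: n_focal x n_ref; self_mask: optional logical matrix marking
# reference columns to exclude per focal row (leave-self-out).
derivative_table <- function(dist_mat, ann1_focal, ref_outputs, ref_op,
                             ref_ids, m, d_index, self_col = NULL) {
  n <- nrow(dist_mat)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("ann1_self", "div_mean_output",
                                        "div_mean_dist", "div_op_prop")))
  for (i in seq_len(n)) {
    keep <- if (is.null(self_col) || is.na(self_col[i])) {
      seq_len(ncol(dist_mat))
    } else {
      setdiff(seq_len(ncol(dist_mat)), self_col[i])
    }
    out[i, ] <- derivative_features(dist_mat[i, keep], ann1_focal[i],
                                    ref_outputs[keep], ref_op[keep],
                                    m, d_index, ids = ref_ids[keep])
  }
  tibble::as_tibble(out)
}

#' Fit the full DANN (ANN I + derivative ANN II)
#'
#' Builds ANN I with [fit_ann1()], computes every participant's ANN I
#' output and pairwise Euclidean distances in normalized input space,
#' then searches division size `m` (2-10 by default) and division index
#' `d_index` (1..m): each `(m, d_index)` candidate yields a
#' four-column derivative-feature table (leave-self-out against the
#' training reference) on which a candidate ANN II is fitted with the
#' same RBF recipe. Candidates are scored by the Spearman correlation
#' between ANN II output and normalized BMD on the verification set; the
#' argmax becomes ANN II. The full `(m, d_index, rho)` grid is retained
#' for inspection and plotting.
#'
#' @param cohort Training cohort tibble.
#' @param features Model input columns (marker first).
#' @param seed Integer seed.
#' @param m_range Candidate division sizes (subset of 2:10).
#' @param ann1 Optional pre-fitted `ann1_model` (must share the cohort).
#' @param threshold Default risk cut-off on the DANN score; scores below
#'   it call osteoporosis.
#' @param refit_full After the architecture search, refit both networks
#'   (at their selected sizes) on the whole cohort instead of the
#'   training split only. Used by [kfold_cv()], where the holdout
#'   generalization report is not needed and the extra rows sharpen the
#'   fold model; the default `FALSE` preserves the strict holdout
#'   protocol (one quarter of the cohort never touches fitting).
#' @param k_grid,lambda Passed to the RBF fits.
#' @return A `dann_model` with `ann1`, `ann2`, selected `m` and
#'   `d_index`, the search `grid`, a `reference` snapshot (normalized
#'   features, ANN I outputs, osteoporosis labels, ids), the stored
#'   training `scores`, and `rho_full` (Spearman of the training-cohort
#'   DANN scores with BMD).
#' @export
fit_dann <- function(cohort, features, seed, m_range = 2:10, ann1 = NULL,
                     threshold = 0.38, refit_full = FALSE, k_grid = NULL,
                     lambda = 1e-3) {
  validate_cohort(cohort)
  if (any(m_range < 2 | m_range > 10)) {
    stop("m_range must lie within 2..10", call. = FALSE)
  }
  if (is.null(ann1)) {
    ann1 <- fit_ann1(cohort, features, seed, k_grid = k_grid,
                     lambda = lambda)
  }
  n <- nrow(cohort)
  Xn <- as.matrix(normalize_features(ann1$normalization, cohort, features))
  yn <- apply_minmax(ann1$normalization, cohort$bmd, "bmd")
  outputs <- predict(ann1$network, Xn)
  op <- is_osteoporosis(cohort$status)
  dist_mat <- sqrt(sqdist(Xn, Xn))
  split <- ann1$split
  best <- NULL; best_rho <- -Inf
  grid <- list()
  for (m in m_range) {
    for (d_index in seq_len(m)) {
      feats <- derivative_table(dist_mat, outputs, outputs, op,
                                cohort$id, m, d_index,
                                self_col = seq_len(n))
      net <- tryCatch(
        fit_rbf(feats[split$train, ], yn[split$train],
                feats[split$verify, ], yn[split$verify],
                seed = seed + 7L * m + d_index, k_grid = k_grid,
                lambda = lambda),
        error = function(e) NULL)
      rho <- if (is.null(net)) NA_real_ else {
        safe_cor(predict(net, feats[split$verify, ]), yn[split$verify],
                 method = "spearman")
      }
      grid[[length(grid) + 1L]] <- tibble::tibble(m = m, d_index = d_index,
                                                  rho_verify = rho)
      if (!is.na(rho) && rho > best_rho) {
        best_rho <- rho
        best <- list(net = net, m = m, d_index = d_index, feats = feats)
      }
    }
  }
  if (is.null(best)) stop("no ANN II candidate could be fitted",
                          call. = FALSE)
  ann2 <- best$net
  if (refit_full) {
    net1 <- rbf_fit_k(Xn, yn, ann1$network$k, seed = seed + 101L,
                      lambda = lambda)
    if (!is.null(net1)) {
      ann1$network$centers <- net1$centers
      ann1$network$widths <- net1$widths
      ann1$network$weights <- net1$weights
      outputs <- predict(ann1$network, Xn)
    }
    best$feats <- derivative_table(dist_mat, outputs, outputs, op,
                                   cohort$id, best$m, best$d_index,
                                   self_col = seq_len(n))
    net2 <- rbf_fit_k(as.matrix(best$feats), yn, ann2$k,
                      seed = seed + 202L, lambda = lambda)
    if (!is.null(net2)) {
      ann2$centers <- net2$centers
      ann2$widths <- net2$widths
      ann2$weights <- net2$weights
    }
  }
  scores <- predict(ann2, best$feats)
  r_test <- if (length(split$test) > 1) {
    safe_cor(scores[split$test], yn[split$test])
  } else NA_real_
  model <- structure(list(
    ann1 = ann1, ann2 = ann2, m = best$m, d_index = best$d_index,
    grid = dplyr::bind_rows(grid),
    reference = list(features_normalized = Xn, outputs = outputs,
                     op = op, ids = cohort$id),
    features = features, seed = seed, threshold = threshold,
    scores = scores,
    rho_full = safe_cor(scores, cohort$bmd, method = "spearman"),
    r_train = safe_cor(scores[split$train], yn[split$train]),
    r_test = r_test),
    class = "dann_model")
  model
}

#' Score participants with a fitted DANN
#'
#' Normalizes the raw inputs with the training-cohort parameters
#' (clipping out-of-range values), runs ANN I, computes the four
#' derivative features against the stored training reference using the
#' model's selected `(m, d_index)`, and runs ANN II. A participant whose
#' id matches a reference id is scored against the reference without
#' herself, so re-scoring the training cohort reproduces the stored
#' training scores exactly; external participants use the full
#' reference.
#'
#' @param object A `dann_model`.
#' @param newdata Cohort-like data frame with the raw model features
#'   (and optionally `id`).
#' @param type `"score"` for the continuous BMD-like score (higher =
#'   healthier) or `"class"` for the binary call (osteoporosis when the
#'   score falls below the model threshold).
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, or a logical osteoporosis call.
#' @export
predict.dann_model <- function(object, newdata,
                               type = c("score", "class"), ...) {
  type <- match.arg(type)
  Xn <- as.matrix(normalize_features(object$ann1$normalization, newdata,
                                     object$features))
  outputs <- predict(object$ann1$network, Xn)
  ref <- object$reference
  dist_mat <- sqrt(sqdist(Xn, ref$features_normalized))
  self_col <- if ("id" %in% names(newdata)) {
    match(newdata$id, ref$ids)
  } else rep(NA_integer_, nrow(Xn))
  feats <- derivative_table(dist_mat, outputs, ref$outputs, ref$op,
                            ref$ids, object$m, object$d_index,
                            self_col = self_col)
  scores <- predict(object$ann2, feats)
  if (type == "class") scores < object$threshold else scores
}

#' @export
print.dann_model <- function(x, ...) {
  cat("DANN: ANN I ->", sprintf("division (m = %d, index = %d)", x$m,
                                x$d_index), "-> ANN II\n")
  cat(sprintf("  training-cohort Spearman rho(score, BMD) = %.3f\n",
              x$rho_full))
  cat(sprintf("  ANN II holdout R_Tr = %.3f, R_Te = %.3f\n",
              x$r_train, x$r_test))
  cat(sprintf("  risk threshold = %.2f (score below => osteoporosis)\n",
              x$threshold))
  invisible(x)
}
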