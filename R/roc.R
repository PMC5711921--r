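#' Empirical ROC curve
#'
#' Builds the empirical ROC of a continuous score for detecting
#' osteoporosis. Score orientation is explicit, never inferred:
#' `direction = "low"` means a *lower* score indicates the positive
#' class (the convention for BMD-like model outputs, where higher means
#' healthier); `direction = "high"` means a higher score is positive
#' (the convention for the raw marker, which rises as BMD falls). The
#' AUC is the trapezoidal area, identical to the tie-corrected
#' concordance probability.
#'
#' @param scores Numeric vector.
#' @param labels Logical positives, or a bone-status factor (positive =
#'   osteoporosis only).
#' @param direction `"low"` or `"high"`: which end of the score scale is
#'   positive.
#' @return A `roc_result` with `points` (one operating point per
#'   distinct threshold: `threshold`, `se`, `sp`), `auc`, `direction`,
#'   and class counts. For `direction = "low"` a point's rule is
#'   "positive iff score <= threshold"; for `"high"`, ">= threshold".
#' @export
#' @examples
#' r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
#'                direction = "high")
#' r$auc
roc_curve <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (!is.logical(labels)) labels <- is_osteoporosis(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  # risk-oriented score: higher = more positive
  risk <- if (direction == "low") -scores else scores
  auc <- (mean(rank(risk)[labels]) - (n_pos + 1) / 2) / n_neg
  thr <- sort(unique(scores), decreasing = (direction == "low"))
  # sweep thresholds from the most permissive end
  se <- vapply(thr, function(t) {
    if (direction == "low") mean(scores[labels] <= t) else
      mean(scores[labels] >= t)
  }, numeric(1))
  sp <- vapply(thr, function(t) {
    if (direction == "low") mean(scores[!labels] > t) else
      mean(scores[!labels] < t)
  }, numeric(1))
  points <- tibble::tibble(threshold = thr, se = se, sp = sp)
  structure(list(points = points, auc = auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg,
                 positive = "osteoporosis"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  opt <- optimal_cutoff(x)
  cat(sprintf("ROC (%d positive / %d negative, %s score = positive)\n",
              x$n_pos, x$n_neg,
              if (x$direction == "low") "low" else "high"))
  cat(sprintf("  AUC = %.3f\n", x$auc))
  cat(sprintf("  Youden-optimal cut-off %.3g: SE = %.2f, SP = %.2f\n",
              opt$threshold, opt$se, opt$sp))
  cat(sprintf("  SE at SP >= 0.9: %.2f\n", se_at_fixed_sp(x, 0.9)))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Maximizes the Youden index `J = SE + SP - 1` over the empirical
#' operating points; ties are broken toward higher specificity.
#'
#' @param roc A `roc_result`.
#' @return A one-row tibble `threshold`, `se`, `sp`, `youden`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points
  j <- p$se + p$sp - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(p$sp[best])]
  tibble::tibble(threshold = p$threshold[best], se = p$se[best],
                 sp = p$sp[best], youden = j[best])
}

#' Sensitivity at fixed specificity
#'
#' The maximum sensitivity over achievable empirical operating points
#' with specificity at least `sp_min` (step rule, no interpolation).
#'
#' @param roc A `roc_result`.
#' @param sp_min Specificity floor (default 0.9).
#' @return Sensitivity (0 if no non-trivial point attains the floor).
#' @export
se_at_fixed_sp <- function(roc, sp_min = 0.9) {
  stopifnot(inherits(roc, "roc_result"))
  ok <- roc$points$sp >= sp_min
  if (!any(ok)) return(0)
  max(roc$points$se[ok])
}

#' Classification accuracy at a fixed risk threshold
#'
#' For BMD-like scores (low = risk): the fraction of participants for
#' whom `score < threshold` agrees with the osteoporosis label.
#'
#' @param scores BMD-like scores (higher = healthier).
#' @param labels Logical positives or bone-status factor.
#' @param threshold Risk cut-off (default 0.38).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_at_threshold <- function(scores, labels, threshold = 0.38) {
  if (!is.logical(labels)) labels <- is_osteoporosis(labels)
  mean((scores < threshold) == labels)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using
#' the DeLong placement-value covariance estimate and a two-sided normal
#' reference. Each score carries its own orientation, so a BMD-like
#' model output can be compared directly against a risk-like marker.
#'
#' @param scores1,scores2 Paired numeric scores.
#' @param labels Logical positives or bone-status factor.
#' @param direction1,direction2 Orientation of each score
#'   (see [roc_curve()]).
#' @return A `delong_comparison` list: `auc1`, `auc2`, `delta`,
#'   `variance`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels,
                        direction1 = "low", direction2 = "low") {
  if (!is.logical(labels)) labels <- is_osteoporosis(labels)
  stopifnot(length(scores1) == length(labels),
            length(scores2) == length(labels))
  orient <- function(s, d) if (d == "low") -s else s
  X <- cbind(orient(scores1, direction1), orient(scores2, direction2))
  pos <- X[labels, , drop = FALSE]
  neg <- X[!labels, , drop = FALSE]
  m <- nrow(pos); n <- nrow(neg)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  auc <- numeric(2)
  V10 <- matrix(0, m, 2); V01 <- matrix(0, n, 2)
  for (r in 1:2) {
    P <- outer(pos[, r], neg[, r], psi)
    auc[r] <- mean(P)
    V10[, r] <- rowMeans(P)
    V01[, r] <- colMeans(P)
  }
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  delta <- auc[1] - auc[2]
  z <- if (delta == 0) 0 else delta / sqrt(max(v, .Machine$double.eps))
  p <- if (delta == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(auc1 = auc[1], auc2 = auc[2], delta = delta,
                 variance = v, z = z, p = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.3f vs %.3f (delta %.3f)\n",
              x$auc1, x$auc2, x$delta))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}
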