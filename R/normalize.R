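#' Fit per-feature min-max normalization on a reference cohort
#'
#' Model inputs and the BMD target are normalized into the unit interval
#' before network fitting. Parameters are learned once on a reference
#' (training) cohort and reused, with clipping, for any external cohort.
#'
#' @param data Data frame holding the features (a cohort tibble).
#' @param features Character vector of column names to fit. Each feature
#'   needs at least two distinct non-missing values; a constant feature is
#'   refused rather than silently dividing by zero.
#' @return A `minmax_params` tibble with columns `feature`, `min`, `max`.
#' @export
#' @examples
#' p <- fit_minmax(data.frame(x = c(2, 5, 10)), "x")
#' apply_minmax(p, 5, "x")
fit_minmax <- function(data, features) {
  stopifnot(is.data.frame(data), is.character(features), length(features) > 0)
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0L) {
    stop("feature(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  params <- purrr::map_dfr(features, function(f) {
    v <- data[[f]][!is.na(data[[f]])]
    if (length(unique(v)) < 2L) {
      stop("degenerate feature '", f, "': fewer than 2 distinct values",
           call. = FALSE)
    }
    tibble::tibble(feature = f, min = min(v), max = max(v))
  })
  class(params) <- c("minmax_params", class(params))
  params
}

#' Apply min-max normalization to values of one feature
#'
#' Computes `(value - min) / (max - min)` and clips to `[0, 1]`, so
#' external-cohort values outside the reference range remain valid
#' network inputs.
#'
#' @param params A `minmax_params` object from [fit_minmax()].
#' @param value Numeric vector to normalize.
#' @param feature Feature name; must have been fitted.
#' @return Numeric vector in `[0, 1]` (missing values stay missing).
#' @export
apply_minmax <- function(params, value, feature) {
  row <- params[params$feature == feature, ]
  if (nrow(row) != 1L) {
    stop("no normalization parameters fitted for feature '", feature, "'",
         call. = FALSE)
  }
  pmin(pmax((value - row$min) / (row$max - row$min), 0), 1)
}

#' Normalize several cohort columns at once
#'
#' @inheritParams apply_minmax
#' @param data Data frame containing every fitted feature.
#' @param features Features to normalize; default all fitted features.
#' @return A tibble of the normalized features, same row order as `data`.
#' @export
normalize_features <- function(params, data, features = params$feature) {
  out <- purrr::map(features, function(f) apply_minmax(params, data[[f]], f))
  names(out) <- features
  tibble::as_tibble(out)
}
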