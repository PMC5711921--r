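#' Read a cohort table from delimited text
#'
#' Reads a comma-separated cohort file with one row per participant and
#' columns `id`, `mir194` (relative miR-194-5p expression, 2^-ddCT units),
#' the examination items named in the registry, `bmd` (lumbar L1-L4 areal
#' density, g/cm^2) and `t_score` (SD units). Missing examination-item
#' values are encoded as empty fields; non-numeric cells in numeric
#' columns become missing with a warning. `id` must be unique and `bmd`,
#' `mir194`, `t_score` must be complete.
#'
#' @param path Path to a CSV file with a header row.
#' @param registry Item registry tibble; defaults to
#'   [default_item_registry()]. EI columns in the file that are absent
#'   from the registry are a schema error.
#' @param provenance Optional provenance tag stored as an attribute.
#' @return A validated cohort tibble with a `status` factor column added
#'   by [classify_bone_status()].
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path, registry = default_item_registry(),
                        provenance = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) stop("cohort file has no participants", call. = FALSE)
  core <- cohort_core_columns()
  missing_core <- setdiff(core, names(raw))
  if (length(missing_core) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_core, collapse = ", "),
         call. = FALSE)
  }
  ei_cols <- setdiff(names(raw), core)
  unknown <- setdiff(ei_cols, registry$item)
  if (length(unknown) > 0L) {
    stop("examination item(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate participant id: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("mir194", "bmd", "t_score", ei_cols)
  out <- raw
  n_bad <- 0L
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(vals)
    n_bad <- n_bad + sum(bad)
    out[[col]] <- vals
  }
  if (n_bad > 0L) {
    warning(n_bad, " non-numeric cell(s) set to missing", call. = FALSE)
  }
  validate_cohort(out)
  out$status <- classify_bone_status(out$t_score)
  out <- dplyr::relocate(out, "id", "mir194",
                         dplyr::all_of(intersect(registry$item, ei_cols)),
                         "bmd", "t_score", "status")
  if (!is.null(provenance)) attr(out, "provenance") <- provenance
  out
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: numeric fields round-trip within
#' decimal-text precision. The derived `status` column is not written.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[setdiff(names(cohort), "status")]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  for (col in cohort_core_columns()) {
    if (!col %in% names(cohort)) {
      stop("missing mandatory column: ", col, call. = FALSE)
    }
  }
  if (anyDuplicated(cohort$id)) stop("duplicate participant id", call. = FALSE)
  if (anyNA(cohort$bmd) || any(cohort$bmd <= 0)) {
    stop("bmd must be present and positive for every participant",
         call. = FALSE)
  }
  if (anyNA(cohort$mir194) || any(cohort$mir194 < 0)) {
    stop("mir194 must be present and non-negative", call. = FALSE)
  }
  if (anyNA(cohort$t_score)) stop("t_score must be present", call. = FALSE)
  invisible(cohort)
}

cohort_ei_columns <- function(cohort) {
  setdiff(names(cohort), c(cohort_core_columns(), "status"))
}

#' Classify bone status from the spine T-score
#'
#' Applies the WHO diagnostic cuts: T-score > -1.0 is normal bone mass,
#' -2.5 < T-score <= -1.0 is osteopenia, and T-score <= -2.5 is
#' osteoporosis. Each boundary belongs to the lower-BMD class, so -2.5
#' classifies as osteoporosis and -1.0 as osteopenia.
#'
#' @param t_score Numeric vector of T-scores (SD units); must be finite.
#' @return A factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @export
#' @examples
#' classify_bone_status(c(0.3, -1.0, -2.5))
classify_bone_status <- function(t_score) {
  if (!is.numeric(t_score) || any(!is.finite(t_score))) {
    stop("t_score must be finite numeric", call. = FALSE)
  }
  cut(t_score, breaks = c(-Inf, -2.5, -1.0, Inf),
      labels = c("osteoporosis", "osteopenia", "normal"),
      right = TRUE) |>
    factor(levels = c("normal", "osteopenia", "osteoporosis"))
}

#' Binary osteoporosis risk label
#'
#' The ROC positive class throughout the package is osteoporosis only;
#' osteopenia counts as negative.
#'
#' @param status Factor from [classify_bone_status()], or a T-score vector.
#' @return Logical vector, `TRUE` for osteoporosis.
#' @export
is_osteoporosis <- function(status) {
  if (is.numeric(status)) status <- classify_bone_status(status)
  status == "osteoporosis"
}
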