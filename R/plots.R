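#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot: the empirical ROC with the chance diagonal and the
#'   Youden-optimal operating point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$sp, .data$se)
  pts <- dplyr::bind_rows(tibble::tibble(threshold = NA, se = 0, sp = 1),
                          pts,
                          tibble::tibble(threshold = NA, se = 1, sp = 0))
  opt <- optimal_cutoff(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = tibble::tibble(sp = opt$sp, se = opt$se),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot screening results as a correlation profile
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot of per-item Spearman rho, BMD-correlated items
#'   highlighted.
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- dplyr::mutate(tidy(object),
                      item = factor(.data$item, levels = .data$item))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$rho,
                                   fill = .data$bmd_correlated)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.1, 0.1), linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = "BMD-correlated") +
    ggplot2::labs(x = NULL, y = "Spearman rho with spine BMD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the DANN division-search profile
#'
#' Per division size `m`, the best verification-set Spearman rho over
#' the division indices, with the selected `m` marked.
#'
#' @param object A `dann_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dann_model <- function(object, ...) {
  prof <- dplyr::summarise(dplyr::group_by(object$grid, .data$m),
                           rho = max(abs(.data$rho_verify), na.rm = TRUE),
                           .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$m, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$m, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_continuous(breaks = unique(prof$m)) +
    ggplot2::labs(x = "division size m",
                  y = "best |rho| (verification set)") +
    ggplot2::theme_minimal()
}

#' Density-peak decision plot
#'
#' The Rodriguez-Laio decision graph: local density rho against delta,
#' centres highlighted.
#'
#' @param object A `density_peak` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_peak <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho, y = .data$delta,
                                       colour = .data$is_center)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "grey40"),
                                 name = "centre") +
    ggplot2::labs(x = "local density rho", y = "delta") +
    ggplot2::theme_minimal()
}
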