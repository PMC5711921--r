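#' Pipeline run configuration
#'
#' Bundles every tunable constant of the end-to-end analysis with its
#' study default: the screening rule (`|rho| > 0.1`, `p < 0.01`), the
#' collinearity threshold (0.3), the PPSN edge threshold (0.198), the
#' division-size range (2-10), the specificity floor (0.9), and the
#' risk cut-off (0.38).
#'
#' @param cohort Optional cohort tibble; when `NULL` a synthetic cohort
#'   from `sim_config` is generated.
#' @param external Optional external-validation cohort tibble.
#' @param sim_config A [cohort_sim_config()] for synthetic input.
#' @param seed Master seed; per-stage seeds are derived from it by
#'   stage-name hashing so stages can be re-run in isolation.
#' @param mode Feature-selection mode, see [select_model_inputs()].
#' @param n_ei Number of examination items in the model.
#' @param rho_threshold,p_threshold,collinearity_threshold,ppsn_threshold,sp_floor,risk_threshold
#'   Analysis constants (study defaults).
#' @param m_range Division sizes searched for ANN II.
#' @param cv_folds Folds for [kfold_cv()]; 0 skips cross-validation.
#' @param out_dir Output directory for artifacts; `NULL` for none.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, external = NULL,
                            sim_config = cohort_sim_config(), seed = 1,
                            mode = "noncollinear", n_ei = 5,
                            rho_threshold = 0.1, p_threshold = 0.01,
                            collinearity_threshold = 0.3,
                            ppsn_threshold = 0.198, sp_floor = 0.9,
                            risk_threshold = 0.38, m_range = 2:10,
                            cv_folds = 10, out_dir = NULL) {
  structure(list(cohort = cohort, external = external,
                 sim_config = sim_config, seed = seed, mode = mode,
                 n_ei = n_ei, rho_threshold = rho_threshold,
                 p_threshold = p_threshold,
                 collinearity_threshold = collinearity_threshold,
                 ppsn_threshold = ppsn_threshold, sp_floor = sp_floor,
                 risk_threshold = risk_threshold, m_range = m_range,
                 cv_folds = cv_folds, out_dir = out_dir),
            class = "pipeline_config")
}

# Deterministic per-stage seed derived from the master seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + h * 131L) %% 2147483587L
}

#' Run the end-to-end analysis
#'
#' Executes, in order: cohort intake (or simulation), Spearman
#' screening and collinearity, model-input selection, ANN I fitting
#' with the 2:1:1 holdout, the DANN division search, the
#' patient-similarity network with density-peak clustering, ROC
#' evaluation of the raw marker and of the DANN score (including the
#' DeLong paired comparison), optional k-fold cross-validation, and
#' optional external-cohort validation at the fixed risk threshold.
#' When `config$out_dir` is set, artifacts (cohort CSV, screening and
#' collinearity CSVs, the hyperparameter grid CSV, the PPSN GraphML,
#' cluster table, and a metrics JSON) are written together with a run
#' manifest listing every file with its MD5 content hash. Runs are
#' idempotent per `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with components `cohort`,
#'   `screening`, `collinearity`, `features`, `ann1`, `dann`, `ppsn`,
#'   `clusters`, `marker_roc`, `dann_roc`, `delong`, `cv`, `external`,
#'   `metrics`, and `manifest` (when writing).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$sim_config$n,
                              seed = stage_seed(config$seed, "simulate"),
                              config = config$sim_config)
  }
  screening <- screen_items(cohort, rho_threshold = config$rho_threshold,
                            p_threshold = config$p_threshold)
  coll <- collinearity_matrix(cohort,
                              items = c("mir194",
                                        screening$item[screening$bmd_correlated &
                                                         screening$item != "mir194"]),
                              threshold = config$collinearity_threshold)
  features <- select_model_inputs(screening, coll, mode = config$mode,
                                  n_ei = config$n_ei)
  dann <- fit_dann(cohort, features,
                   seed = stage_seed(config$seed, "dann"),
                   m_range = config$m_range,
                   threshold = config$risk_threshold)
  ppsn <- build_ppsn(cohort, features, threshold = config$ppsn_threshold,
                     normalization = dann$ann1$normalization)
  Xn <- dann$reference$features_normalized
  clusters <- density_peak(sqrt(sqdist(Xn, Xn)),
                           d_c = config$ppsn_threshold)
  marker_roc <- roc_curve(cohort$mir194, cohort$status, direction = "high")
  dann_roc <- roc_curve(dann$scores, cohort$status, direction = "low")
  delong <- delong_test(cohort$mir194, dann$scores, cohort$status,
                        direction1 = "high", direction2 = "low")
  cv <- if (config$cv_folds >= 2) {
    kfold_cv(cohort, features, k = config$cv_folds,
             seed = stage_seed(config$seed, "crossval"),
             m_range = config$m_range)
  }
  external <- if (!is.null(config$external)) {
    ext_scores <- predict(dann, config$external)
    list(scores = ext_scores,
         accuracy = accuracy_at_threshold(ext_scores,
                                          config$external$status,
                                          config$risk_threshold),
         rho = safe_cor(ext_scores, config$external$bmd,
                        method = "spearman"))
  }
  marker_opt <- optimal_cutoff(marker_roc)
  dann_opt <- optimal_cutoff(dann_roc)
  metrics <- list(
    n = nrow(cohort),
    status_counts = as.list(table(cohort$status)),
    features = features,
    marker_rho = screening$rho[screening$item == "mir194"],
    n_bmd_correlated_ei = sum(screening$bmd_correlated &
                                screening$item != "mir194"),
    ann1_r_train = dann$ann1$r_train, ann1_r_test = dann$ann1$r_test,
    dann_m = dann$m, dann_d_index = dann$d_index,
    dann_rho = dann$rho_full,
    marker_auc = marker_roc$auc, dann_auc = dann_roc$auc,
    marker_se_optimal = marker_opt$se, marker_sp_optimal = marker_opt$sp,
    dann_se_optimal = dann_opt$se, dann_sp_optimal = dann_opt$sp,
    dann_optimal_threshold = dann_opt$threshold,
    marker_se_at_sp = se_at_fixed_sp(marker_roc, config$sp_floor),
    dann_se_at_sp = se_at_fixed_sp(dann_roc, config$sp_floor),
    delong_p = delong$p,
    cv_rho = if (!is.null(cv)) cv$rho else NULL,
    cv_auc = if (!is.null(cv) && !is.null(cv$roc)) cv$roc$auc else NULL,
    external_accuracy = if (!is.null(external)) external$accuracy else NULL)
  result <- list(cohort = cohort, screening = screening,
                 collinearity = coll, features = features,
                 ann1 = dann$ann1, dann = dann, ppsn = ppsn,
                 clusters = clusters, marker_roc = marker_roc,
                 dann_roc = dann_roc, delong = delong, cv = cv,
                 external = external, metrics = metrics,
                 config = config)
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_artifacts(result, config$out_dir)
  }
  class(result) <- "pipeline_result"
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)
  write_cohort(result$cohort, fp("cohort.csv"))
  sc <- attr(result$cohort, "sim_config")
  if (!is.null(sc)) {
    jsonlite::write_json(
      list(n = sc$n, class_proportions = as.list(sc$class_proportions),
           target_spearman = as.list(sc$target_spearman)),
      fp("cohort_sim_params.json"), auto_unbox = TRUE, digits = NA)
  }
  readr::write_csv(tibble::as_tibble(result$screening), fp("screening.csv"),
                   progress = FALSE)
  utils::write.csv(result$collinearity$abs_rho, fp("collinearity.csv"))
  readr::write_csv(result$dann$grid, fp("dann_grid.csv"), progress = FALSE)
  export_graph(result$ppsn, fp("ppsn.graphml"), format = "graphml")
  readr::write_csv(
    dplyr::mutate(tibble::as_tibble(result$clusters),
                  id = result$cohort$id),
    fp("clusters.csv"), progress = FALSE)
  jsonlite::write_json(result$metrics, fp("metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("osteomir")),
    files = purrr::map(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat("osteomir pipeline run (n =", m$n, ")\n")
  cat("  model inputs:", paste(m$features, collapse = ", "), "\n")
  cat(sprintf("  marker: rho = %.3f, AUC = %.3f, SE@SP>=%.2f = %.2f\n",
              m$marker_rho, m$marker_auc, x$config$sp_floor,
              m$marker_se_at_sp))
  cat(sprintf("  DANN (m = %d): rho = %.3f, AUC = %.3f, SE@SP>=%.2f = %.2f\n",
              m$dann_m, m$dann_rho, m$dann_auc, x$config$sp_floor,
              m$dann_se_at_sp))
  if (!is.null(m$cv_rho)) {
    cat(sprintf("  %d-fold CV: rho = %.3f, AUC = %.3f\n",
                x$config$cv_folds, m$cv_rho, m$cv_auc))
  }
  if (!is.null(m$external_accuracy)) {
    cat(sprintf("  external validation accuracy = %.1f%%\n",
                100 * m$external_accuracy))
  }
  invisible(x)
}
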