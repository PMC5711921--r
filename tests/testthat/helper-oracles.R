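# Independent oracles and small fixture builders used across the suite.

# Brute-force concordance probability: ties between a positive and a
# negative score count one half.
auc_concordance <- function(scores, labels, direction = "low") {
  risk <- if (direction == "low") -scores else scores
  pos <- risk[labels]; neg <- risk[!labels]
  P <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(P)
}

# Trapezoidal area under the empirical ROC step curve, computed from the
# operating points only (third, independent route to the AUC).
auc_trapezoid <- function(points) {
  ord <- order(1 - points$sp, points$se) # follow the ROC path at corners
  fpr <- c(0, (1 - points$sp)[ord], 1)
  tpr <- c(0, points$se[ord], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Paired permutation oracle for the DeLong test: under the null the two
# markers are exchangeable within each subject, so each subject's pair
# of (risk-oriented) scores is swapped with probability one half.
delong_permutation_p <- function(scores1, scores2, labels,
                                 direction1 = "low", direction2 = "low",
                                 n_perm = 10000, seed = 1) {
  orient <- function(s, d) if (d == "low") -s else s
  a <- orient(scores1, direction1); b <- orient(scores2, direction2)
  auc_of <- function(x) {
    (mean(rank(x)[labels]) - (sum(labels) + 1) / 2) / sum(!labels)
  }
  obs <- abs(auc_of(a) - auc_of(b))
  withr::with_seed(seed, {
    hits <- 0L
    n <- length(a)
    for (i in seq_len(n_perm)) {
      swap <- stats::runif(n) < 0.5
      a2 <- ifelse(swap, b, a); b2 <- ifelse(swap, a, b)
      if (abs(auc_of(a2) - auc_of(b2)) >= obs - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  })
}

# Minimal valid cohort tibble around given feature columns.
toy_cohort <- function(features, t_score = NULL, bmd = NULL) {
  n <- nrow(features)
  if (is.null(t_score)) t_score <- seq(-3, 1, length.out = n)
  if (is.null(bmd)) bmd <- seq(0.6, 1.1, length.out = n)
  out <- tibble::tibble(id = sprintf("T%03d", seq_len(n)),
                        mir194 = seq(0.5, 2.5, length.out = n),
                        bmd = bmd, t_score = t_score)
  out <- dplyr::bind_cols(out, features)
  out$status <- classify_bone_status(out$t_score)
  out
}

# Small simulated cohorts shared by several expensive tests (memoised
# per-session so repeated calls are free).
sim_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed, config = cohort_sim_config()) {
  key <- paste0("n", n, "s", seed, "p",
                paste(round(config$class_proportions, 3), collapse = "_"))
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_cohort(n, seed = seed, config = config)
  }
  sim_cache[[key]]
}

external_cohort_config <- function(n = 30) {
  cohort_sim_config(n = n,
                    class_proportions = c(normal = 0.400,
                                          osteopenia = 0.267,
                                          osteoporosis = 0.333),
                    id_prefix = "Q")
}

# Screening + collinearity + feature selection in one step.
select_features <- function(cohort, n_ei = 5) {
  scr <- screen_items(cohort)
  cand <- scr$item[scr$bmd_correlated & scr$item != "mir194"]
  if (length(cand) == 0L) {
    return(suppressWarnings(select_model_inputs(scr, NULL)))
  }
  cmx <- collinearity_matrix(cohort, c("mir194", cand))
  select_model_inputs(scr, cmx, n_ei = n_ei)
}

# Seed-mean calibration of the planted Spearman targets, memoised.
calib_store <- new.env(parent = emptyenv())
calib_rhos <- function(n_seeds = 200) {
  key <- paste0("k", n_seeds)
  if (is.null(calib_store[[key]])) {
    calib_store[[key]] <- vapply(seq_len(n_seeds), function(s) {
      co <- cached_cohort(230, seed = s)
      c(marker = cor(co$mir194, co$bmd, method = "spearman"),
        pair = abs(cor(co$LVDS, co$LVEDD, method = "spearman")),
        weight = cor(co$weight, co$bmd, method = "spearman"))
    }, numeric(3))
  }
  calib_store[[key]]
}
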