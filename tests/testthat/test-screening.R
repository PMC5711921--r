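test_that("spearman_test matches the hand rank formula and is rank-invariant", {
  st <- spearman_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(st$rho, 0.8) # 1 - 6 * 4 / (5 * 24)
  expect_equal(st$n, 5)
  # strictly monotone transforms of either argument leave rho unchanged
  x <- withr::with_seed(1, runif(30)); y <- withr::with_seed(2, runif(30))
  rho0 <- spearman_test(x, y)$rho
  for (f in list(function(v) exp(v), function(v) v^3 + 2,
                 function(v) rank(v))) {
    expect_equal(spearman_test(f(x), y)$rho, rho0)
    expect_equal(spearman_test(x, f(y))$rho, rho0)
  }
  expect_equal(spearman_test(x, exp(x))$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  expect_error(spearman_test(1:3, 3:1), "at least 4")
  expect_error(spearman_test(rep(1, 10), 1:10), "zero variance")
  # pairwise-complete filtering
  xm <- c(x, NA); ym <- c(y, 1)
  expect_equal(spearman_test(xm, ym)$n, 30)
})

test_that("t-approximation p-values agree with the permutation reference", {
  x <- withr::with_seed(3, rnorm(40))
  y <- 0.4 * x + withr::with_seed(4, rnorm(40))
  p_t <- spearman_test(x, y)$p
  p_perm <- spearman_test(x, y, method = "permutation", n_perm = 20000,
                          seed = 9)$p
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("correlation bands use the reconstructed cut-points", {
  expect_equal(as.character(band_of(c(0.05, -0.365, 0.649, 0.15, 0.85, 0))),
               c("none", "weak", "moderate", "extremely-weak", "strong",
                 "none"))
  # boundary values belong to the upper band (left-closed intervals)
  expect_equal(as.character(band_of(c(0.1, 0.2, 0.4, 0.7))),
               c("extremely-weak", "weak", "moderate", "strong"))
  expect_error(band_of(1.5), "<= 1")
})

test_that("screen_items flags by the joint |rho| and p rule in stable order", {
  cohort <- cached_cohort(230, seed = 1)
  scr <- screen_items(cohort)
  expect_equal(scr$item, c("mir194", default_item_registry()$item))
  expect_true(all(scr$valid))
  # the flag is exactly the |rho| > 0.1 & p < 0.01 rule
  expect_equal(scr$bmd_correlated, abs(scr$rho) > 0.1 & scr$p < 0.01)
  # strongly planted items are recovered
  flagged <- scr$item[scr$bmd_correlated]
  expect_true(all(c("mir194", "age", "weight") %in% flagged))
  # a constant item is reported invalid, not dropped
  broken <- cohort
  broken$EF <- 1
  scr2 <- screen_items(broken)
  expect_false(scr2$valid[scr2$item == "EF"])
  expect_false(scr2$bmd_correlated[scr2$item == "EF"])
  expect_equal(as.character(scr2$band[scr2$item == "EF"]), "none")
})

test_that("collinearity matrices are symmetric with unit diagonal", {
  cohort <- cached_cohort(230, seed = 1)
  cm <- collinearity_matrix(cohort, c("mir194", "age", "LVDS", "LVEDD"))
  expect_equal(cm$abs_rho, t(cm$abs_rho))
  expect_equal(unname(diag(cm$abs_rho)), rep(1, 4))
  expect_true(cm$flagged["LVDS", "LVEDD"]) # planted rho 0.63
  expect_false(any(diag(cm$flagged)))
  expect_true(all(cm$abs_rho >= 0 & cm$abs_rho <= 1))
})

test_that("independent items are almost never flagged collinear", {
  hits <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(230))
    y <- withr::with_seed(s + 500, rnorm(230))
    abs(spearman_test(x, y)$rho) > 0.3
  }, logical(1))
  expect_equal(sum(hits), 0)
})

test_that("feature selection ranks by |rho| and prunes collinear inputs", {
  records <- tibble::tibble(
    item = c("mir194", "weight", "age", "LVDS", "LVEDD", "ALT", "U_EC"),
    rho = c(-0.365, 0.28, -0.26, -0.19, -0.185, -0.18, -0.17),
    p = rep(0.001, 7), n = 230,
    band = band_of(c(-0.365, 0.28, -0.26, -0.19, -0.185, -0.18, -0.17)),
    bmd_correlated = TRUE, valid = TRUE)
  m <- diag(6)
  dimnames(m) <- list(records$item[-1], records$item[-1])
  m["LVDS", "LVEDD"] <- m["LVEDD", "LVDS"] <- 0.63
  cm <- structure(list(abs_rho = m, flagged = m > 0.3 & m < 1,
                       threshold = 0.3), class = "collinearity_matrix")
  expect_equal(select_model_inputs(records, cm, "noncollinear", n_ei = 5),
               c("mir194", "weight", "age", "LVDS", "ALT", "U_EC"))
  expect_equal(select_model_inputs(records, cm, "collinear", n_ei = 5),
               c("mir194", "weight", "age", "LVDS", "LVEDD", "ALT"))
  # single candidate comes through unchanged in either mode
  one <- records[records$item %in% c("mir194", "weight"), ]
  expect_equal(select_model_inputs(one, cm, "noncollinear"),
               c("mir194", "weight"))
  expect_equal(select_model_inputs(one, cm, "collinear"),
               c("mir194", "weight"))
  # no candidate at all -> marker-only model with a warning
  none <- records
  none$bmd_correlated <- c(TRUE, rep(FALSE, 6))
  expect_warning(sel <- select_model_inputs(none, cm), "marker-only")
  expect_equal(sel, "mir194")
})

test_that("per-item false-flag rate under the null stays near the nominal level", {
  # all-null examination items at n = 230: the joint rule is dominated by
  # p < 0.01, so about 1% of items should be flagged
  null_cfg <- cohort_sim_config(target_spearman = c(mir194 = -0.365),
                                collinear_pairs = list())
  flags <- 0L; total <- 0L
  for (s in 101:110) {
    co <- simulate_cohort(230, seed = s, config = null_cfg)
    scr <- screen_items(co)
    ei <- scr[scr$item != "mir194", ]
    flags <- flags + sum(ei$bmd_correlated)
    total <- total + nrow(ei)
  }
  expect_lte(flags / total, 0.025) # 1% nominal + Monte-Carlo slack
})
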