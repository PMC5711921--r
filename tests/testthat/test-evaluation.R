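test_that("ROC analysis matches hand-enumerated operating points", {
  # higher score = positive; positives are 0.35 and 0.8
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
                 direction = "high")
  expect_equal(r$auc, 0.75) # 3 of 4 concordant pairs
  # perfect separation in either orientation
  perfect <- roc_curve(c(1, 2, 3, 10, 11), c(rep(FALSE, 3), rep(TRUE, 2)),
                       direction = "high")
  expect_equal(perfect$auc, 1)
  expect_equal(optimal_cutoff(perfect)$se, 1)
  expect_equal(optimal_cutoff(perfect)$sp, 1)
  expect_equal(se_at_fixed_sp(perfect, 0.9), 1)
  flipped <- roc_curve(-c(1, 2, 3, 10, 11), c(rep(FALSE, 3), rep(TRUE, 2)),
                       direction = "low")
  expect_equal(flipped$auc, 1)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("six-point fixture: Youden tie-break and sensitivity at fixed specificity", {
  scores <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_curve(scores, labels, direction = "high")
  expect_equal(r$auc, 8 / 9)
  opt <- optimal_cutoff(r)
  # J = 2/3 at both t = 0.8 (SP 1) and t = 0.3 (SP 2/3): tie goes to SP 1
  expect_equal(opt$threshold, 0.8)
  expect_equal(opt$se, 2 / 3)
  expect_equal(opt$sp, 1)
  expect_equal(se_at_fixed_sp(r, 0.9), 2 / 3)
  expect_equal(se_at_fixed_sp(r, 0.5), 1)
  # non-increasing in the specificity floor
  floors <- seq(0, 1, by = 0.1)
  ses <- vapply(floors, function(f) se_at_fixed_sp(r, f), numeric(1))
  expect_true(all(diff(ses) <= 0))
})

test_that("the AUC equals brute-force concordance and the trapezoid area", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(10:200, 1))
    scores <- withr::with_seed(s + 100, round(runif(n), 2)) # force ties
    labels <- withr::with_seed(s + 200, runif(n) < 0.3)
    if (!any(labels) || all(labels)) next
    for (dir in c("low", "high")) {
      r <- roc_curve(scores, labels, direction = dir)
      expect_equal(r$auc, auc_concordance(scores, labels, dir))
      expect_equal(r$auc, auc_trapezoid(r$points))
    }
  }
})

test_that("accuracy at a fixed risk threshold counts agreement with the label", {
  scores <- c(0.2, 0.5, 0.3, 0.9)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(accuracy_at_threshold(scores, labels, 0.38), 1)
  expect_equal(accuracy_at_threshold(scores, !labels, 0.38), 0)
  # threshold below all scores calls everyone negative
  expect_equal(accuracy_at_threshold(scores, labels, 0.05),
               mean(!labels))
})

test_that("the DeLong test is exact under identity and monotone transforms", {
  scores <- withr::with_seed(41, rnorm(40))
  labels <- withr::with_seed(42, runif(40) < 0.4)
  d0 <- delong_test(scores, scores, labels, "low", "low")
  expect_equal(d0$delta, 0)
  expect_equal(d0$p, 1)
  # monotone rescaling changes neither AUC
  d1 <- delong_test(scores, exp(scores), labels, "low", "low")
  expect_equal(d1$delta, 0)
  # antisymmetry in the argument order
  other <- withr::with_seed(43, scores + rnorm(40))
  a <- delong_test(scores, other, labels, "low", "low")
  b <- delong_test(other, scores, labels, "low", "low")
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_gt(a$variance, 0)
})

test_that("DeLong p-values agree with the paired permutation oracle at n = 30", {
  labels <- rep(c(TRUE, FALSE), c(10, 20))
  truth <- as.numeric(labels)
  s1 <- truth + withr::with_seed(51, rnorm(30, sd = 1.2))
  s2 <- 0.5 * truth + withr::with_seed(52, rnorm(30, sd = 1.2))
  d <- delong_test(s1, s2, labels, "high", "high")
  p_perm <- delong_permutation_p(s1, s2, labels, "high", "high",
                                 n_perm = 10000, seed = 5)
  expect_lt(abs(d$p - p_perm), 0.02)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  scores1 <- withr::with_seed(61, rnorm(60))
  labels <- withr::with_seed(62, runif(60) < 0.4)
  scores2 <- scores1 * 0.3 + withr::with_seed(63, rnorm(60))
  ours <- delong_test(scores1, scores2, labels, "high", "high")
  ref <- pROC::roc.test(
    pROC::roc(labels, scores1, direction = "<", quiet = TRUE),
    pROC::roc(labels, scores2, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(ours$auc1, as.numeric(ref$estimate[1]), tolerance = 1e-8)
  expect_equal(ours$auc2, as.numeric(ref$estimate[2]), tolerance = 1e-8)
})

test_that("the omnibus normality statistic reproduces reference values", {
  x <- c(1.2, 3.4, 0.5, 2.2, 8.9, 1.1, 0.3, 4.4, 2.0, 1.7, 0.9, 5.1,
         2.8, 0.6, 1.4, 3.0, 7.2, 0.8, 2.5, 1.9, 6.3, 0.4, 1.0, 2.1)
  r <- dagostino_pearson(x)
  expect_equal(r$skewness, 1.368445957217712, tolerance = 1e-12)
  expect_equal(r$kurtosis, 4.057756128567775, tolerance = 1e-12)
  expect_equal(r$z_skewness, 2.8192957486215344, tolerance = 1e-9)
  expect_equal(r$z_kurtosis, 1.5878214356353397, tolerance = 1e-9)
  expect_equal(r$k2, 10.469605429658529, tolerance = 1e-9)
  expect_equal(r$p, 0.00532787549096881, tolerance = 1e-9)
  expect_false(r$pass)
  # mirror-symmetric samples have exactly zero sample skewness
  sym <- c(-3, -1, -0.5, 0, 0.5, 1, 3)
  expect_equal(dagostino_pearson(rep(sym, 4))$skewness, 0)
  expect_error(dagostino_pearson(rnorm(19)), "at least 20")
})

test_that("the normality test is calibrated and has power at n = 230", {
  res <- vapply(1:100, function(s) {
    c(normal = dagostino_pearson(withr::with_seed(s, rnorm(230)))$pass,
      lognormal = dagostino_pearson(
        withr::with_seed(s + 5000, rlnorm(230, sdlog = 1)))$pass)
  }, logical(2))
  expect_gte(mean(res["normal", ]), 0.95)   # size near the 0.01 level
  expect_lte(mean(res["lognormal", ]), 0.01) # heavy skew always caught
})

test_that("group comparisons follow the classical identities", {
  v <- withr::with_seed(71, rnorm(60))
  g2 <- rep(c("a", "b"), each = 30)
  gc <- group_compare(v, g2)
  # two groups: ANOVA F equals the square of the pooled t statistic
  f_stat <- summary(gc$fit)[[1]][["F value"]][1]
  t_pooled <- t.test(v[g2 == "a"], v[g2 == "b"], var.equal = TRUE)$statistic
  expect_equal(f_stat, unname(t_pooled)^2)
  # identical groups give a large p
  gc0 <- group_compare(rep(c(1, 2, 3), 10), rep(c("a", "b"), 15))
  expect_gt(gc0$anova_p, 0.5)
  # a planted one-SD shift at n = 60 per group is essentially always seen
  ps <- vapply(1:20, function(s) {
    x <- withr::with_seed(s + 300, c(rnorm(60), rnorm(60, mean = 1)))
    group_compare(x, rep(c("a", "b"), each = 60))$anova_p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.99)
  expect_error(group_compare(1:3, c("a", "a", "b")), "at least 2 members")
  # three bone-status groups produce all pairwise contrasts
  cohort <- cached_cohort(230, seed = 1)
  gc3 <- group_compare(cohort$mir194, cohort$status)
  expect_equal(nrow(gc3$pairwise), 3)
  expect_true("osteopenia" %in% gc3$pairwise$group1 |
                "osteopenia" %in% gc3$pairwise$group2)
})
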