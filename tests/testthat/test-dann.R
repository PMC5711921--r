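test_that("euclidean distance behaves in the unit box", {
  expect_equal(euclidean(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(euclidean(c(0, 0), c(0, 1)), 1)
  expect_equal(euclidean(rep(0, 6), rep(1, 6)), sqrt(6))
  expect_equal(euclidean(c(1, 0), c(0, 1)), euclidean(c(0, 1), c(1, 0)))
  expect_error(euclidean(1:2, 1:3), "dimension mismatch")
})

test_that("divisions partition the reference into nearly equal distance blocks", {
  d229 <- withr::with_seed(1, runif(229))
  expect_equal(lengths(make_divisions(d229, 4)), c(58, 57, 57, 57))
  expect_equal(lengths(make_divisions(withr::with_seed(2, runif(10)), 2)),
               c(5, 5))
  # partition contract across a grid of (n, m)
  for (n in c(5, 10, 37, 100, 229, 300)) {
    d <- withr::with_seed(n, runif(n))
    for (m in 2:min(10, n)) {
      div <- make_divisions(d, m)
      expect_equal(sort(unlist(div)), 1:n)         # exhaustive, disjoint
      expect_lte(diff(range(lengths(div))), 1)     # near-equal sizes
      # blocks are ordered by distance: max of block i <= min of block i+1
      maxs <- vapply(div, function(ix) max(d[ix]), numeric(1))
      mins <- vapply(div, function(ix) min(d[ix]), numeric(1))
      expect_true(all(utils::head(maxs, -1) <= utils::tail(mins, -1)))
    }
  }
  expect_error(make_divisions(runif(20), 1), "\\[2, 10\\]")
  expect_error(make_divisions(runif(20), 11), "\\[2, 10\\]")
  expect_error(make_divisions(runif(3), 4), "more divisions")
})

test_that("derivative features match a hand-computed five-member fixture", {
  # focal participant at (0.2, 0.2); reference members A-E with known
  # coordinates, ANN I outputs, and osteoporosis labels
  dists <- c(A = 0.1, B = 0.4, C = 0.5, D = sqrt(0.65), E = sqrt(0.02))
  outs <- c(A = 0.9, B = 0.5, C = 0.4, D = 0.2, E = 0.8)
  op <- c(A = FALSE, B = FALSE, C = TRUE, D = TRUE, E = FALSE)
  # distance order: A (0.1), E (0.1414), B (0.4), C (0.5), D (0.8062);
  # m = 2 splits 5 members into blocks of 3 and 2
  f1 <- derivative_features(dists, ann1_self = 0.7, outs, op,
                            m = 2, d_index = 1, ids = names(dists))
  expect_equal(unname(f1), c(0.7, (0.9 + 0.8 + 0.5) / 3,
                             (0.1 + sqrt(0.02) + 0.4) / 3, 0))
  f2 <- derivative_features(dists, ann1_self = 0.7, outs, op,
                            m = 2, d_index = 2, ids = names(dists))
  expect_equal(unname(f2), c(0.7, (0.4 + 0.2) / 2,
                             (0.5 + sqrt(0.65)) / 2, 1))
  expect_error(derivative_features(dists, 0.7, outs, op, 2, 3), "1..m")
})

test_that("degenerate division geometry collapses to the self output", {
  # every reference member identical to the focal participant
  f <- derivative_features(rep(0, 6), ann1_self = 0.42, rep(0.42, 6),
                           rep(TRUE, 6), m = 3, d_index = 2)
  expect_equal(unname(f), c(0.42, 0.42, 0, 1))
})

test_that("the division search logs the full grid and selects within range", {
  cohort <- cached_cohort(120, seed = 21,
                          config = cohort_sim_config(n = 120))
  d <- fit_dann(cohort, c("mir194", "age", "weight"), seed = 3,
                m_range = 2:4)
  expect_equal(nrow(d$grid), 2 + 3 + 4)
  expect_equal(d$grid[c("m", "d_index")],
               tibble::tibble(m = rep(2:4, 2:4),
                              d_index = c(1:2, 1:3, 1:4)))
  expect_true(d$m %in% 2:4 && d$d_index <= d$m)
  expect_error(fit_dann(cohort, c("mir194", "age"), seed = 1,
                        m_range = 1:3), "2..10")
})

test_that("scoring the training cohort reproduces the stored scores exactly", {
  cohort <- cached_cohort(120, seed = 22,
                          config = cohort_sim_config(n = 120))
  d <- fit_dann(cohort, c("mir194", "age", "weight"), seed = 4,
                m_range = 2:4)
  expect_identical(predict(d, cohort), d$scores)
  # determinism: refitting with the same seed gives the same model
  d2 <- fit_dann(cohort, c("mir194", "age", "weight"), seed = 4,
                 m_range = 2:4)
  expect_identical(c(d2$m, d2$d_index), c(d$m, d$d_index))
  expect_identical(d2$scores, d$scores)
  # class-type prediction applies the stored threshold
  cls <- predict(d, cohort, type = "class")
  expect_identical(cls, d$scores < d$threshold)
})

test_that("external participants are scored against the full reference", {
  cohort <- cached_cohort(120, seed = 23,
                          config = cohort_sim_config(n = 120))
  d <- fit_dann(cohort, c("mir194", "age", "weight"), seed = 5,
                m_range = 2:4)
  ext <- cached_cohort(30, seed = 24, config = external_cohort_config())
  sc <- predict(d, ext)
  expect_length(sc, 30)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_false(anyNA(sc))
  # derivative features never use the focal participant's own label:
  # flipping an external participant's status does not change her score
  ext2 <- ext
  ext2$t_score[1] <- 1
  ext2$status <- classify_bone_status(ext2$t_score)
  expect_identical(predict(d, ext2)[1], sc[1])
})

test_that("the DANN score outperforms the raw marker on planted structure", {
  wins <- vapply(1:5, function(s) {
    cohort <- cached_cohort(230, seed = s)
    d <- fit_dann(cohort, select_features(cohort), seed = s)
    d$rho_full > abs(cor(cohort$mir194, cohort$bmd, method = "spearman"))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the DANN output is closer to normal than its skewed inputs", {
  passes <- vapply(1:3, function(s) {
    cohort <- cached_cohort(230, seed = s)
    d <- fit_dann(cohort, select_features(cohort), seed = s)
    c(dann = dagostino_pearson(d$scores)$pass,
      alt = dagostino_pearson(cohort$ALT)$pass)
  }, logical(2))
  expect_gte(sum(passes["dann", ]), sum(passes["alt", ]))
  expect_equal(sum(passes["alt", ]), 0) # lognormal ALT always rejected
})
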