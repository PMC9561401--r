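test_that("parameter vector spans min..max in 100 equal steps", {
  pv <- parameter_vector(c(0:99))
  expect_length(pv$thresholds, 100L)
  expect_equal(pv$thresholds, as.numeric(0:99))
  expect_false(pv$degenerate)
  set.seed(11)
  for (rep in 1:10) {
    v <- rnorm(sample(5:40, 1), sd = runif(1, 0.1, 50))
    pv <- parameter_vector(v)
    expect_equal(pv$thresholds[1], min(v))
    expect_equal(pv$thresholds[100], max(v))
    expect_equal(diff(pv$thresholds),
                 rep((max(v) - min(v)) / 99, 99), tolerance = 1e-9)
  }
})

test_that("constant and missing attributes are handled explicitly", {
  pv <- parameter_vector(rep(5, 10))
  expect_true(pv$degenerate)
  expect_equal(pv$thresholds, rep(5, 100))
  expect_error(parameter_vector(rep(NA_real_, 5)), "missing")
  expect_error(parameter_vector(c(1, NA)), "2 non-missing")
})

test_that("binarize codes strictly-above as 1, ties as 0, missing as missing", {
  la <- binarize(c(1, 2, 3), 2.5)  # 'sports sampled at age 12 over 2.5'
  expect_equal(la$indicator, c(0L, 0L, 1L))
  expect_equal(binarize(c(1, 2, 3), 0)$indicator, c(1L, 1L, 1L))
  expect_equal(binarize(c(1, 2, 3), 2)$indicator, c(0L, 0L, 1L))
  expect_equal(binarize(c(1, 2, 3), 2, ties = "one")$indicator, c(0L, 1L, 1L))
  expect_equal(binarize(c(1, NA, 3), 2)$indicator, c(0L, NA, 1L))
  set.seed(12)
  v <- rnorm(40)
  for (theta in rnorm(10))
    expect_equal(sum(binarize(v, theta)$indicator), sum(v > theta))
})

test_that("contingency reproduces cell counts, margins and exclusions", {
  lab <- study_labels()
  ind <- c(rep(0, 22), 1, rep(1, 4), 0, 0)  # 1 low exposed, 4 high exposed
  ct <- contingency(ind, lab)
  expect_equal(unclass(ct)[1:4], c(a = 4L, b = 1L, c = 2L, d = 22L))
  expect_equal(attr(ct, "excluded"), 0L)
  ct0 <- contingency(rep(0, 29), lab)
  expect_equal(unclass(ct0)[1:4], c(a = 0L, b = 0L, c = 6L, d = 23L))
  set.seed(13)
  for (rep in 1:20) {
    ind <- sample(c(0L, 1L, NA), 29, replace = TRUE, prob = c(.45, .45, .1))
    if (all(is.na(ind[1:23])) || all(is.na(ind[24:29]))) next
    ct <- contingency(ind, lab)
    expect_equal(ct["a"] + ct["c"], c(a = sum(!is.na(ind[24:29]))))
    expect_equal(ct["b"] + ct["d"], c(b = sum(!is.na(ind[1:23]))))
    expect_equal(attr(ct, "excluded"), sum(is.na(ind)))
  }
  expect_error(contingency(c(NA, NA, 1, 0), c("high", "high", "low", "low")),
               "empty")
})

test_that("small-sample-adjusted OR is finite for all tables", {
  expect_equal(odds_ratio_small(c(4, 1, 2, 22)), 88 / 6)
  expect_equal(odds_ratio_small(c(2, 0, 4, 23)), 9.2)
  expect_equal(odds_ratio_small(c(0, 5, 3, 7)), 0)
  expect_equal(odds_ratio_small(c(6, 5, 0, 18)), 18)
  expect_true(is.finite(odds_ratio_small(c(10, 0, 0, 10))))
  expect_error(odds_ratio_small(c(-1, 2, 3, 4)), "non-negative")
})

test_that("odds_ratio_small reproduces every printed table row except the erratum", {
  d <- published_rules()
  ok <- !d$anomaly
  ors <- apply(d[ok, c("a", "b", "c", "d")], 1, odds_ratio_small)
  expect_equal(unname(round(ors, 2)), d$or[ok], tolerance = 1e-12)
  # the erratum row: the formula gives 0.13, not the printed 0.06
  bad <- d[d$anomaly, ]
  expect_equal(round(odds_ratio_small(unlist(bad[c("a", "b", "c", "d")])), 2),
               0.13)
})

test_that("fisher_exact has no association at balanced tables and is symmetric", {
  expect_equal(fisher_exact(c(3, 3, 3, 3)), 1)
  set.seed(14)
  for (rep in 1:25) {
    x <- as.integer(rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    # transposing exposure and group leaves the two-sided p unchanged
    expect_equal(fisher_exact(x), fisher_exact(x[c(1, 3, 2, 4)]))
  }
})

test_that("fisher_exact matches full enumeration over fixed-margin tables", {
  set.seed(15)
  for (rep in 1:60) {
    x <- as.integer(rmultinom(1, sample(6:30, 1), runif(4, 0.05, 1)))
    for (alt in c("two.sided", "greater", "less"))
      expect_equal(fisher_exact(x, alt), enum_fisher(x[1], x[2], x[3], x[4], alt),
                   tolerance = 1e-9)
  }
})

test_that("fisher_ci brackets the conditional MLE and handles zero cells", {
  expect_equal(unname(fisher_ci(c(0, 5, 4, 7))[1]), 0)
  expect_equal(unname(fisher_ci(c(3, 0, 2, 8))[2]), Inf)
  ci <- fisher_ci(c(4, 1, 2, 22))
  expect_lt(ci[1], 14.67); expect_gt(ci[2], 14.67)
  set.seed(16)
  for (rep in 1:15) {
    x <- as.integer(rmultinom(1, 25, runif(4, 0.1, 1)))
    ci <- fisher_ci(x)
    cmle <- stats::fisher.test(matrix(c(x[1], x[3], x[2], x[4]), 2))$estimate
    expect_lte(ci[1], cmle + 1e-9); expect_gte(ci[2], cmle - 1e-9)
  }
})

test_that("true positive rate is the high-group prevalence", {
  expect_equal(true_positive_rate(c(4, 1, 2, 22)), 4 / 6)
  expect_equal(true_positive_rate(c(0, 5, 6, 18)), 0)
  expect_equal(true_positive_rate(c(6, 10, 0, 13)), 1)
  expect_error(true_positive_rate(c(0, 5, 0, 18)), "high")
})

test_that("optimized threshold is a grid member chosen by the cascade", {
  lab <- study_labels()
  set.seed(17)
  # perfectly separating attribute: compare against an independent
  # enumeration oracle applied to every grid point
  v <- c(sort(runif(23, 0, 1)), sort(runif(6, 1.3, 2)))
  opt <- optimize_parameter(v, lab)
  expect_true(opt$theta %in% opt$grid)
  oracle_theta <- NA
  for (th in opt$grid) {
    a <- sum(v[24:29] > th); b <- sum(v[1:23] > th)
    if (enum_fisher(a, b, 6 - a, 23 - b, "two.sided") < 0.05) {
      oracle_theta <- th; break
    }
  }
  expect_equal(opt$theta, oracle_theta)
  expect_equal(opt$status, "both")
})

test_that("null attributes fall back to the range minimum in the large majority", {
  set.seed(18)
  lab <- study_labels()
  res <- replicate(120, {
    v <- rnorm(29)
    opt <- optimize_parameter(v, sample(lab))
    c(fallback = opt$status == "fallback",
      at_min = opt$theta == min(opt$grid))
  })
  # branch 3 always returns the range minimum
  expect_true(all(res["at_min", res["fallback", ] == 1] == 1))
  expect_gt(mean(res["fallback", ]), 0.6)
})

test_that("degenerate attributes report their constant threshold", {
  opt <- optimize_parameter(rep(2, 29), study_labels())
  expect_equal(opt$status, "degenerate")
  expect_equal(opt$theta, 2)
})

test_that("exposure counts are non-increasing in the threshold", {
  set.seed(19)
  v <- rnorm(29); lab <- study_labels()
  th <- parameter_vector(v)$thresholds
  a <- vapply(th, function(t) sum(v[24:29] > t), 1)
  b <- vapply(th, function(t) sum(v[1:23] > t), 1)
  expect_true(all(diff(a) <= 0))
  expect_true(all(diff(b) <= 0))
})

test_that("importance grading follows the midpoint scheme and its boundaries", {
  d <- published_rules()
  dist <- d$or_small <- apply(d[c("a", "b", "c", "d")], 1, odds_ratio_small)
  dist <- d$or_small[d$importance != ""]
  expect_equal(as.character(grade_importance(14.67, 4 / 6, dist)), "high")
  expect_equal(as.character(grade_importance(9.2, 2 / 6, dist)), "moderate")
  # non-significant inputs grade not_significant whatever their values
  expect_equal(as.character(grade_importance(100, 1, dist, significant = FALSE)),
               "not_significant")
  # zero TPR can never reach High for a positive-association rule
  g0 <- grade_importance(c(1, 2, 5, 20, 1e4), 0, dist)
  expect_false(any(g0 == "high"))
  # protective rules are graded by the inverse rule
  expect_equal(as.character(grade_importance(0.04, 2 / 6, dist)), "high")
  expect_equal(as.character(grade_importance(0, 0, dist)), "high")
})

test_that("empirical anchors use the OR distribution percentiles", {
  sc <- importance_scales(anchors = "empirical")
  dist <- c(1, 2, 4, 8, 16, 32)
  g <- grade_importance(32, 1, dist, scales = sc)
  expect_equal(as.character(g), "high")
  expect_error(grade_importance(2, 0.5, numeric(), scales = sc), "empty")
  expect_error(grade_importance(2, 0.5, rep(3, 5), scales = sc), "degenerate")
})

test_that("importance_scales validates its configuration", {
  expect_error(importance_scales(anchor_or = c(4, 3, 2, 1)), "increasing")
  expect_error(importance_scales(cut_high = 30, cut_moderate = 40),
               "increasing")
})

test_that("commonalities flag high-prevalence non-discriminators only", {
  lab <- study_labels()
  common <- c(rep(1, 21), 0, 0, rep(1, 5), 0)   # ~91% low, ~83% high, p >= .05
  discr <- c(rep(0, 21), 1, 1, rep(1, 6))        # 9% low vs 100% high
  rare <- c(rep(0, 23), 1, rep(0, 5))
  fc <- find_commonalities(list(common = common, discr = discr, rare = rare),
                           lab)
  expect_true(fc$commonality[fc$attribute == "common"])
  expect_false(fc$commonality[fc$attribute == "discr"])
  expect_false(fc$commonality[fc$attribute == "rare"])
  # brute-force agreement on random cohorts
  set.seed(20)
  for (rep in 1:10) {
    ind <- lapply(1:5, function(i) rbinom(29, 1, runif(1, .2, .9)))
    names(ind) <- paste0("r", 1:5)
    fc <- find_commonalities(ind, lab, prevalence_threshold = 0.6)
    for (i in 1:5) {
      ph <- mean(ind[[i]][24:29]); pl <- mean(ind[[i]][1:23])
      p <- enum_fisher(sum(ind[[i]][24:29]), sum(ind[[i]][1:23]),
                       6 - sum(ind[[i]][24:29]), 23 - sum(ind[[i]][1:23]))
      expect_equal(fc$commonality[i], p >= 0.05 && ph >= 0.6 && pl >= 0.6)
    }
  }
})

test_that("screen_cohort is deterministic and reports run context", {
  sim <- tiny_cohort(seed = 22, n_attributes = 30,
                     planted = list(planted_effect("pe", p_high = 1,
                                                   p_low = 0)))
  s1 <- screen_cohort(sim$features, sim$labels)
  s2 <- screen_cohort(sim$features, sim$labels)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 30L)
  expect_true(all(s1$theta >= -Inf))
  pe_row <- s1[s1$attribute == "pe", ]
  expect_lt(pe_row$p, 0.05)
  expect_equal(as.character(pe_row$importance), "high")
  expect_gt(attr(s1, "n_tests"), 0)
  dt <- discriminator_table(s1)
  expect_equal(nrow(dt), sum(s1$p < 0.05))
})
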