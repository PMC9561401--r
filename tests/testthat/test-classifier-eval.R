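sep_train <- function() {
  list(x = data.frame(f = c(0, 0.1, 0.2, 0.8, 0.9, 1.0)),
       y = c("low", "low", "low", "high", "high", "high"))
}

test_that("all four families classify a separable held-out point correctly", {
  tr <- sep_train()
  for (kind in c("naive_bayes", "c45_tree", "linear_svm", "knn")) {
    lo <- fit_predict(kind, tr$x, tr$y, data.frame(f = 0.05))
    hi <- fit_predict(kind, tr$x, tr$y, data.frame(f = 0.95))
    expect_equal(lo$label, "low", info = kind)
    expect_equal(hi$label, "high", info = kind)
    # scores orient toward the positive (low) class
    expect_gt(lo$score, hi$score)
  }
  expect_error(fit_predict("knn", tr$x, rep("low", 6), data.frame(f = 0.5)),
               "single-class")
})

test_that("naive Bayes posterior matches the hand-computed Gaussian rule", {
  x <- data.frame(f = c(0, 2, 10, 12))
  y <- c("low", "low", "high", "high")
  fp <- fit_predict("naive_bayes", x, y, data.frame(f = 3), positive = "low")
  mu <- c(low = 1, high = 11); s <- c(low = sqrt(2), high = sqrt(2))
  lik <- dnorm(3, mu, s) * 0.5
  expect_equal(fp$score, unname(lik["low"] / sum(lik)), tolerance = 1e-6)
  expect_equal(fp$label, "low")
})

test_that("1-nn returns the label of the nearest training point", {
  x <- data.frame(f = c(0, 1, 4, 5))
  y <- c("low", "low", "high", "high")
  expect_equal(fit_predict("knn", x, y, data.frame(f = 1.2))$label, "low")
  expect_equal(fit_predict("knn", x, y, data.frame(f = 3.9))$label, "high")
})

test_that("loocv produces one held-out prediction per athlete", {
  sim <- tiny_cohort(seed = 51, n_attributes = 10,
                     planted = list(planted_effect("pe", p_high = 1,
                                                   p_low = 0)))
  nf <- minmax_normalize(sim$features)
  sub <- nf; sub$values <- nf$values["pe"]
  pr <- loocv(sub, sim$labels, "naive_bayes")
  expect_equal(nrow(pr), 29L)
  expect_equal(pr$athlete_id, sim$features$athlete_id)
  expect_true(all(pr$pred %in% c("high", "low")))
})

test_that("loocv predictions are invariant to athlete order", {
  sim <- tiny_cohort(seed = 52, n_attributes = 6)
  nf <- minmax_normalize(sim$features)
  sub <- nf; sub$values <- nf$values[1:3]
  for (kind in c("naive_bayes", "linear_svm", "knn")) {
    pr <- loocv(sub, sim$labels, kind, seed = 9)
    perm <- sample(29)
    shuf <- sub
    shuf$values <- sub$values[perm, , drop = FALSE]
    shuf$athlete_id <- sub$athlete_id[perm]
    pr2 <- loocv(shuf, sim$labels, kind, seed = 9)
    expect_equal(pr2$pred[match(pr$athlete_id, pr2$athlete_id)], pr$pred,
                 info = kind)
  }
})

test_that("loocv agrees with a per-fold brute-force refit", {
  set.seed(53)
  x <- data.frame(f1 = rnorm(10), f2 = rnorm(10))
  lab <- rep(c("low", "high"), each = 5)
  cb <- codebook(c("f1", "f2"))
  ft <- feature_table(x, cb)
  gl <- group_labels(ft$athlete_id, lab)
  pr <- loocv(ft, gl, "naive_bayes")
  for (i in 1:10) {
    fit <- e1071::naiveBayes(x[-i, ], factor(lab[-i],
                                             levels = c("high", "low")))
    expect_equal(pr$pred[i],
                 as.character(predict(fit, x[i, , drop = FALSE])))
  }
  expect_error(loocv(ft$values[1:2, ], lab[1:2], "knn"), "at least 3")
})

test_that("constant features degrade to majority-class predictions", {
  cb <- codebook("k")
  ft <- feature_table(data.frame(k = rep(0.5, 29)), cb)
  gl <- group_labels(ft$athlete_id, study_labels())
  for (kind in c("naive_bayes", "c45_tree", "knn")) {
    pr <- loocv(ft, gl, kind)
    expect_true(all(pr$pred == "low"), info = kind)
  }
})

test_that("confusion metrics reproduce the published example and identity", {
  # 23/23 low correct, 5/6 high correct, positive class = low
  truth <- study_labels()
  pred <- c(rep("low", 23), "low", rep("high", 5))
  cm <- confusion_metrics(pred, truth, positive = "low")
  expect_equal(unname(round(cm["accuracy"], 2)), 96.55)
  expect_equal(unname(cm["sensitivity"]), 1)
  expect_equal(unname(round(cm["specificity"], 3)), 0.833)
  expect_equal(confusion_metrics(truth, truth),
               c(accuracy = 100, sensitivity = 1, specificity = 1))
  set.seed(54)
  for (rep in 1:15) {
    pr <- sample(c("low", "high"), 29, replace = TRUE)
    cm <- confusion_metrics(pr, truth)
    expect_equal(cm[["accuracy"]] / 100,
                 (cm[["sensitivity"]] * 23 + cm[["specificity"]] * 6) / 29)
  }
  expect_error(confusion_metrics(pred, rep("low", 29)), "empty class")
})

test_that("rank-based AUC matches the all-pairs comparison", {
  truth <- c(rep("high", 4), rep("low", 6))
  expect_equal(roc_auc(c(rep(0, 4), rep(1, 6)), truth), 1)
  expect_warning(a <- roc_auc(rep(0.3, 10), truth), "constant")
  expect_equal(a, 0.5)
  set.seed(55)
  for (rep in 1:20) {
    sc <- round(runif(10), 1)  # rounding forces ties
    pos <- sc[truth == "low"]; neg <- sc[truth == "high"]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(sc, truth), mean(pairs))
  }
})

test_that("null scores give AUC near one half", {
  set.seed(56)
  truth <- study_labels()
  aucs <- replicate(200, roc_auc(rnorm(29), truth))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("aggregate report appends the arithmetic-mean row", {
  rows <- data.frame(
    classifier = c("naive_bayes", "linear_svm", "c45_tree", "knn"),
    accuracy = c(96.55, 96.55, 82.8, 86.2),
    sensitivity = c(1, 1, 0.913, 0.957),
    specificity = c(0.833, 0.833, 0.5, 0.5),
    auc = c(0.986, 0.916, 0.836, 0.728))
  rep5 <- aggregate_report(rows)
  expect_equal(nrow(rep5), 5L)
  agg <- rep5[5, ]
  expect_equal(round(agg$accuracy, 1), 90.5)
  expect_equal(agg$auc, mean(rows$auc))
  # idempotence: four identical rows aggregate to the same row
  same <- rows; same[2:4, -1] <- same[rep(1, 3), -1]
  expect_equal(unlist(aggregate_report(same)[5, -1]),
               unlist(same[1, -1]), tolerance = 1e-12)
  expect_error(aggregate_report(rows[1:3, ]), "four")
})

test_that("evaluate_classifiers assembles four rows plus the aggregate", {
  sim <- tiny_cohort(seed = 57, n_attributes = 12,
                     planted = list(planted_effect("pe", p_high = 0.9,
                                                   p_low = 0.05)))
  nf <- minmax_normalize(sim$features)
  ev <- evaluate_classifiers(nf, c("pe", "attr_0002"), sim$labels, seed = 57)
  expect_equal(ev$report$classifier,
               c("naive_bayes", "c45_tree", "linear_svm", "knn",
                 "all_classifiers"))
  expect_equal(ev$report$accuracy[5], mean(ev$report$accuracy[1:4]))
  expect_true(all(vapply(ev$predictions, nrow, 1L) == 29L))
  expect_error(evaluate_classifiers(nf, "ghost", sim$labels), "not in table")
})
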