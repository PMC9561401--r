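# Leave-one-out cross-validated classification of the summary-model features
# with four classifier families, and the per-classifier / aggregate report.

CLASSIFIER_KINDS <- c("naive_bayes", "c45_tree", "linear_svm", "knn")

#' Fit a classifier on a training set and predict one held-out point
#'
#' The four families mirror a conventional small-cohort toolkit: Gaussian
#' naive Bayes, a pruned classification tree (CART standing in for the
#' C4.5/J48 family), a linear soft-margin support vector machine with unit
#' cost, and k-nearest neighbours with k = 1 (all distance ties vote).
#'
#' @param kind one of `"naive_bayes"`, `"c45_tree"`, `"linear_svm"`, `"knn"`.
#' @param train_x data frame of numeric features.
#' @param train_y factor/character labels (`"high"`/`"low"`); both classes
#'   must be present.
#' @param test_x single-row data frame with the same columns.
#' @param positive the class whose probability/margin is returned as the
#'   score (default `"low"`, the majority class of the study design).
#' @param seed integer seed set before fitting (the fits used here are
#'   deterministic; the seed guards any future stochastic engine).
#' @param knn_k neighbour count, `cost` SVM cost, `tree_cp` CART complexity.
#' @return List with `label` (predicted class) and `score` (probability or
#'   margin for the positive class, usable for ROC).
#' @export
fit_predict <- function(kind = CLASSIFIER_KINDS, train_x, train_y, test_x,
                        positive = "low", seed = 1L, knn_k = 1L, cost = 1,
                        tree_cp = 0.01) {
  kind <- match.arg(kind)
  train_y <- factor(as.character(train_y), levels = c("high", "low"))
  if (nlevels(droplevels(train_y)) < 2)
    stop("single-class training set")
  train_x <- as.data.frame(train_x)
  test_x <- as.data.frame(test_x)[names(train_x)]
  negative <- setdiff(levels(train_y), positive)
  with_seed_(seed, {
    if (kind == "naive_bayes") {
      fit <- e1071::naiveBayes(train_x, train_y)
      # floor zero within-class sds so constant features degrade gracefully
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-9); tb
      })
      raw <- stats::predict(fit, test_x, type = "raw")
      score <- as.numeric(raw[1, positive])
      label <- colnames(raw)[which.max(raw[1, ])]
    } else if (kind == "c45_tree") {
      dat <- cbind(train_x, .y = train_y)
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 4, cp = tree_cp, xval = 0))
      prob <- stats::predict(fit, test_x, type = "prob")
      score <- as.numeric(prob[1, positive])
      label <- colnames(prob)[which.max(prob[1, ])]
    } else if (kind == "linear_svm") {
      fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = cost,
                        scale = FALSE)
      pred <- stats::predict(fit, test_x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # decision value is positive toward the first class in its colname
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      score <- if (first == positive) dv[1, 1] else -dv[1, 1]
      label <- as.character(pred[1])
    } else {  # knn
      pred <- class::knn(train = as.matrix(train_x),
                         test = as.matrix(test_x),
                         cl = train_y, k = knn_k, prob = TRUE,
                         use.all = TRUE)
      p_win <- attr(pred, "prob")[1]
      label <- as.character(pred[1])
      score <- if (label == positive) p_win else 1 - p_win
    }
    list(label = label, score = unname(score))
  })
}

#' Leave-one-out cross-validation of one classifier family
#'
#' Exactly n folds; fold i trains on all athletes except i and predicts
#' athlete i. Predictions do not depend on row order.
#'
#' @param ft a [feature_table()] (or plain data frame) restricted to the
#'   model features.
#' @param labels a [group_labels()] (or character vector aligned with rows).
#' @param kind classifier family, see [fit_predict()].
#' @param positive positive class for scores, default `"low"`.
#' @param seed integer seed forwarded to every fold.
#' @param ... further arguments to [fit_predict()].
#' @return Data frame with `athlete_id`, `truth`, `pred`, `score` (one row
#'   per athlete).
#' @export
loocv <- function(ft, labels, kind = CLASSIFIER_KINDS, positive = "low",
                  seed = 1L, ...) {
  kind <- match.arg(kind)
  if (inherits(ft, "feature_table")) {
    x <- ft$values; ids <- ft$athlete_id
  } else {
    x <- as.data.frame(ft); ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("row_", seq_len(nrow(x)))
  }
  lab <- if (inherits(labels, "group_labels") || is.data.frame(labels))
    labels$label[match(ids, labels$athlete_id)] else as.character(labels)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 athletes for LOOCV")
  if (length(unique(lab)) < 2) stop("both classes must be present")
  if (anyNA(x))
    stop("missing values in model features; LOOCV classifiers need complete data")
  preds <- character(n); scores <- numeric(n)
  for (i in seq_len(n)) {
    fp <- fit_predict(kind, x[-i, , drop = FALSE], lab[-i],
                      x[i, , drop = FALSE], positive = positive,
                      seed = seed, ...)
    preds[i] <- fp$label; scores[i] <- fp$score
  }
  data.frame(athlete_id = ids, truth = lab, pred = preds, score = scores,
             stringsAsFactors = FALSE)
}

#' Confusion-matrix metrics
#'
#' Accuracy in percent, sensitivity (correct-classification rate of the
#' positive class) and specificity (of the negative class).
#'
#' @param pred,truth aligned label vectors.
#' @param positive positive class, default `"low"` (the majority class).
#' @return Named numeric `c(accuracy, sensitivity, specificity)`; accuracy
#'   on the 0-100 scale, the rates on 0-1.
#' @export
confusion_metrics <- function(pred, truth, positive = "low") {
  stopifnot(length(pred) == length(truth))
  truth <- as.character(truth); pred <- as.character(pred)
  pos <- truth == positive
  if (!any(pos) || all(pos)) stop("empty class in truth labels")
  c(accuracy = 100 * mean(pred == truth),
    sensitivity = mean(pred[pos] == truth[pos]),
    specificity = mean(pred[!pos] == truth[!pos]))
}

#' Rank-based area under the ROC curve
#'
#' Tie-corrected Mann-Whitney AUC (equal to the trapezoidal integral of the
#' ROC curve), oriented so that higher scores indicate the positive class.
#' Constant scores return 0.5 with a warning.
#'
#' @param scores numeric scores for the positive class.
#' @param truth label vector.
#' @param positive positive class, default `"low"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth, positive = "low") {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  if (length(unique(truth)) < 2) stop("both classes must be present")
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC undefined, returning 0.5")
    return(0.5)
  }
  negative <- setdiff(unique(truth), positive)[1]
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Aggregate a four-classifier report
#'
#' Appends the arithmetic-mean row across the four per-classifier rows.
#'
#' @param rows data frame with columns `classifier`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc` and exactly four rows.
#' @return A `classifier_report` data frame with the aggregate
#'   `all_classifiers` row appended (means kept at full precision; printing
#'   rounds to the display precision of the report).
#' @export
aggregate_report <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("classifier", "accuracy", "sensitivity", "specificity", "auc")
  stopifnot(all(need %in% names(rows)))
  if (nrow(rows) != 4) stop("exactly four classifier rows are required")
  agg <- data.frame(classifier = "all_classifiers",
                    accuracy = mean(rows$accuracy),
                    sensitivity = mean(rows$sensitivity),
                    specificity = mean(rows$specificity),
                    auc = mean(rows$auc),
                    stringsAsFactors = FALSE)
  out <- rbind(rows[need], agg)
  rownames(out) <- NULL
  class(out) <- c("classifier_report", "data.frame")
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  fmt <- data.frame(classifier = x$classifier,
                    accuracy = sprintf("%.1f%%", x$accuracy),
                    sensitivity = sprintf("%.3f", x$sensitivity),
                    specificity = sprintf("%.3f", x$specificity),
                    auc = sprintf("%.3f", x$auc))
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Evaluate the summary model by LOOCV with all four classifiers
#'
#' Runs [loocv()] for each classifier family on the model features and
#' assembles the per-classifier and aggregate metric rows. The positive
#' class defaults to the low-performing (majority) group; AUC pools the
#' held-out scores across folds.
#'
#' @param ft a [feature_table()] (normalized values recommended).
#' @param model a [consensus_model()] or character vector of feature names.
#' @param labels a [group_labels()].
#' @param positive positive class, default `"low"`.
#' @param seed integer seed.
#' @param ... further arguments to [fit_predict()].
#' @return List with `report` (a [aggregate_report()] table) and
#'   `predictions` (per-athlete LOOCV predictions per classifier).
#' @export
evaluate_classifiers <- function(ft, model, labels, positive = "low",
                                 seed = 1L, ...) {
  feats <- if (inherits(model, "summary_model") || is.data.frame(model))
    model$attribute else as.character(model)
  if (!length(feats)) stop("empty model")
  missing_f <- setdiff(feats, names(ft$values))
  if (length(missing_f))
    stop("model features not in table: ", paste(missing_f, collapse = ", "))
  sub <- ft
  sub$values <- ft$values[feats]
  sub$codebook <- ft$codebook[match(feats, ft$codebook$name), , drop = FALSE]
  preds <- list(); rows <- list()
  for (kind in CLASSIFIER_KINDS) {
    pr <- loocv(sub, labels, kind, positive = positive, seed = seed, ...)
    cm <- confusion_metrics(pr$pred, pr$truth, positive)
    rows[[kind]] <- data.frame(classifier = kind, accuracy = cm["accuracy"],
                               sensitivity = cm["sensitivity"],
                               specificity = cm["specificity"],
                               auc = roc_auc(pr$score, pr$truth, positive),
                               stringsAsFactors = FALSE)
    preds[[kind]] <- pr
  }
  report <- aggregate_report(do.call(rbind, rows))
  list(report = report, predictions = preds)
}
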