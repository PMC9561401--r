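# Min-max normalization, four univariate feature-ranking procedures, and the
# top-20 consensus rule producing the tiered summary model.

#' Min-max normalize a feature table
#'
#' Affinely maps every column so its observed minimum becomes 0 and its
#' maximum 1, preserving within-column ordering. Constant columns map to 0
#' and are flagged in `attr(, "constant_columns")`; missing cells stay
#' missing. `attr(, "ranges")` stores the original (min, max) per column so
#' the transform can be inverted.
#'
#' @param ft a [feature_table()].
#' @return A normalized [feature_table()].
#' @export
minmax_normalize <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  constant <- character()
  ranges <- matrix(NA_real_, 2, ncol(ft$values),
                   dimnames = list(c("min", "max"), names(ft$values)))
  for (j in seq_along(ft$values)) {
    v <- ft$values[[j]]
    lo <- suppressWarnings(min(v, na.rm = TRUE))
    hi <- suppressWarnings(max(v, na.rm = TRUE))
    ranges[, j] <- c(lo, hi)
    if (!is.finite(lo)) next  # fully missing column: leave as is
    if (lo == hi) {
      ft$values[[j]] <- ifelse(is.na(v), NA_real_, 0)
      constant <- c(constant, names(ft$values)[j])
    } else {
      ft$values[[j]] <- (v - lo) / (hi - lo)
    }
  }
  attr(ft, "constant_columns") <- constant
  attr(ft, "ranges") <- ranges
  ft
}

# ---- univariate leave-one-out discrimination scorers ------------------------
# Each returns c(accuracy, tiebreak): the LOOCV accuracy of the family's 1-D
# classifier plus a continuous tie-break, both higher-better.

score_bayes_ <- function(x, y_high) {
  n <- length(x)
  m1 <- sum(y_high); m0 <- n - m1
  s1 <- sum(x[y_high]); s0 <- sum(x[!y_high])
  ss1 <- sum(x[y_high]^2); ss0 <- sum(x[!y_high]^2)
  mu1 <- ifelse(y_high, (s1 - x) / (m1 - 1), s1 / m1)
  mu0 <- ifelse(y_high, s0 / m0, (s0 - x) / (m0 - 1))
  va1 <- ifelse(y_high, (ss1 - x^2) / (m1 - 1) - mu1^2, ss1 / m1 - mu1^2)
  va0 <- ifelse(y_high, ss0 / m0 - mu0^2, (ss0 - x^2) / (m0 - 1) - mu0^2)
  sd1 <- sqrt(pmax(va1, 1e-12)); sd0 <- sqrt(pmax(va0, 1e-12))
  pr1 <- ifelse(y_high, (m1 - 1) / (n - 1), m1 / (n - 1))
  l1 <- pr1 * stats::dnorm(x, mu1, sd1)
  l0 <- (1 - pr1) * stats::dnorm(x, mu0, sd0)
  post1 <- ifelse(l1 + l0 > 0, l1 / (l1 + l0), 1 - pr1 >= pr1)
  pred_high <- post1 > 0.5
  acc <- mean(pred_high == y_high)
  c(acc, mean(ifelse(y_high, post1, 1 - post1)))
}

stump_counts_ <- function(x, y_high, thr) {
  E <- outer(x, thr, ">")
  AH <- colSums(E & y_high); AL <- colSums(E & !y_high)
  list(E = E, AH = AH, AL = AL)
}

score_tree_ <- function(x, y_high) {
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2) return(c(mean(!y_high), 0))  # constant: majority vote
  thr <- (ux[-1] + ux[-length(ux)]) / 2
  sc <- stump_counts_(x, y_high, thr)
  m1 <- sum(y_high)
  # leave-one-out right/left class counts, folds in rows, thresholds in cols
  aH <- sweep(-(sc$E * y_high), 2, sc$AH, `+`)
  aL <- sweep(-(sc$E * !y_high), 2, sc$AL, `+`)
  nH <- m1 - y_high; nL <- (n - m1) - !y_high
  cH <- nH - aH; cL <- nL - aL
  nR <- aH + aL; nL2 <- cH + cL
  gini <- function(h, l) { t <- h + l; ifelse(t > 0, 2 * h * l / t^2, 0) }
  parent <- gini(matrix(nH, nrow(aH), ncol(aH)), matrix(nL, nrow(aH), ncol(aH)))
  gain <- parent - (nR * gini(aH, aL) + nL2 * gini(cH, cL)) / (n - 1)
  best <- max.col(gain, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  right <- sc$E[idx]
  pred_high <- ifelse(right, aH[idx] > aL[idx], cH[idx] > cL[idx])
  acc <- mean(pred_high == y_high)
  c(acc, mean(gain[idx]))
}

score_margin_ <- function(x, y_high) {
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2) return(c(mean(!y_high), 0))  # constant: majority vote
  thr <- (ux[-1] + ux[-length(ux)]) / 2
  halfgap <- diff(ux) / 2              # geometric margin of each midpoint
  sc <- stump_counts_(x, y_high, thr)
  m1 <- sum(y_high)
  aH <- sweep(-(sc$E * y_high), 2, sc$AH, `+`)
  aL <- sweep(-(sc$E * !y_high), 2, sc$AL, `+`)
  nH <- m1 - y_high; nL <- (n - m1) - !y_high
  # orientation +1: predict high when x > t;  -1: predict high when x <= t
  err_up <- (nH - aH) + aL
  err_dn <- aH + (nL - aL)
  hg <- matrix(halfgap, n, length(thr), byrow = TRUE)
  # minimize error, break ties by the widest margin
  key_up <- err_up - hg / (max(halfgap) + 1)
  key_dn <- err_dn - hg / (max(halfgap) + 1)
  up_best <- max.col(-key_up, ties.method = "first")
  dn_best <- max.col(-key_dn, ties.method = "first")
  iu <- cbind(seq_len(n), up_best); id <- cbind(seq_len(n), dn_best)
  use_up <- key_up[iu] <= key_dn[id]
  j <- ifelse(use_up, up_best, dn_best)
  ij <- cbind(seq_len(n), j)
  pred_high <- ifelse(use_up, sc$E[ij], !sc$E[ij])
  acc <- mean(pred_high == y_high)
  marg <- abs(x - thr[j]) * ifelse(pred_high == y_high, 1, -1)
  c(acc, mean(marg))
}

score_neighbour_ <- function(x, y_high) {
  n <- length(x)
  D <- abs(outer(x, x, "-"))
  diag(D) <- Inf
  d_like <- d_unlike <- numeric(n)
  pred_high <- logical(n)
  for (i in seq_len(n)) {
    same <- y_high == y_high[i]; same[i] <- FALSE
    d_like[i] <- min(D[i, same])
    d_unlike[i] <- min(D[i, !same])
    nn <- which(D[i, ] == min(D[i, ]))
    votes_high <- sum(y_high[nn]); votes_low <- length(nn) - votes_high
    pred_high[i] <- votes_high > votes_low   # distance ties: majority, then low
  }
  acc <- mean(pred_high == y_high)
  c(acc, mean(pmin(d_unlike, 1e6) - pmin(d_like, 1e6)))
}

RANK_METHODS <- c("bayes", "tree", "margin", "neighbour")

#' Rank attributes by univariate discrimination under a classifier family
#'
#' Scores every attribute by the leave-one-out accuracy of a one-dimensional
#' classifier of the requested family — Gaussian naive Bayes, a Gini decision
#' stump, a max-margin threshold, or the single nearest neighbour — with a
#' family-specific continuous tie-break and the attribute name as the final
#' deterministic tie-break. Missing values are excluded pairwise per
#' attribute.
#'
#' @param ft a (normalized) [feature_table()].
#' @param labels a [group_labels()] covering the athletes.
#' @param method one of `"bayes"`, `"tree"`, `"margin"`, `"neighbour"`.
#' @param k the top-k cut used downstream (recorded in the ranking; truncated
#'   with a warning when it exceeds the attribute count).
#' @param seed unused by these deterministic scorers; kept so callers can
#'   treat all ranking engines uniformly.
#' @return A `feature_ranking`: list with `method`, `attributes` (all
#'   attributes, best first), `scores` (LOOCV accuracy), `tiebreak` and `k`.
#' @export
rank_features <- function(ft, labels, method = RANK_METHODS, k = 20,
                          seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ft, "feature_table"))
  lab <- labels$label[match(ft$athlete_id, labels$athlete_id)]
  if (anyNA(lab)) stop("labels do not cover all athletes")
  if (length(unique(lab)) < 2) {
    warning("all athletes carry the same label: ranking is degenerate")
    nms <- sort(names(ft$values))
    return(structure(list(method = method, attributes = nms,
                          scores = stats::setNames(rep(NA_real_, length(nms)),
                                                   nms),
                          tiebreak = rep(NA_real_, length(nms)),
                          k = min(k, length(nms))),
                     class = "feature_ranking"))
  }
  if (k > ncol(ft$values)) {
    warning(sprintf("k = %d exceeds attribute count %d; truncated", k,
                    ncol(ft$values)))
    k <- ncol(ft$values)
  }
  scorer <- switch(method, bayes = score_bayes_, tree = score_tree_,
                   margin = score_margin_, neighbour = score_neighbour_)
  p <- ncol(ft$values)
  acc <- tb <- numeric(p)
  for (j in seq_len(p)) {
    v <- ft$values[[j]]
    keep <- !is.na(v)
    yk <- lab[keep] == "high"
    if (sum(keep) < 4 || sum(yk) < 2 || sum(!yk) < 2) { acc[j] <- 0; tb[j] <- -Inf
    } else {
      s <- scorer(v[keep], yk)
      acc[j] <- s[1]; tb[j] <- s[2]
    }
  }
  nms <- names(ft$values)
  o <- order(-acc, -tb, nms)
  structure(list(method = method, attributes = nms[o],
                 scores = stats::setNames(acc[o], nms[o]),
                 tiebreak = tb[o], k = k),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> method '%s', %d attributes; top %d:\n",
              x$method, length(x$attributes), min(5, x$k)))
  print(utils::head(x$scores, min(5, x$k)))
  invisible(x)
}

#' Consensus summary model from four rankings
#'
#' Attributes appearing in the top-k of all four rankings are tiered
#' `very_important`, in any three `important`, in any two
#' `fairly_important`; attributes in fewer than two top-k lists are
#' excluded.
#'
#' @param rankings list of exactly four [rank_features()] results.
#' @param k top-k cut, default 20.
#' @return A `summary_model` data frame: `attribute`, `appearances`, `tier`.
#' @export
consensus_model <- function(rankings, k = 20) {
  if (length(rankings) != 4) stop("exactly four rankings are required")
  tops <- lapply(rankings, function(r) {
    kk <- min(k, length(r$attributes))
    if (k > length(r$attributes))
      warning("k exceeds attribute count; truncated")
    utils::head(r$attributes, kk)
  })
  counts <- table(unlist(tops))
  keep <- counts >= 2
  tier_of <- c(`2` = "fairly_important", `3` = "important",
               `4` = "very_important")
  sm <- data.frame(attribute = names(counts)[keep],
                   appearances = as.integer(counts[keep]),
                   stringsAsFactors = FALSE)
  sm$tier <- factor(tier_of[as.character(sm$appearances)],
                    levels = c("fairly_important", "important",
                               "very_important"))
  sm <- sm[order(-sm$appearances, sm$attribute), , drop = FALSE]
  rownames(sm) <- NULL
  attr(sm, "k") <- k
  attr(sm, "methods") <- vapply(rankings, function(r) r$method, character(1))
  class(sm) <- c("summary_model", "data.frame")
  sm
}

#' @export
print.summary_model <- function(x, ...) {
  cat(sprintf("<summary_model> %d attributes (top-%d consensus of %s)\n",
              nrow(x), attr(x, "k"),
              paste(attr(x, "methods"), collapse = "/")))
  print(as.data.frame(x))
  invisible(x)
}

#' Direction of influence of an attribute
#'
#' Marks `+` for the group with the greater mean of the attribute, `-` for
#' the other, `0` for both on a tie. Computed on whatever scale the supplied
#' table carries (conventionally the min-max-normalized one).
#'
#' @param attribute attribute name.
#' @param ft a [feature_table()].
#' @param labels a [group_labels()].
#' @return Named character vector `c(low = , high = )`.
#' @export
direction_of_influence <- function(attribute, ft, labels) {
  if (!attribute %in% names(ft$values))
    stop("attribute not in table: ", attribute)
  lab <- labels$label[match(ft$athlete_id, labels$athlete_id)]
  v <- ft$values[[attribute]]
  m_high <- mean(v[lab == "high"], na.rm = TRUE)
  m_low <- mean(v[lab == "low"], na.rm = TRUE)
  if (isTRUE(all.equal(m_high, m_low))) c(low = "0", high = "0")
  else if (m_high > m_low) c(low = "-", high = "+")
  else c(low = "+", high = "-")
}
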