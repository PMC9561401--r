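# The core screen: logical attributes over a 100-point threshold grid,
# threshold optimization by exact-test significance, small-sample-adjusted
# odds ratios with Fisher exact inference, importance grading, and
# commonality detection.

#' Threshold grid for one attribute
#'
#' A sequence of 100 equally spaced candidate thresholds from the observed
#' minimum to the observed maximum of the attribute.
#'
#' @param values numeric attribute column (missing values ignored); at least
#'   two non-missing values required.
#' @param n_points grid size, default 100.
#' @return A `parameter_vector`: list with `thresholds` (length `n_points`,
#'   first = min, last = max, equal spacing) and `degenerate` (`TRUE` for a
#'   constant attribute, whose grid collapses to 100 copies of the constant).
#' @export
parameter_vector <- function(values, n_points = 100L) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("attribute is fully missing")
  if (length(v) < 2) stop("need at least 2 non-missing values")
  lo <- min(v); hi <- max(v)
  degenerate <- lo == hi
  thresholds <- if (degenerate) rep(lo, n_points)
                else seq(lo, hi, length.out = n_points)
  structure(list(thresholds = thresholds, degenerate = degenerate),
            class = "parameter_vector")
}

#' Binarize an attribute at a threshold
#'
#' Builds the logical attribute "value over theta": indicator 1 when the
#' value is strictly above the threshold, 0 otherwise (ties count as 0 by
#' default, configurable), missing in, missing out.
#'
#' @param values numeric attribute column.
#' @param theta finite threshold.
#' @param name attribute name carried into the rule label.
#' @param ties `"zero"` (default; value equal to theta codes 0) or `"one"`.
#' @return A `logical_attribute`: list with `name`, `theta`, `direction`
#'   (`"over"`), and `indicator` (integer 0/1/NA per athlete).
#' @export
binarize <- function(values, theta, name = "attribute",
                     ties = c("zero", "one")) {
  ties <- match.arg(ties)
  stopifnot(is.finite(theta))
  ind <- if (ties == "zero") as.integer(values > theta)
         else as.integer(values >= theta)
  structure(list(name = name, theta = theta, direction = "over",
                 indicator = ind),
            class = "logical_attribute")
}

#' @export
print.logical_attribute <- function(x, ...) {
  cat(sprintf("<logical_attribute> %s > %g: %d of %d exposed (%d missing)\n",
              x$name, x$theta, sum(x$indicator == 1, na.rm = TRUE),
              length(x$indicator), sum(is.na(x$indicator))))
  invisible(x)
}

#' 2x2 contingency counts of a logical attribute against performance group
#'
#' Cells: `a` = exposed & high, `b` = exposed & low, `c` = unexposed & high,
#' `d` = unexposed & low. Athletes with a missing indicator are excluded and
#' tallied in `attr(, "excluded")`.
#'
#' @param indicator a [binarize()] result, or a plain 0/1/NA vector aligned
#'   with `labels`.
#' @param labels a [group_labels()] (or character vector of "high"/"low").
#' @return A `contingency` object: named integer vector `c(a, b, c, d)`.
#' @export
contingency <- function(indicator, labels) {
  if (inherits(indicator, "logical_attribute")) indicator <- indicator$indicator
  lab <- if (inherits(labels, "group_labels") || is.data.frame(labels))
    labels$label else as.character(labels)
  stopifnot(length(indicator) == length(lab))
  keep <- !is.na(indicator)
  excluded <- sum(!keep)
  ind <- indicator[keep]; lab <- lab[keep]
  if (!any(lab == "high") || !any(lab == "low"))
    stop("a group is empty after excluding missing indicators")
  counts <- c(a = sum(ind == 1 & lab == "high"),
              b = sum(ind == 1 & lab == "low"),
              c = sum(ind == 0 & lab == "high"),
              d = sum(ind == 0 & lab == "low"))
  structure(as.integer(counts), names = names(counts),
            excluded = excluded, class = "contingency")
}

as_counts_ <- function(counts) {
  x <- as.integer(unclass(counts))
  if (length(x) != 4 || any(is.na(x)) || any(x < 0))
    stop("counts must be four non-negative integers (a, b, c, d)")
  x
}

#' Small-sample-adjusted odds ratio
#'
#' The "small" adjustment `a*d / ((b + 1) * (c + 1))` keeps the odds ratio
#' finite for every non-negative table, including zero cells: a zero
#' numerator cell gives OR 0, and a zero denominator cell no longer
#' divides by zero.
#'
#' @param counts a [contingency()] or a numeric vector `c(a, b, c, d)`.
#' @return The adjusted odds ratio (dimensionless, >= 0).
#' @export
odds_ratio_small <- function(counts) {
  x <- as_counts_(counts)
  (x[1] * x[4]) / ((x[2] + 1) * (x[3] + 1))
}

# memoised Fisher p-values: the screen revisits a few hundred distinct
# tables tens of thousands of times
.fisher_env <- new.env(parent = emptyenv())

fisher_p_ <- function(a, b, c, d, alternative) {
  key <- paste(a, b, c, d, alternative, sep = ",")
  p <- .fisher_env[[key]]
  if (is.null(p)) {
    p <- stats::fisher.test(matrix(c(a, c, b, d), 2),
                            alternative = alternative)$p.value
    .fisher_env[[key]] <- p
  }
  p
}

#' Fisher exact test probability for a 2x2 table
#'
#' Exact conditional (hypergeometric) tail probability. The two-sided
#' default sums all fixed-margin tables at most as probable as the observed
#' one.
#'
#' @param counts a [contingency()] or numeric `c(a, b, c, d)`.
#' @param alternative `"two.sided"` (default), `"greater"` (exposure
#'   enriched in the high group) or `"less"`.
#' @return The exact p-value.
#' @export
fisher_exact <- function(counts,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as_counts_(counts)
  fisher_p_(x[1], x[2], x[3], x[4], alternative)
}

#' Exact conditional confidence interval for the odds ratio
#'
#' Tail-inversion interval of the noncentral hypergeometric likelihood (the
#' interval reported by [stats::fisher.test()]). Zero cells yield 0 or `Inf`
#' endpoints. Note the point estimate used throughout this package is the
#' small-sample-adjusted OR, which no standard interval recipe matches
#' exactly; intervals are reported for context.
#'
#' @param counts a [contingency()] or numeric `c(a, b, c, d)`.
#' @param level confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
fisher_ci <- function(counts, level = 0.95) {
  x <- as_counts_(counts)
  ci <- stats::fisher.test(matrix(c(x[1], x[3], x[2], x[4]), 2),
                           conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' True positive rate of a logical attribute
#'
#' The prevalence of the condition in the high-performing group,
#' `a / (a + c)`.
#'
#' @param counts a [contingency()] or numeric `c(a, b, c, d)`.
#' @return TPR in \[0, 1\].
#' @export
true_positive_rate <- function(counts) {
  x <- as_counts_(counts)
  if (x[1] + x[3] == 0) stop("empty high group")
  x[1] / (x[1] + x[3])
}

#' Optimize the binarization threshold of one attribute
#'
#' Scans the 100-point grid and selects, in a cascade:
#' branch 1, the lowest threshold whose association is significant viewed
#' from both directions (two-sided exact p < alpha); else branch 2, the
#' lowest threshold with at least one one-sided exact p < alpha; else
#' branch 3, the minimum of the range. With `directional = "twosided"` both
#' checks use the two-sided p (so branches 1 and 2 coincide).
#'
#' @param values numeric attribute column.
#' @param labels a [group_labels()] or character vector.
#' @param vector optional precomputed [parameter_vector()].
#' @param alpha significance level, default 0.05.
#' @param directional `"onesided"` (default; branch 2 uses the smaller
#'   one-sided p) or `"twosided"` (literal mode).
#' @param ties passed to [binarize()].
#' @return List with `theta` (a member of the grid), `status` (`"both"`,
#'   `"single"`, `"fallback"` or `"degenerate"`), `p_two` and `p_one` at the
#'   selected threshold, and the `grid` used.
#' @export
optimize_parameter <- function(values, labels, vector = NULL, alpha = 0.05,
                               directional = c("onesided", "twosided"),
                               ties = c("zero", "one")) {
  directional <- match.arg(directional)
  ties <- match.arg(ties)
  if (is.null(vector)) vector <- parameter_vector(values)
  lab <- if (inherits(labels, "group_labels") || is.data.frame(labels))
    labels$label else as.character(labels)
  keep <- !is.na(values)
  v <- values[keep]; lab <- lab[keep]
  n_high <- sum(lab == "high"); n_low <- sum(lab == "low")
  if (n_high == 0 || n_low == 0)
    stop("a group is empty after excluding missing values")
  th <- vector$thresholds
  if (vector$degenerate)
    return(list(theta = th[1], status = "degenerate",
                p_two = NA_real_, p_one = NA_real_, grid = th))
  cmp <- if (ties == "zero") `>` else `>=`
  exposed <- outer(v, th, cmp)                      # n x 100
  a <- colSums(exposed & lab == "high")
  b <- colSums(exposed & lab == "low")
  tab <- cbind(a = a, b = b)
  uniq <- !duplicated(tab)
  p_two <- p_one <- numeric(length(th))
  for (i in which(uniq)) {
    dup <- tab[, 1] == tab[i, 1] & tab[, 2] == tab[i, 2]
    p2 <- fisher_p_(a[i], b[i], n_high - a[i], n_low - b[i], "two.sided")
    p1 <- if (directional == "twosided") p2 else
      min(fisher_p_(a[i], b[i], n_high - a[i], n_low - b[i], "greater"),
          fisher_p_(a[i], b[i], n_high - a[i], n_low - b[i], "less"))
    p_two[dup] <- p2
    p_one[dup] <- p1
  }
  hit_both <- which(p_two < alpha)
  hit_one <- which(p_one < alpha)
  if (length(hit_both)) {
    k <- hit_both[1]; status <- "both"
  } else if (length(hit_one)) {
    k <- hit_one[1]; status <- "single"
  } else {
    k <- 1L; status <- "fallback"
  }
  list(theta = th[k], status = status, p_two = p_two[k], p_one = p_one[k],
       grid = th)
}

#' Importance grading scales
#'
#' The grading scheme positions the odds ratio and the true-positive rate on
#' two 0-100 scales and grades by their midpoint. The OR scale is a
#' piecewise-linear map through four anchors; the TPR scale is the rate in
#' percent. Defaults are calibrated so that an OR above 4.6 combined with a
#' TPR above 60% always grades High, the calibration constraint of the
#' published scheme.
#'
#' @param anchors `"calibrated"` (default: fixed anchor ORs
#'   `c(1, 2.5, 4.6, 31)`) or `"empirical"` (the 0th/33rd/66th/100th
#'   percentiles of the significant-OR distribution supplied at grading
#'   time).
#' @param anchor_or anchor OR values when `anchors = "calibrated"`.
#' @param anchor_pos scale positions of the anchors (strictly increasing,
#'   in \[0, 100\]).
#' @param cut_high,cut_moderate midpoint cut-offs for the High and Moderate
#'   grades; the default `cut_high` is the midpoint attained at the
#'   calibration corner (OR 4.6, TPR 60%).
#' @return An `importance_scales` object.
#' @export
importance_scales <- function(anchors = c("calibrated", "empirical"),
                              anchor_or = c(1, 2.5, 4.6, 31),
                              anchor_pos = c(0, 100 / 3, 200 / 3, 100),
                              cut_high = (200 / 3 + 60) / 2,
                              cut_moderate = 40) {
  anchors <- match.arg(anchors)
  stopifnot(length(anchor_or) == length(anchor_pos),
            all(diff(anchor_pos) > 0))
  if (anchors == "calibrated" && any(diff(anchor_or) <= 0))
    stop("anchor ORs must be strictly increasing")
  if (cut_moderate >= cut_high)
    stop("grade cut-offs must be strictly increasing")
  structure(list(anchors = anchors, anchor_or = anchor_or,
                 anchor_pos = anchor_pos, cut_high = cut_high,
                 cut_moderate = cut_moderate),
            class = "importance_scales")
}

or_scale_position_ <- function(or, scales, or_distribution) {
  anchor_or <- if (scales$anchors == "empirical") {
    if (!length(or_distribution)) stop("empty OR distribution")
    q <- stats::quantile(or_distribution, c(0, 0.33, 0.66, 1), names = FALSE,
                         type = 7)
    if (any(diff(q) <= 0))
      stop("degenerate OR distribution: percentile anchors are not increasing")
    q
  } else scales$anchor_or
  stats::approx(anchor_or, scales$anchor_pos, xout = or, rule = 2)$y
}

#' Grade the importance of a significant logical attribute
#'
#' Combines the size of the (small-sample-adjusted) odds ratio with the
#' true-positive rate: the OR is positioned on a 0-100 scale, the TPR on its
#' own 0-100 scale, and the midpoint of the two positions is mapped through
#' the grade cut-offs. Protective rules (OR < 1) are graded by the inverse
#' rule: `1/OR` on the OR scale and `1 - TPR` on the TPR scale. A
#' non-significant input grades `not_significant` regardless of its values.
#'
#' @param or_small adjusted odds ratio(s).
#' @param tpr true positive rate(s) in \[0, 1\].
#' @param or_distribution the significant ORs of the run (used by the
#'   empirical anchor mode).
#' @param scales an [importance_scales()].
#' @param significant logical; is the rule a discriminator (exact p < alpha)?
#' @return Factor with levels `not_significant`, `low`, `moderate`, `high`.
#' @export
grade_importance <- function(or_small, tpr, or_distribution = numeric(),
                             scales = importance_scales(),
                             significant = TRUE) {
  n <- max(length(or_small), length(tpr))
  or_small <- rep_len(or_small, n)
  tpr <- rep_len(tpr, n)
  significant <- rep_len(significant, n)
  protective <- !is.na(or_small) & or_small < 1
  or_eff <- ifelse(protective, 1 / or_small, or_small)   # Inf allowed: clamps
  tpr_eff <- ifelse(protective, 1 - tpr, tpr)
  pos_or <- or_scale_position_(pmin(or_eff, .Machine$double.xmax), scales,
                               or_distribution)
  mid <- (pos_or + 100 * tpr_eff) / 2
  grade <- ifelse(!significant, "not_significant",
           ifelse(mid >= scales$cut_high, "high",
           ifelse(mid >= scales$cut_moderate, "moderate", "low")))
  factor(grade, levels = c("not_significant", "low", "moderate", "high"))
}

#' Detect commonalities among non-discriminating rules
#'
#' A commonality is a logical attribute that does not discriminate the
#' groups (exact p >= alpha) yet is met by a high proportion (default >= 60%)
#' of both groups — interpreted as a baseline requirement for participation
#' rather than a marker of high performance. The published procedure's
#' second criterion, theoretical relevance, needs a domain expert: the
#' returned table is a reviewer checklist, not an automated judgement.
#'
#' @param indicators named list of 0/1/NA indicator vectors (or of
#'   [binarize()] results), one per candidate rule.
#' @param labels a [group_labels()] or character vector.
#' @param prevalence_threshold minimum within-group prevalence, default 0.6.
#' @param alpha significance level separating discriminators from
#'   commonality candidates.
#' @return Data frame with one row per rule: prevalences, exact p, and the
#'   `commonality` flag.
#' @export
find_commonalities <- function(indicators, labels,
                               prevalence_threshold = 0.60, alpha = 0.05) {
  lab <- if (inherits(labels, "group_labels") || is.data.frame(labels))
    labels$label else as.character(labels)
  rows <- lapply(names(indicators), function(nm) {
    ind <- indicators[[nm]]
    if (inherits(ind, "logical_attribute")) ind <- ind$indicator
    ct <- contingency(ind, lab)
    prev_high <- ct["a"] / (ct["a"] + ct["c"])
    prev_low <- ct["b"] / (ct["b"] + ct["d"])
    p <- fisher_exact(ct)
    data.frame(attribute = nm, prev_high = unname(prev_high),
               prev_low = unname(prev_low), p = p,
               commonality = p >= alpha &
                 prev_high >= prevalence_threshold &
                 prev_low >= prevalence_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen every attribute of a cohort
#'
#' Runs the full screen: for each attribute, builds the 100-point threshold
#' grid, optimizes the threshold, forms the 2x2 table at the selected
#' threshold, and computes the adjusted OR, exact p, exact CI and TPR.
#' Importance is graded in a second pass, once the run's distribution of
#' significant ORs is known. No multiple-testing adjustment is applied (the
#' number of tests performed is reported so users can judge).
#'
#' @param ft a [feature_table()].
#' @param labels a [group_labels()] covering the table's athletes.
#' @param alpha significance level, default 0.05.
#' @param scales an [importance_scales()].
#' @param prevalence_threshold commonality prevalence cut-off.
#' @param directional,ties passed to [optimize_parameter()] / [binarize()].
#' @return A `screen_result` data frame with one row per attribute: the rule
#'   (`attribute > theta`), per-group exposure counts and percentages, OR
#'   with CI, p, TPR, importance grade, commonality flag, the optimizer
#'   branch, and exclusion tallies. Attributes `n_tests` and `or_distribution`
#'   record the run context.
#' @export
screen_cohort <- function(ft, labels, alpha = 0.05,
                          scales = importance_scales(),
                          prevalence_threshold = 0.60,
                          directional = c("onesided", "twosided"),
                          ties = c("zero", "one")) {
  stopifnot(inherits(ft, "feature_table"))
  directional <- match.arg(directional)
  ties <- match.arg(ties)
  lab <- labels$label[match(ft$athlete_id, labels$athlete_id)]
  if (anyNA(lab)) stop("labels do not cover all athletes")
  n_tests <- 0L
  rows <- vector("list", ncol(ft$values))
  for (j in seq_along(ft$values)) {
    v <- ft$values[[j]]
    nm <- names(ft$values)[j]
    pv <- parameter_vector(v)
    opt <- optimize_parameter(v, lab, vector = pv, alpha = alpha,
                              directional = directional, ties = ties)
    n_tests <- n_tests + if (pv$degenerate) 0L else
      length(unique(round(opt$grid, 12)))
    la <- binarize(v, opt$theta, name = nm, ties = ties)
    ct <- contingency(la, lab)
    or <- odds_ratio_small(ct)
    p <- fisher_exact(ct)
    ci <- fisher_ci(ct)
    rows[[j]] <- data.frame(
      attribute = nm, theta = opt$theta, status = opt$status,
      a = ct["a"], b = ct["b"], c = ct["c"], d = ct["d"],
      n_excluded = attr(ct, "excluded"),
      prev_high = ct["a"] / (ct["a"] + ct["c"]),
      prev_low = ct["b"] / (ct["b"] + ct["d"]),
      or_small = or, p = p, ci_low = ci[1], ci_high = ci[2],
      tpr = true_positive_rate(ct),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  sig <- res$p < alpha
  or_dist <- res$or_small[sig]
  res$importance <- grade_importance(res$or_small, res$tpr,
                                     or_distribution = or_dist,
                                     scales = scales, significant = sig)
  res$commonality <- !sig &
    res$prev_high >= prevalence_threshold &
    res$prev_low >= prevalence_threshold
  res$rule <- sprintf("%s > %g", res$attribute, res$theta)
  attr(res, "n_tests") <- n_tests
  attr(res, "or_distribution") <- or_dist
  attr(res, "alpha") <- alpha
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d attributes screened, %d discriminators (p < %g), %d commonalities; %d exact tests performed\n",
              nrow(x), sum(x$p < attr(x, "alpha")), attr(x, "alpha"),
              sum(x$commonality), attr(x, "n_tests")))
  invisible(x)
}

#' Export a discriminator table in the published layout
#'
#' One row per discriminating rule: attribute rule, low-group count/percent,
#' high-group count/percent, OR with CI, importance.
#'
#' @param screen a [screen_cohort()] result.
#' @param path optional CSV output path.
#' @return The formatted data frame (invisibly written to `path` if given).
#' @export
discriminator_table <- function(screen, path = NULL) {
  alpha <- attr(screen, "alpha")
  d <- screen[screen$p < alpha, , drop = FALSE]
  out <- data.frame(
    rule = d$rule,
    low_performing = sprintf("%d/%d (%.1f%%)", d$b, d$b + d$d,
                             100 * d$prev_low),
    high_performing = sprintf("%d/%d (%.1f%%)", d$a, d$a + d$c,
                              100 * d$prev_high),
    or_ci = sprintf("%.2f (%.2f-%.2f)", d$or_small, d$ci_low,
                    pmin(d$ci_high, 1e6)),
    importance = as.character(d$importance),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
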