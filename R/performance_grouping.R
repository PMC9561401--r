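# High/low performance labels from competition records via percentile
# standing against a normative reference population.

#' Group labels
#'
#' @param athlete_id character vector of unique athlete ids.
#' @param label `"high"` or `"low"` per athlete.
#' @param threshold percentile threshold used, in (0, 100).
#' @param best_percentile optional best total-percentile per athlete.
#' @param window optional description of the evaluation window.
#' @return A `group_labels` data frame.
#' @export
group_labels <- function(athlete_id, label, threshold = 80,
                         best_percentile = NA_real_, window = "all") {
  athlete_id <- as.character(athlete_id)
  if (anyDuplicated(athlete_id)) stop("every athlete labeled exactly once")
  label <- as.character(label)
  if (!all(label %in% c("high", "low")))
    stop("labels must be 'high' or 'low'")
  stopifnot(threshold > 0, threshold < 100)
  gl <- data.frame(athlete_id = athlete_id, label = label,
                   best_percentile = best_percentile,
                   stringsAsFactors = FALSE)
  attr(gl, "threshold") <- threshold
  attr(gl, "window") <- window
  class(gl) <- c("group_labels", "data.frame")
  gl
}

#' @export
print.group_labels <- function(x, ...) {
  cat(sprintf("<group_labels> %d athletes: %d high / %d low (threshold %g)\n",
              nrow(x), sum(x$label == "high"), sum(x$label == "low"),
              attr(x, "threshold")))
  invisible(x)
}

#' Empirical percentile of a total within its reference stratum
#'
#' The percentile is the weak empirical standing:
#' `100 * #(reference <= total) / #reference`, so a total equal to the
#' stratum maximum stands at 100 and one below the stratum minimum at 0.
#'
#' @param total competition total (kg); vectorized.
#' @param stratum performance-stratum key(s), see [stratum_key()].
#' @param reference a [norms_table()] whose `reference` element holds the
#'   stratum samples.
#' @return Percentile(s) in \[0, 100\].
#' @export
performance_percentile <- function(total, stratum, reference) {
  stopifnot(inherits(reference, "norms_table"))
  stratum <- rep_len(as.character(stratum), length(total))
  vapply(seq_along(total), function(i) {
    ref <- reference$reference[[stratum[i]]]
    if (is.null(ref) || !length(ref))
      stop("empty or missing reference stratum: ", stratum[i])
    100 * sum(ref <= total[i]) / length(ref)
  }, numeric(1))
}

#' Assign performance groups from competition records
#'
#' An athlete is labeled `high` when their summary total-percentile across
#' the evaluation window is at or above the threshold (default: the 80th
#' percentile of the reference population for their age group, sex and
#' bodyweight class), otherwise `low`. Raising the threshold never moves an
#' athlete from low to high, and labels do not depend on record order.
#'
#' @param records a [performance_records()] table; every athlete needs at
#'   least one record.
#' @param reference a [norms_table()] with performance reference samples.
#' @param threshold percentile threshold in (0, 100); default 80.
#' @param summary how to summarize multiple records per athlete: the
#'   `"best"` (default) or the `"latest"` record's percentile.
#' @return A [group_labels()] with each athlete's summary percentile.
#' @export
assign_performance_groups <- function(records, reference, threshold = 80,
                                      summary = c("best", "latest")) {
  summary <- match.arg(summary)
  stopifnot(inherits(reference, "norms_table"))
  if (!nrow(records)) stop("no records supplied")
  key <- stratum_key(records$age_group, records$sex, records$bw_class)
  pct <- performance_percentile(records$total, key, reference)
  ids <- unique(records$athlete_id)
  per_ath <- vapply(ids, function(id) {
    i <- which(records$athlete_id == id)
    if (summary == "best") max(pct[i])
    else pct[i[order(records$date[i])][length(i)]]
  }, numeric(1))
  no_rec <- ids[is.na(per_ath)]
  if (length(no_rec))
    stop("athletes without usable records: ", paste(no_rec, collapse = ", "))
  group_labels(ids,
               ifelse(per_ath >= threshold, "high", "low"),
               threshold = threshold,
               best_percentile = unname(per_ath),
               window = summary)
}
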