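#' @keywords internal
"_PACKAGE"

THEMES <- c("demographics", "physiology", "psychosocial",
            "sport_history", "practice_microstructure")

DTYPES <- c("continuous", "likert_1_7", "hours_per_week",
            "proportion_0_1", "binary", "count")

#' Attribute codebook
#'
#' A codebook describes every attribute of a cohort: its developmental theme,
#' its data type (which drives validation and synthetic generation) and
#' whether it is expressed as a deviation from an age/sex norm.
#'
#' @param name character vector of unique attribute names.
#' @param theme developmental theme, one of
#'   `"demographics"`, `"physiology"`, `"psychosocial"`, `"sport_history"`,
#'   `"practice_microstructure"` (recycled).
#' @param dtype data type, one of `"continuous"`, `"likert_1_7"`,
#'   `"hours_per_week"`, `"proportion_0_1"`, `"binary"`, `"count"`
#'   (recycled).
#' @param norm_adjusted logical; is the attribute expressed as a deviation
#'   from the age/sex norm? (recycled).
#' @param order_key numeric key used to order attributes chronologically in
#'   radar exports; defaults to position in the codebook.
#' @return A `codebook` object (a validated data frame).
#' @export
codebook <- function(name, theme = "demographics", dtype = "continuous",
                     norm_adjusted = FALSE, order_key = seq_along(name)) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicate attribute names in codebook: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  cb <- data.frame(name = name,
                   theme = rep_len(as.character(theme), length(name)),
                   dtype = rep_len(as.character(dtype), length(name)),
                   norm_adjusted = rep_len(as.logical(norm_adjusted),
                                           length(name)),
                   order_key = rep_len(as.numeric(order_key), length(name)),
                   stringsAsFactors = FALSE)
  bad_theme <- setdiff(unique(cb$theme), THEMES)
  if (length(bad_theme))
    stop("unknown theme(s): ", paste(bad_theme, collapse = ", "))
  bad_dtype <- setdiff(unique(cb$dtype), DTYPES)
  if (length(bad_dtype))
    stop("unknown dtype(s): ", paste(bad_dtype, collapse = ", "))
  class(cb) <- c("codebook", "data.frame")
  cb
}

#' Feature table of athletes by attributes
#'
#' The central container: a rectangular numeric table of athletes (rows) by
#' developmental attributes (columns), with an explicit `NA` missing marker
#' and a mandatory codebook entry per column.
#'
#' @param values numeric data frame or matrix, athletes in rows, attributes
#'   in columns; column names must match codebook entries.
#' @param codebook a [codebook()].
#' @param athlete_id character vector of unique athlete identifiers; defaults
#'   to row names or `ath_1 ... ath_n`.
#' @return A `feature_table` object: a list with elements `values`
#'   (numeric data frame), `athlete_id` and `codebook`.
#' @export
feature_table <- function(values, codebook, athlete_id = NULL) {
  values <- as.data.frame(values)
  if (is.null(athlete_id)) {
    athlete_id <- if (!is.null(rownames(values)) &&
                      !identical(rownames(values),
                                 as.character(seq_len(nrow(values)))))
      rownames(values) else sprintf("ath_%d", seq_len(nrow(values)))
  }
  athlete_id <- as.character(athlete_id)
  if (length(athlete_id) != nrow(values))
    stop("athlete_id length does not match number of rows")
  if (anyDuplicated(athlete_id))
    stop("athlete ids must be unique")
  missing_cb <- setdiff(names(values), codebook$name)
  if (length(missing_cb))
    stop("no codebook entry for column(s): ",
         paste(missing_cb, collapse = ", "))
  for (j in names(values)) values[[j]] <- as.numeric(values[[j]])
  rownames(values) <- NULL
  ft <- structure(
    list(values = values,
         athlete_id = athlete_id,
         codebook = codebook[match(names(values), codebook$name), ,
                             drop = FALSE]),
    class = "feature_table")
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d athletes x %d attributes\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$codebook$theme)
  cat("themes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Validate a feature table against its codebook
#'
#' Checks each cell against the constraints implied by its attribute dtype
#' (Likert in \[1, 7\], proportions in \[0, 1\], counts non-negative
#' integers, binary in \{0, 1\}, non-negative weekly hours). Missing cells
#' are always valid.
#'
#' @param ft a [feature_table()].
#' @return Data frame of violations with columns `row` (athlete index),
#'   `athlete_id`, `column`, `value`, `rule`; zero rows when the table is
#'   clean.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  out <- list()
  for (j in seq_along(ft$values)) {
    v <- ft$values[[j]]
    dtype <- ft$codebook$dtype[j]
    bad <- switch(dtype,
      likert_1_7     = which(!is.na(v) & (v < 1 | v > 7)),
      proportion_0_1 = which(!is.na(v) & (v < 0 | v > 1)),
      count          = which(!is.na(v) & (v < 0 | v != floor(v))),
      binary         = which(!is.na(v) & !(v %in% c(0, 1))),
      hours_per_week = which(!is.na(v) & v < 0),
      continuous     = which(!is.na(v) & !is.finite(v)))
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        row = bad, athlete_id = ft$athlete_id[bad],
        column = names(ft$values)[j], value = v[bad],
        rule = dtype, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(), athlete_id = character(),
               column = character(), value = numeric(), rule = character(),
               stringsAsFactors = FALSE)
}

#' Read a cohort from delimited text
#'
#' Reads a comma-separated feature table (header row of attribute names,
#' first column `athlete_id`) together with its codebook, validates cell
#' types against the codebook and reports violations with row/column
#' coordinates. Unparseable cells are recorded as missing with a warning; a
#' data column without a codebook entry is an error.
#'
#' @param table_path path to the feature-table CSV.
#' @param codebook_path path to the codebook CSV
#'   (columns `name,theme,dtype,norm_adjusted[,order_key]`).
#' @return A [feature_table()]; any type violations are attached as
#'   `attr(, "violations")` and reported with a warning.
#' @export
read_cohort <- function(table_path, codebook_path) {
  if (!file.exists(table_path)) stop("no such file: ", table_path)
  if (!file.exists(codebook_path)) stop("no such file: ", codebook_path)
  cb <- read_codebook(codebook_path)
  raw <- utils::read.csv(table_path, colClasses = "character",
                         check.names = FALSE)
  if (!"athlete_id" %in% names(raw))
    stop("feature table must have an 'athlete_id' column")
  ids <- raw$athlete_id
  raw <- raw[setdiff(names(raw), "athlete_id")]
  vals <- lapply(names(raw), function(j) {
    x <- raw[[j]]
    x[x == ""] <- NA_character_
    suppressWarnings(num <- as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad))
      warning(sprintf("column '%s': %d unparseable cell(s) set to missing (rows %s)",
                      j, length(bad),
                      paste(utils::head(bad, 5), collapse = ",")),
              call. = FALSE)
    num
  })
  names(vals) <- names(raw)
  ft <- feature_table(as.data.frame(vals, check.names = FALSE), cb,
                      athlete_id = ids)
  viol <- validate_feature_table(ft)
  if (nrow(viol))
    warning(sprintf("%d cell(s) violate their dtype constraints; see attr(x, 'violations')",
                    nrow(viol)), call. = FALSE)
  attr(ft, "violations") <- viol
  ft
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: writes the feature table (with an
#' `athlete_id` first column and empty cells for missing values) and the
#' codebook as CSV. A write/read round trip reproduces all cells and missing
#' markers.
#'
#' @param ft a [feature_table()].
#' @param table_path,codebook_path output paths.
#' @return Invisibly, `table_path`.
#' @export
write_cohort <- function(ft, table_path, codebook_path) {
  stopifnot(inherits(ft, "feature_table"))
  out <- cbind(data.frame(athlete_id = ft$athlete_id,
                          stringsAsFactors = FALSE),
               ft$values)
  utils::write.csv(out, table_path, row.names = FALSE, na = "")
  write_codebook(ft$codebook, codebook_path)
  invisible(table_path)
}

#' @rdname read_cohort
#' @export
read_codebook <- function(codebook_path) {
  cbdf <- utils::read.csv(codebook_path, stringsAsFactors = FALSE)
  need <- c("name", "theme", "dtype", "norm_adjusted")
  miss <- setdiff(need, names(cbdf))
  if (length(miss))
    stop("codebook lacks column(s): ", paste(miss, collapse = ", "))
  codebook(cbdf$name, cbdf$theme, cbdf$dtype, cbdf$norm_adjusted,
           order_key = if ("order_key" %in% names(cbdf)) cbdf$order_key
                       else seq_len(nrow(cbdf)))
}

#' @rdname write_cohort
#' @param cb a [codebook()].
#' @export
write_codebook <- function(cb, codebook_path) {
  utils::write.csv(as.data.frame(cb), codebook_path, row.names = FALSE)
  invisible(codebook_path)
}

#' Competition performance records
#'
#' One row per athlete-competition with the lifted weights and the stratum
#' descriptors (sex, age group, bodyweight class) used for percentile
#' standing. When snatch, clean-and-jerk and total are all present the total
#' must equal their sum.
#'
#' @param athlete_id,date,snatch,clean_and_jerk,total,sex,age_group,bw_class
#'   record fields; `total` defaults to `snatch + clean_and_jerk`.
#' @return A `performance_records` data frame.
#' @export
performance_records <- function(athlete_id, date = NA, snatch = NA,
                                clean_and_jerk = NA, total = NULL,
                                sex, age_group, bw_class) {
  n <- length(athlete_id)
  if (is.null(total)) total <- snatch + clean_and_jerk
  pr <- data.frame(athlete_id = as.character(athlete_id), date = date,
                   snatch = as.numeric(snatch),
                   clean_and_jerk = as.numeric(clean_and_jerk),
                   total = as.numeric(total),
                   sex = as.character(sex),
                   age_group = as.character(age_group),
                   bw_class = as.character(bw_class),
                   stringsAsFactors = FALSE)
  full <- stats::complete.cases(pr[c("snatch", "clean_and_jerk", "total")])
  if (any(full & abs(pr$snatch + pr$clean_and_jerk - pr$total) > 1e-8))
    stop("total must equal snatch + clean_and_jerk where all are present")
  w <- c(pr$snatch, pr$clean_and_jerk, pr$total)
  if (any(!is.na(w) & w <= 0)) stop("lifted weights must be positive")
  class(pr) <- c("performance_records", "data.frame")
  pr
}

#' Stratum keys for normative lookups
#'
#' Performance strata are age group x sex x bodyweight class; anthropometric
#' strata are age group x sex.
#'
#' @param age_group,sex,bw_class stratum components; omit `bw_class` (or pass
#'   `NULL`) for anthropometric strata.
#' @return Character vector of keys.
#' @export
stratum_key <- function(age_group, sex, bw_class = NULL) {
  if (is.null(bw_class)) paste(age_group, sex, sep = "|")
  else paste(age_group, sex, bw_class, sep = "|")
}

#' Normative reference table
#'
#' Holds (a) expected values for norm-adjusted anthropometric attributes per
#' age/sex stratum and (b) reference samples of competition totals per
#' age/sex/bodyweight performance stratum, against which athlete percentiles
#' are computed.
#'
#' @param expected data frame with columns `stratum`, `attribute`,
#'   `expected` (may have zero rows).
#' @param reference named list mapping performance-stratum keys to non-empty
#'   numeric vectors of reference totals.
#' @return A `norms_table` object.
#' @export
norms_table <- function(expected = NULL, reference = NULL) {
  if (is.null(expected))
    expected <- data.frame(stratum = character(), attribute = character(),
                           expected = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("stratum", "attribute", "expected") %in% names(expected)))
  if (is.null(reference)) reference <- list()
  if (length(reference)) {
    if (is.null(names(reference)) || any(names(reference) == ""))
      stop("reference samples must be a named list keyed by stratum")
    empty <- names(reference)[!vapply(reference, length, 1L)]
    if (length(empty))
      stop("empty reference sample for stratum: ",
           paste(empty, collapse = ", "))
  }
  structure(list(expected = expected, reference = reference),
            class = "norms_table")
}

#' @export
print.norms_table <- function(x, ...) {
  cat(sprintf("<norms_table> %d expected-value rows, %d performance strata\n",
              nrow(x$expected), length(x$reference)))
  invisible(x)
}

#' Deviation of a measurement from its age/sex norm
#'
#' Returns `value - expected(stratum)`, the quantity on which logical
#' attributes such as "tibia length > 3.79 cm above norm" operate.
#' Translation-equivariant: shifting both the value and the norm by a
#' constant leaves the deviation unchanged.
#'
#' @param value measurement (vectorized).
#' @param stratum anthropometric stratum key(s), see [stratum_key()].
#' @param norms a [norms_table()].
#' @param attribute attribute name to look up in the expected-value table.
#' @return Numeric deviation in the measurement's units.
#' @export
norm_deviation <- function(value, stratum, norms, attribute) {
  stopifnot(inherits(norms, "norms_table"))
  key <- paste(norms$expected$stratum, norms$expected$attribute, sep = "\r")
  idx <- match(paste(stratum, attribute, sep = "\r"), key)
  if (anyNA(idx)) {
    bad <- unique(stratum[is.na(idx)])
    stop("unknown stratum for attribute '", attribute, "': ",
         paste(bad, collapse = ", "))
  }
  value - norms$expected$expected[idx]
}
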