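# Orchestration of the full analysis: grouping, screening, model selection,
# classification, and plot-ready exports, with config, logging and seeds.

#' Pipeline run configuration
#'
#' Either a simulation config (`cohort`) or input paths must be supplied.
#' The validated config is serialized next to the outputs of every run.
#'
#' @param cohort a [cohort_config()] for synthetic runs, or `NULL`.
#' @param table_path,codebook_path,labels_path input files for runs on real
#'   data (`labels_path` is a CSV with `athlete_id,label`).
#' @param alpha screening significance level.
#' @param percentile_threshold performance-grouping percentile.
#' @param scales an [importance_scales()].
#' @param k top-k cut for the consensus model.
#' @param positive positive class for classifier metrics.
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = cohort_config(), table_path = NULL,
                       codebook_path = NULL, labels_path = NULL,
                       alpha = 0.05, percentile_threshold = 80,
                       scales = importance_scales(), k = 20,
                       positive = "low", seed = 1L, out_dir = NULL) {
  if (is.null(cohort) && (is.null(table_path) || is.null(codebook_path)))
    stop("supply either a cohort simulation config or table + codebook paths")
  stopifnot(alpha > 0, alpha < 1,
            percentile_threshold > 0, percentile_threshold < 100)
  structure(list(cohort = cohort, table_path = table_path,
                 codebook_path = codebook_path, labels_path = labels_path,
                 alpha = alpha, percentile_threshold = percentile_threshold,
                 scales = scales, k = k, positive = positive,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash_ <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL    # hash the scientific config, not the output path
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# CSV with a one-line provenance header; read back with comment.char = "#"
write_output_ <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# talentscreen seed=%d config_hash=%s", seed, hash),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their methodological order: performance grouping
#' (for simulated cohorts the generator's labels are reproduced from the
#' generated competition records), threshold-optimized odds-ratio screening,
#' min-max normalization and four-way feature ranking, consensus model
#' selection, LOOCV classifier evaluation, and radar-data export. Runs are
#' idempotent given the seed; every output file embeds the seed and a config
#' hash on its first line.
#'
#' @param config a [run_config()].
#' @return A list (class `pipeline_result`): `labels`, `screen`, `rankings`,
#'   `model`, `directions`, `eval`, `radar`, `config`, plus `paths` when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash_(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$cohort)) {
    config$cohort$seed <- config$seed
    sim <- stage("simulate", generate_cohort(config$cohort))
    ft <- sim$features
    labels <- stage("group",
                    assign_performance_groups(sim$records, sim$norms,
                                              config$percentile_threshold))
    # align to the feature table's athlete order
    labels <- labels[match(ft$athlete_id, labels$athlete_id), ]
    class(labels) <- c("group_labels", "data.frame")
  } else {
    ft <- stage("read", read_cohort(config$table_path, config$codebook_path))
    lb <- utils::read.csv(config$labels_path, stringsAsFactors = FALSE)
    labels <- stage("group", group_labels(lb$athlete_id, lb$label,
                                          config$percentile_threshold))
  }

  screen <- stage("screen",
                  screen_cohort(ft, labels, alpha = config$alpha,
                                scales = config$scales))
  message(sprintf("screen: %d exact tests, %d athlete-cells excluded, branches both/single/fallback/degenerate = %d/%d/%d/%d",
                  attr(screen, "n_tests"), sum(screen$n_excluded),
                  sum(screen$status == "both"),
                  sum(screen$status == "single"),
                  sum(screen$status == "fallback"),
                  sum(screen$status == "degenerate")))

  norm <- stage("normalize", minmax_normalize(ft))
  rankings <- stage("select", lapply(RANK_METHODS, function(m)
    rank_features(norm, labels, m, k = config$k, seed = config$seed)))
  model <- stage("select", consensus_model(rankings, k = config$k))

  directions <- NULL; ev <- NULL; radar <- NULL
  if (nrow(model)) {
    directions <- t(vapply(model$attribute, direction_of_influence,
                           character(2), ft = norm, labels = labels))
    ev <- stage("classify",
                evaluate_classifiers(norm, model, labels,
                                     positive = config$positive,
                                     seed = config$seed))
    radar <- stage("report", export_radar_data(model, norm, labels))
  } else {
    message("consensus model is empty; classification stage skipped")
  }

  out <- structure(list(labels = labels, screen = screen,
                        rankings = rankings, model = model,
                        directions = directions, eval = ev, radar = radar,
                        config = config, config_hash = hash),
                   class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_output_(as.data.frame(labels), p("labels.csv"), config$seed, hash)
    write_output_(as.data.frame(screen), p("screen.csv"), config$seed, hash)
    write_output_(discriminator_table(screen), p("discriminators.csv"),
                  config$seed, hash)
    if (nrow(model)) {
      mod_out <- cbind(as.data.frame(model),
                       direction_low = directions[, "low"],
                       direction_high = directions[, "high"])
      write_output_(mod_out, p("model.csv"), config$seed, hash)
      write_output_(as.data.frame(ev$report), p("classifier_report.csv"),
                    config$seed, hash)
      write_output_(do.call(rbind, ev$predictions), p("predictions.csv"),
                    config$seed, hash)
      write_output_(radar, p("radar.csv"), config$seed, hash)
    }
    writeLines(jsonlite::toJSON(list(seed = config$seed, config_hash = hash,
                                     alpha = config$alpha,
                                     k = config$k,
                                     n_tests = attr(screen, "n_tests")),
                                auto_unbox = TRUE, pretty = TRUE),
               p("run_info.json"))
    out$paths <- vapply(c("labels.csv", "screen.csv", "discriminators.csv",
                          "run_info.json"), p, character(1))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$labels); print(x$screen)
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$eval)) print(x$eval$report)
  invisible(x)
}

#' Radar-plot data for the summary model
#'
#' One row per model feature with the min-max-normalized group means (both
#' in \[0, 1\]), ordered by the codebook's chronological `order_key` — the
#' layout of the published radar figure.
#'
#' @param model a [consensus_model()] (or character vector of features).
#' @param norm_ft the min-max-normalized [feature_table()].
#' @param labels a [group_labels()].
#' @return Data frame `attribute`, `tier`, `mean_low`, `mean_high`.
#' @export
export_radar_data <- function(model, norm_ft, labels) {
  feats <- if (is.data.frame(model)) model$attribute else as.character(model)
  if (!length(feats)) stop("empty model")
  missing_f <- setdiff(feats, names(norm_ft$values))
  if (length(missing_f))
    stop("model features missing from table: ",
         paste(missing_f, collapse = ", "))
  lab <- labels$label[match(norm_ft$athlete_id, labels$athlete_id)]
  ord <- order(norm_ft$codebook$order_key[match(feats, norm_ft$codebook$name)])
  feats <- feats[ord]
  tier <- if (is.data.frame(model)) as.character(model$tier)[ord] else
    rep(NA_character_, length(feats))
  rows <- lapply(seq_along(feats), function(i) {
    v <- norm_ft$values[[feats[i]]]
    data.frame(attribute = feats[i], tier = tier[i],
               mean_low = mean(v[lab == "low"], na.rm = TRUE),
               mean_high = mean(v[lab == "high"], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
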