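# Synthetic cohorts with the statistical structure the screening pipeline
# assumes: two small performance groups, a large block of mixed-type
# developmental attributes, and optional planted discriminative attributes.

#' Planted discriminative attribute
#'
#' Describes one attribute whose distribution differs between the performance
#' groups. `prevalence_shift` plants a latent exceedance: a fraction `p_high`
#' of the high group and `p_low` of the low group lie above a latent
#' threshold (the quantity the screening stage should rediscover).
#' `mean_shift` plants a standardized location shift.
#'
#' @param name attribute name (must be unique among planted effects).
#' @param mechanism `"prevalence_shift"` or `"mean_shift"`.
#' @param p_high,p_low exceedance probabilities per group
#'   (prevalence_shift only), both in \[0, 1\].
#' @param effect_size standardized mean difference (mean_shift only).
#' @param noise standard deviation of nuisance noise added after planting.
#' @param exact if `TRUE`, plant exactly `round(p * n)` exceedances per group
#'   instead of Bernoulli draws.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(name,
                           mechanism = c("prevalence_shift", "mean_shift"),
                           p_high = 0.8, p_low = 0.05, effect_size = 2,
                           noise = 0, exact = FALSE) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "prevalence_shift") {
    stopifnot(p_high >= 0, p_high <= 1, p_low >= 0, p_low <= 1)
  } else {
    stopifnot(is.finite(effect_size))
  }
  structure(list(name = as.character(name), mechanism = mechanism,
                 p_high = p_high, p_low = p_low, effect_size = effect_size,
                 noise = noise, exact = isTRUE(exact)),
            class = "planted_effect")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions the pipeline was designed for:
#' 23 low-performing and 6 high-performing athletes described by 648
#' mixed-type attributes across five developmental themes.
#'
#' @param n_low,n_high group sizes (both >= 1).
#' @param n_attributes total number of attributes, planted ones included.
#' @param theme_mix named numeric vector of theme proportions summing to 1.
#' @param planted_effects list of [planted_effect()]s with unique names.
#' @param seed integer seed; every [generate_cohort()] call with the same
#'   config is bit-identical.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_low = 23, n_high = 6, n_attributes = 648,
                          theme_mix = c(demographics = 0.03,
                                        physiology = 0.10,
                                        psychosocial = 0.04,
                                        sport_history = 0.38,
                                        practice_microstructure = 0.45),
                          planted_effects = list(), seed = 1L) {
  stopifnot(n_low >= 1, n_high >= 1, n_attributes >= 1)
  if (!setequal(names(theme_mix), THEMES))
    stop("theme_mix must name all five themes")
  if (abs(sum(theme_mix) - 1) > 1e-8)
    stop("theme_mix proportions must sum to 1")
  nms <- vapply(planted_effects, function(e) e$name, character(1))
  if (anyDuplicated(nms))
    stop("planted attribute name collision: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (length(nms) > n_attributes)
    stop("more planted effects than attributes")
  structure(list(n_low = n_low, n_high = n_high,
                 n_attributes = n_attributes,
                 theme_mix = theme_mix[THEMES],
                 planted_effects = planted_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# largest-remainder apportionment of n items to proportions p
apportion_ <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

# Likert scale score: mean of n_items latent-normal items each discretized
# to 1..7 (scores land on a 1/n_items grid, like questionnaire subscales)
r_likert_ <- function(n, mu = 4, sd = 1.3, n_items = 4) {
  items <- matrix(pmin(7, pmax(1, round(stats::rnorm(n * n_items, mu, sd)))),
                  nrow = n)
  rowMeans(items)
}

# zero-inflated lognormal weekly training hours
r_hours_ <- function(n, p_zero = 0.5, meanlog = 0.4, sdlog = 0.8) {
  ifelse(stats::runif(n) < p_zero, 0, stats::rlnorm(n, meanlog, sdlog))
}

# latent exceedance column: P(value > tau) = p within each group
r_prevalence_shift_ <- function(labels, p_high, p_low, tau = 1,
                                noise = 0, exact = FALSE) {
  n <- length(labels)
  p <- ifelse(labels == "high", p_high, p_low)
  if (exact) {
    exposed <- logical(n)
    for (g in c("high", "low")) {
      idx <- which(labels == g)
      pg <- if (g == "high") p_high else p_low
      k <- as.integer(round(pg * length(idx)))
      exposed[idx[seq_len(k)]] <- TRUE
    }
  } else {
    exposed <- stats::runif(n) < p
  }
  ptau <- stats::pnorm(tau)
  u <- ifelse(exposed,
              stats::runif(n, ptau, 1),
              stats::runif(n, 0, ptau))
  stats::qnorm(u) + if (noise > 0) stats::rnorm(n, 0, noise) else 0
}

#' Generate a synthetic cohort
#'
#' Produces a feature table, group labels, per-athlete competition records
#' consistent with those labels, and a normative reference table. Non-planted
#' attributes are identically distributed in both groups; planted attributes
#' follow their configured group-conditional distributions. Given the config
#' seed the output is bit-identical across calls.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `features` ([feature_table()]), `labels`
#'   ([group_labels()]), `records` ([performance_records()]) and `norms`
#'   ([norms_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_(config$seed, generate_cohort_(config))
}

generate_cohort_ <- function(config) {
  n <- config$n_low + config$n_high
  labels <- rep(c("low", "high"), c(config$n_low, config$n_high))
  ids <- sprintf("ath_%02d", seq_len(n))

  n_theme <- apportion_(config$n_attributes, config$theme_mix)
  names(n_theme) <- THEMES
  theme <- rep(THEMES, n_theme)
  name <- sprintf("attr_%04d", seq_len(config$n_attributes))

  dtype <- character(config$n_attributes)
  norm_adj <- logical(config$n_attributes)
  cols <- vector("list", config$n_attributes)
  prop_family <- 0L  # rotating Dirichlet family accumulator
  fam_left <- 0L; fam_alpha <- NULL; fam_draws <- NULL; fam_col <- 0L
  for (j in seq_len(config$n_attributes)) {
    th <- theme[j]
    if (th == "demographics") {
      r <- j %% 3
      if (r == 0) { dtype[j] <- "binary"; cols[[j]] <- stats::rbinom(n, 1, 0.4) }
      else if (r == 1) { dtype[j] <- "count"; cols[[j]] <- stats::rpois(n, 2) }
      else { dtype[j] <- "continuous"
             cols[[j]] <- stats::rlnorm(n, log(20000), 1) }  # population-like
    } else if (th == "physiology") {
      dtype[j] <- "continuous"; norm_adj[j] <- TRUE
      cols[[j]] <- stats::rnorm(n, 0, 2)   # deviation from age/sex norm
    } else if (th == "psychosocial") {
      dtype[j] <- "likert_1_7"
      cols[[j]] <- r_likert_(n)
    } else if (th == "sport_history") {
      if (j %% 5 == 0) { dtype[j] <- "count"; cols[[j]] <- stats::rpois(n, 3) }
      else { dtype[j] <- "hours_per_week"; cols[[j]] <- r_hours_(n) }
    } else {  # practice_microstructure: Dirichlet families of 4 + hours
      if (j %% 2 == 0) {
        dtype[j] <- "hours_per_week"; cols[[j]] <- r_hours_(n, p_zero = 0.3)
      } else {
        dtype[j] <- "proportion_0_1"
        if (fam_left == 0L) {    # start a new 4-component practice family
          fam_alpha <- c(2, 1.5, 1, 0.5)
          g <- matrix(stats::rgamma(n * 4, shape = rep(fam_alpha, each = n)),
                      nrow = n)
          fam_draws <- g / rowSums(g)
          fam_left <- 4L; fam_col <- 0L
        }
        fam_col <- fam_col + 1L
        cols[[j]] <- fam_draws[, fam_col]
        fam_left <- fam_left - 1L
      }
    }
  }

  # plant effects into the leading columns, keeping the planted names
  for (k in seq_along(config$planted_effects)) {
    e <- config$planted_effects[[k]]
    name[k] <- e$name
    theme[k] <- theme[k]
    dtype[k] <- "continuous"
    norm_adj[k] <- FALSE
    cols[[k]] <- if (e$mechanism == "prevalence_shift")
      r_prevalence_shift_(labels, e$p_high, e$p_low,
                          noise = e$noise, exact = e$exact)
    else
      stats::rnorm(n, ifelse(labels == "high", e$effect_size, 0), 1) +
        if (e$noise > 0) stats::rnorm(n, 0, e$noise) else 0
  }
  if (anyDuplicated(name))
    stop("planted attribute name collision with generated names")

  vals <- as.data.frame(cols, col.names = name, check.names = FALSE)
  cb <- codebook(name, theme, dtype, norm_adj)
  ft <- feature_table(vals, cb, athlete_id = ids)

  # strata, norms and competition records consistent with the labels
  sex <- rep(c("M", "F"), length.out = n)
  age_group <- rep(c("U15", "U17", "U20"), length.out = n)
  bw_class <- rep(c("55", "61", "67", "73"), length.out = n)
  strata <- unique(data.frame(age_group = age_group, sex = sex,
                              bw_class = bw_class,
                              stringsAsFactors = FALSE))
  norms <- generate_reference_population_(strata, n_per_stratum = 100)
  recs <- lapply(seq_len(n), function(i) {
    key <- stratum_key(age_group[i], sex[i], bw_class[i])
    ref <- sort(norms$reference[[key]])
    m <- length(ref)
    cut <- ref[ceiling(0.8 * m)]   # totals >= cut stand at or above the 80th
    tot <- if (labels[i] == "high") {
      hi <- ref[ref >= cut]
      hi[sample.int(length(hi), 1)]
    } else {
      lo <- ref[ref < cut]
      lo[sample.int(length(lo), 1)] - 0.5
    }
    sn <- round(0.45 * tot, 1)
    data.frame(athlete_id = ids[i], date = sprintf("2020-%02d-01",
                                                   sample.int(12, 1)),
               snatch = sn, clean_and_jerk = tot - sn, total = tot,
               sex = sex[i], age_group = age_group[i],
               bw_class = bw_class[i], stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  recs <- performance_records(recs$athlete_id, recs$date, recs$snatch,
                              recs$clean_and_jerk, recs$total, recs$sex,
                              recs$age_group, recs$bw_class)

  list(features = ft,
       labels = group_labels(ids, labels, threshold = 80),
       records = recs,
       norms = norms)
}

#' Generate a normative reference population
#'
#' Builds a [norms_table()] whose performance strata each hold an i.i.d.
#' reference sample of competition totals, standing in for a national results
#' database; anthropometric strata hold expected values for norm-adjusted
#' attributes.
#'
#' @param strata data frame with columns `age_group`, `sex`, `bw_class`.
#' @param n_per_stratum reference sample size per stratum (>= 10).
#' @param seed integer seed.
#' @param anthro_attributes optional character vector; expected values are
#'   generated for each attribute in every age_group x sex stratum.
#' @return A [norms_table()].
#' @export
generate_reference_population <- function(strata, n_per_stratum = 100,
                                          seed = 1L,
                                          anthro_attributes = character()) {
  with_seed_(seed, generate_reference_population_(strata, n_per_stratum,
                                                  anthro_attributes))
}

generate_reference_population_ <- function(strata, n_per_stratum,
                                           anthro_attributes = character()) {
  stopifnot(n_per_stratum >= 10)
  keys <- stratum_key(strata$age_group, strata$sex, strata$bw_class)
  # stratum mean grows with bodyweight class and age group
  mu <- 60 + 10 * as.integer(factor(strata$age_group)) +
    0.8 * suppressWarnings(as.numeric(strata$bw_class))
  mu[is.na(mu)] <- 110
  reference <- lapply(seq_along(keys), function(s) {
    pmax(20, stats::rnorm(n_per_stratum, mu[s], 15))
  })
  names(reference) <- keys
  expected <- NULL
  if (length(anthro_attributes)) {
    ag <- unique(strata[c("age_group", "sex")])
    expected <- expand.grid(attribute = anthro_attributes,
                            idx = seq_len(nrow(ag)),
                            stringsAsFactors = FALSE)
    expected$stratum <- stratum_key(ag$age_group[expected$idx],
                                    ag$sex[expected$idx])
    expected$expected <- stats::rnorm(nrow(expected), 36, 4)
    expected <- expected[c("stratum", "attribute", "expected")]
  }
  norms_table(expected = expected, reference = reference)
}
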