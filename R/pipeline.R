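#' Pipeline run configuration
#'
#' Either synthetic (a [simulation_config()]) or file-based (paths to the four
#' CSV inputs). Every stochastic stage consumes a seed derived
#' deterministically from the master seed.
#'
#' @param simulation optional [simulation_config()]; if given, inputs are
#'   generated.
#' @param surveys,lakes,waterlevel,monthly input CSV paths (ignored when
#'   `simulation` is given; `monthly` may be NULL, in which case the driver
#'   stage is skipped).
#' @param seed master integer seed.
#' @param n_mc Monte-Carlo draws for the max-t adjustment.
#' @param n_perm PERMANOVA permutations.
#' @param stepwise_threshold GAMM backward-selection stopping p-value.
#' @param out output directory for tables, reports and the run manifest.
#' @return a `ddg_run_config` list.
#' @export
run_config <- function(simulation = NULL, surveys = NULL, lakes = NULL,
                       waterlevel = NULL, monthly = NULL,
                       seed = 1, n_mc = 10000, n_perm = 999,
                       stepwise_threshold = 0.05, out = NULL) {
  if (is.null(simulation) && (is.null(surveys) || is.null(lakes))) {
    stop("either a simulation config or survey + lake input paths are required")
  }
  cfg <- list(simulation = simulation, surveys = surveys, lakes = lakes,
              waterlevel = waterlevel, monthly = monthly, seed = as.integer(seed),
              n_mc = n_mc, n_perm = n_perm,
              stepwise_threshold = stepwise_threshold, out = out)
  class(cfg) <- "ddg_run_config"
  cfg
}

.stage_seed <- function(master, stage) {
  # deterministic per-stage seeds, kept within 32-bit integer range
  (as.integer(master) * 1009L + stage * 101L) %% 2147483562L + 1L
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full depth-diversity-gradient pipeline
#'
#' Executes filtering, richness partitioning, DDG peak measures and pattern
#' classification, robust depth contrasts, correlation and association tests,
#' environmental-driver reduction and GAMMs (when monthly physiochemistry is
#' available), PERMANOVA representativeness, invariability and trend tables.
#' All artifacts are written under `config$out` (if set) as CSV/JSON, plus a
#' manifest with seeds, tier counts and row counts. Identical config and seed
#' give an identical manifest.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly; the full set of result tables is attached
#'   as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ddg_run_config"))
  if (!is.null(config$simulation)) {
    system <- generate_lake_system(config$simulation)
    surveys <- system$surveys; lakes <- system$lakes
    waterlevel <- system$waterlevel; monthly <- system$monthly
  } else {
    surveys <- read_surveys(config$surveys)
    lakes <- read_lakes(config$lakes)
    waterlevel <- if (!is.null(config$waterlevel)) read_waterlevel(config$waterlevel)
    monthly <- if (!is.null(config$monthly)) read_monthly(config$monthly)
  }

  filtered <- filter_records(surveys, lakes)
  if (nrow(filtered) == 0) stop("stage filter: no records survive the selection rules")
  excl <- exclusion_log(filtered)

  profiles <- richness_profiles(filtered)
  measures <- suppressWarnings(ddg_measures(filtered))
  mt <- measure_table(measures, profiles)

  pat_freq <- sapply(c("alpha", "beta", "gamma"), function(cc)
    pattern_frequencies(measures, cc))

  comparisons <- lapply(c("alpha", "beta", "gamma"), function(cc) {
    cmp <- robust_depth_comparisons(profiles$depth, profiles[[cc]],
                                    n_mc = config$n_mc,
                                    seed = .stage_seed(config$seed, 1L))
    cmp$component <- cc
    cmp
  })
  comparisons <- do.call(rbind, comparisons)

  correlations <- component_correlations(profiles[, c("alpha", "beta", "gamma")])
  pat_counts <- t(sapply(c("alpha", "beta", "gamma"), function(cc)
    table(factor(measures$pattern[measures$component == cc],
                 levels = pattern_types()))))
  assoc <- tryCatch(
    pattern_component_association(pat_counts[, colSums(pat_counts) > 0, drop = FALSE]),
    error = function(e) NULL)

  # environmental drivers (skipped without monthly data)
  env <- NULL; pca <- NULL; gamms <- NULL; permanova <- NULL
  have_env <- !is.null(monthly) && nrow(monthly) > 0 && !is.null(waterlevel)
  if (have_env) {
    camps <- unique(filtered[, c("lake_id", "year")])
    env <- env_records(camps, monthly, lakes, waterlevel)
  }
  tiers <- dataset_tiers(filtered, env)
  if (have_env && nrow(tiers$environment_biodiversity) >= 10 &&
      length(unique(tiers$environment_biodiversity$lake_id)) >= 3) {
    pca <- pca_drivers(env)
    axes <- paste0("PC", seq_len(pca$retained))
    dat <- merge(mt, pca$scores[, c("lake_id", "year", axes)],
                 by = c("lake_id", "year"))
    responses <- setdiff(names(mt), c("lake_id", "year"))
    gamms <- lapply(responses, function(rr) {
      d <- dat[!is.na(dat[[rr]]), , drop = FALSE]
      tryCatch(fit_gamm(d, rr, axes, threshold = config$stepwise_threshold),
               error = function(e) NULL)
    })
    names(gamms) <- responses
    sub_keys <- paste(tiers$environment_biodiversity$lake_id,
                      tiers$environment_biodiversity$year)
    if (sum(!(paste(mt$lake_id, mt$year) %in% sub_keys)) >= 2) {
      permanova <- representativeness_check(
        mt[paste(mt$lake_id, mt$year) %in% sub_keys, ],
        mt, n_perm = config$n_perm, seed = .stage_seed(config$seed, 2L))
    }
  }

  ts_mt <- mt[mt$lake_id %in% unique(tiers$time_series$lake_id), , drop = FALSE]
  trends <- NULL; invar <- NULL
  if (nrow(ts_mt)) {
    trends <- trend_table(ts_mt)
    invar <- invariability_table(ts_mt)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lakeddg")),
    seed = config$seed,
    stage_seeds = list(depth_contrasts = .stage_seed(config$seed, 1L),
                       permanova = .stage_seed(config$seed, 2L)),
    exclusion_log = excl,
    tiers = list(
      biodiversity = list(campaigns = nrow(tiers$biodiversity),
                          transects = nrow(unique(filtered[, c("lake_id", "year", "transect_id")])),
                          lakes = length(unique(tiers$biodiversity$lake_id))),
      environment_biodiversity = list(
        campaigns = nrow(tiers$environment_biodiversity),
        lakes = length(unique(tiers$environment_biodiversity$lake_id))),
      time_series = list(campaigns = nrow(tiers$time_series),
                         lakes = length(unique(tiers$time_series$lake_id)))),
    rows = list(records = nrow(filtered), profiles = nrow(profiles),
                measures = nrow(measures)),
    stages_skipped = if (have_env) character(0) else "env_drivers"
  )

  results <- list(filtered = filtered, profiles = profiles, measures = measures,
                  measure_table = mt, pattern_frequencies = pat_freq,
                  comparisons = comparisons, correlations = correlations,
                  association = assoc, env = env, pca = pca, gamms = gamms,
                  permanova = permanova, trends = trends,
                  invariability = invar, tiers = tiers)

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) if (!is.null(df))
      write.csv(df, file.path(config$out, f), row.names = FALSE)
    w(profiles, "profiles.csv")
    w(measures, "ddg_measures.csv")
    w(mt, "measure_table.csv")
    w(comparisons, "comparisons.csv")
    w(as.data.frame(pat_freq), "pattern_histogram.csv")
    w(env, "env_records.csv")
    if (!is.null(pca)) w(as.data.frame(pca$loadings), "pca_loadings.csv")
    if (!is.null(trends)) {
      w(trends, "trends.csv")
      w(format_trend_table(trends), "trend_table.csv")
    }
    w(invar, "invariability.csv")
    if (!is.null(gamms)) {
      rep <- lapply(gamms, function(g) if (is.null(g)) NULL else
        list(retained = as.list(g$p_values), adj_r_squared = g$adj_r_squared,
             dev_explained = g$dev_explained,
             drop_contribution = as.list(g$drop_contribution)))
      .write_json(rep, file.path(config$out, "gamm_report.json"))
    }
    if (!is.null(permanova)) .write_json(permanova, file.path(config$out, "permanova.json"))
    .write_json(manifest, file.path(config$out, "manifest.json"))
  }
  attr(manifest, "results") <- results
  invisible(manifest)
}
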