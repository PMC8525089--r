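# Table of the twelve physiochemical variables with the across-lake location
# and spread of their annual means, and the seasonal amplitude used for the
# monthly sinusoid. Values below detection occur only for variables whose
# observed minimum is zero.
.env_variables <- function() {
  data.frame(
    variable  = c("Chl", "Cond", "N_tot", "NH4", "NO3", "O2diss",
                  "P_tot", "pH", "SiO2", "Temp", "Transp", "SAC"),
    mean      = c(7.58, 292.57, 0.66, 0.02, 0.37, 10.23,
                  0.01, 8.32, 1.68, 13.38, 451.74, 8.85),
    sd        = c(3.94, 61.96, 0.22, 0.02, 0.28, 0.51,
                  0.004, 0.11, 0.88, 2.09, 198.39, 7.84),
    amplitude = c(1.0, 15.0, 0.1, 0.01, 0.1, 1.0,
                  0.003, 0.05, 0.4, 8.0, 60.0, 1.5),
    detectable_zero = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                        TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic lake-system generator
#'
#' Defaults emulate the Bavarian monitoring design: 28 deep, natural, dimictic
#' lakes, three transects per campaign, four survey years (about 112 field
#' campaigns), a pool of 75 submerged species, and monthly physiochemistry
#' for 12 of the lakes with annual means centred on the study population.
#' Species depth niches are Gaussian: species s occurs at depth d with
#' probability `max_presence * exp(-(d - optimum)^2 / (2 tolerance^2))`,
#' scaled per lake by an affinity multiplier.
#'
#' @param n_lakes number of lakes.
#' @param n_transects transects per campaign (>= 2 to survive filtering).
#' @param years integer vector of survey years (every lake is mapped in all).
#' @param species_pool number of species in the regional pool.
#' @param n_env_lakes number of lakes with monthly physiochemistry.
#' @param optimum_mean,optimum_sd distribution of species depth optima (m,
#'   negative down).
#' @param tolerance_meanlog,tolerance_sdlog log-normal niche breadth (m).
#' @param max_presence_min,max_presence_max uniform range of the peak
#'   presence probability per species.
#' @param affinity_zero_prob probability a species is absent from a given
#'   lake (its affinity there is 0); lakes host sparse subsets of the pool,
#'   which produces between-lake turnover and per-lake richness in the range
#'   observed in deep-lake monitoring.
#' @param affinity_min,affinity_max uniform range of the per-lake affinity
#'   multiplier for species that do occur in the lake.
#' @param shoreline_frac fraction of the pool that are patchy shoreline
#'   specialists: shallow optima (`shoreline_optimum_mean`, sd
#'   `shoreline_optimum_sd`, tolerance `shoreline_tolerance`) and a
#'   per-transect reachability of only `1 - shoreline_patchiness`, so
#'   different transects hit different shoreline species. This concentrates
#'   between-transect turnover (beta richness) in the shallow classes, as
#'   shoreline habitat heterogeneity does in real lakes.
#' @param shoreline_optimum_mean,shoreline_optimum_sd,shoreline_tolerance
#'   niche parameters of the shoreline specialists (m).
#' @param shoreline_patchiness probability a shoreline specialist is out of
#'   reach of a given transect.
#' @param missing_month_prob probability a monthly sample is missing.
#' @param below_detection_prob probability a sample of a trace variable
#'   (NH4, NO3, P_tot, SiO2, SAC) is flagged below detection.
#' @param env_noise_sd Gaussian noise of monthly values, as a fraction of the
#'   variable's across-lake sd.
#' @param optimum_drift_per_year linear shift of all niche optima (m/yr;
#'   positive = shallower).
#' @param pool_drift_per_year linear growth of the available species pool
#'   (species/yr; may be negative).
#' @param seed mandatory integer seed.
#' @return a `ddg_sim_config` list.
#' @export
simulation_config <- function(n_lakes = 28, n_transects = 3,
                              years = 2014:2017, species_pool = 75,
                              n_env_lakes = 12,
                              optimum_mean = -2.8, optimum_sd = 1.0,
                              tolerance_meanlog = 0, tolerance_sdlog = 0.3,
                              max_presence_min = 0.4, max_presence_max = 0.9,
                              affinity_zero_prob = 0.6,
                              affinity_min = 0.3, affinity_max = 1.0,
                              shoreline_frac = 0.5,
                              shoreline_optimum_mean = -0.6,
                              shoreline_optimum_sd = 0.4,
                              shoreline_tolerance = 0.5,
                              shoreline_patchiness = 0.75,
                              missing_month_prob = 0.05,
                              below_detection_prob = 0.05,
                              env_noise_sd = 0.25,
                              optimum_drift_per_year = 0,
                              pool_drift_per_year = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(species_pool >= 1, n_transects >= 1, n_lakes >= 1,
            max_presence_min >= 0, max_presence_max <= 1,
            affinity_min >= 0, affinity_max <= 1,
            affinity_zero_prob >= 0, affinity_zero_prob <= 1,
            missing_month_prob >= 0, missing_month_prob <= 1,
            below_detection_prob >= 0, below_detection_prob <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "ddg_sim_config"
  cfg
}

.gauss_niche_prob <- function(d, optimum, tolerance, max_presence) {
  if (tolerance <= 0) return(ifelse(d == optimum, max_presence, 0))
  max_presence * exp(-(d - optimum)^2 / (2 * tolerance^2))
}

#' Generate a virtual lake system with known DDG structure
#'
#' Draws a species pool with Gaussian depth niches, simulates per-transect
#' presence/absence surveys with independent Bernoulli draws, and produces
#' lake metadata, water-level statistics and monthly physiochemistry in the
#' same schemas the readers in this package consume. The analytic expectation
#' of the alpha profile, `E[alpha](d) = sum_s p_s(d) * affinity(s, lake)`, and
#' its argmax over the four depth midpoints are returned as ground truth.
#' Identical configurations (including seed) give identical outputs.
#'
#' @param config a [simulation_config()].
#' @return list with `surveys`, `lakes`, `waterlevel`, `monthly` data.frames
#'   and `truth`: per lake the expected alpha profile (`expected_alpha`,
#'   lakes x depths) and expected peak depth (`expected_peak_depth`), plus
#'   the per-year niche pool used.
#' @export
generate_lake_system <- function(config) {
  stopifnot(inherits(config, "ddg_sim_config"))
  if (config$species_pool < 1) stop("species pool is empty")
  set.seed(config$seed)
  mids <- depth_midpoints()
  years <- sort(config$years)
  n_years <- length(years)

  # species pool, sized for the largest year under pool drift
  pool_by_year <- pmax(1L, round(config$species_pool +
    config$pool_drift_per_year * (seq_len(n_years) - 1L)))
  max_pool <- max(pool_by_year)
  species <- data.frame(
    species_id = sprintf("sp%03d", seq_len(max_pool)),
    optimum = stats::rnorm(max_pool, config$optimum_mean, config$optimum_sd),
    tolerance = stats::rlnorm(max_pool, config$tolerance_meanlog, config$tolerance_sdlog),
    max_presence = stats::runif(max_pool, config$max_presence_min, config$max_presence_max),
    shoreline = stats::runif(max_pool) < config$shoreline_frac,
    stringsAsFactors = FALSE
  )
  species$optimum[species$shoreline] <-
    stats::rnorm(sum(species$shoreline), config$shoreline_optimum_mean,
                 config$shoreline_optimum_sd)
  species$tolerance[species$shoreline] <- config$shoreline_tolerance
  species$transect_prob <- ifelse(species$shoreline,
                                  1 - config$shoreline_patchiness, 1)

  lakes <- data.frame(
    lake_id = sprintf("lake%02d", seq_len(config$n_lakes)),
    area = round(stats::rlnorm(config$n_lakes, log(624), 1.0), 1),
    max_depth = round(stats::runif(config$n_lakes, 12, 190), 1),
    mixing_regime = "dimictic",
    natural = TRUE,
    natural_water_level = TRUE,
    stringsAsFactors = FALSE
  )

  affinity <- matrix(stats::runif(config$n_lakes * max_pool,
                                  config$affinity_min, config$affinity_max),
                     nrow = config$n_lakes,
                     dimnames = list(lakes$lake_id, species$species_id))
  absent <- matrix(stats::runif(config$n_lakes * max_pool) < config$affinity_zero_prob,
                   nrow = config$n_lakes)
  affinity[absent] <- 0

  mlw <- stats::runif(config$n_lakes, 0.5, 2.0)
  wlf <- pmax(0.01, stats::rnorm(config$n_lakes, 0.58, 0.28))
  waterlevel <- data.frame(lake_id = lakes$lake_id,
                           MHW = mlw + wlf, MLW = mlw, WLF = wlf,
                           stringsAsFactors = FALSE)

  # surveys: independent Bernoulli presence per lake/year/transect/species/depth
  rows <- vector("list", config$n_lakes * n_years)
  idx <- 0L
  for (li in seq_len(config$n_lakes)) {
    for (yi in seq_len(n_years)) {
      npool <- pool_by_year[yi]
      shift <- config$optimum_drift_per_year * (yi - 1L)
      p <- sapply(seq_len(npool), function(s) {
        .gauss_niche_prob(mids, species$optimum[s] + shift,
                          species$tolerance[s], species$max_presence[s]) *
          affinity[li, s] * species$transect_prob[s]
      })  # depths x species
      nt <- config$n_transects
      draws <- array(stats::runif(nt * length(mids) * npool),
                     dim = c(nt, length(mids), npool))
      pres <- sweep(draws, c(2, 3), p, "<")
      hit <- which(pres, arr.ind = TRUE)
      if (nrow(hit)) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          lake_id = lakes$lake_id[li],
          year = years[yi],
          transect_id = sprintf("T%02d", hit[, 1]),
          depth_class = depth_classes()$label[hit[, 2]],
          taxon = species$species_id[hit[, 3]],
          rank = "species",
          growth_form = "submerged",
          kohler_freq = sample(5L, nrow(hit), replace = TRUE),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  surveys <- do.call(rbind, rows[seq_len(idx)])
  if (is.null(surveys)) surveys <- as_survey_records(
    data.frame(lake_id = character(), year = integer(), transect_id = character(),
               depth_class = character(), taxon = character(), rank = character(),
               growth_form = character(), kohler_freq = integer(),
               stringsAsFactors = FALSE))
  surveys <- surveys[order(surveys$lake_id, surveys$year, surveys$transect_id,
                           surveys$depth_class, surveys$taxon), , drop = FALSE]
  rownames(surveys) <- NULL
  surveys <- as_survey_records(surveys)

  # truth: expectation under the baseline year (no drift applied)
  p_base <- sapply(seq_len(config$species_pool), function(s) {
    .gauss_niche_prob(mids, species$optimum[s], species$tolerance[s],
                      species$max_presence[s])
  })  # depths x species
  tp <- species$transect_prob[seq_len(config$species_pool)]
  expected_alpha <- t(apply(affinity[, seq_len(config$species_pool), drop = FALSE],
                            1, function(a) as.vector(p_base %*% (a * tp))))
  colnames(expected_alpha) <- format(mids)
  expected_peak <- mids[apply(expected_alpha, 1, which.max)]

  monthly <- .generate_monthly(config, lakes, years)

  list(surveys = surveys, lakes = lakes, waterlevel = waterlevel,
       monthly = monthly, species = species,
       truth = list(expected_alpha = expected_alpha,
                    expected_peak_depth = stats::setNames(expected_peak, lakes$lake_id),
                    pool_by_year = stats::setNames(pool_by_year, years)))
}

# monthly physiochemistry: annual lake mean + seasonal sinusoid + noise;
# temperature at four depths with summer stratification so Tempsd is seasonal
.generate_monthly <- function(config, lakes, years) {
  ev <- .env_variables()
  n_env <- min(config$n_env_lakes, nrow(lakes))
  if (n_env == 0) {
    return(data.frame(lake_id = character(), year = integer(), month = integer(),
                      variable = character(), measure_depth = numeric(),
                      value = numeric(), below_detection = logical(),
                      stringsAsFactors = FALSE))
  }
  temp_depths <- c(0, -2, -4, -6)
  temp_damp <- c(1, 0.85, 0.6, 0.4)  # seasonal amplitude damping with depth
  out <- vector("list", n_env * length(years))
  idx <- 0L
  for (li in seq_len(n_env)) {
    lake_mean <- pmax(0, stats::rnorm(nrow(ev), ev$mean, ev$sd))
    for (yi in seq_along(years)) {
      months <- 1:12
      season <- sin(2 * pi * (months - 4) / 12)
      parts <- vector("list", nrow(ev))
      for (vi in seq_len(nrow(ev))) {
        v <- ev$variable[vi]
        noise_sd <- config$env_noise_sd * ev$sd[vi]
        if (v == "Temp") {
          vals <- lapply(seq_along(temp_depths), function(di) {
            x <- lake_mean[vi] + ev$amplitude[vi] * temp_damp[di] * season +
              stats::rnorm(12, 0, noise_sd)
            data.frame(month = months, measure_depth = temp_depths[di],
                       value = pmax(0, x), below_detection = FALSE)
          })
          df <- do.call(rbind, vals)
        } else {
          x <- lake_mean[vi] + ev$amplitude[vi] * season + stats::rnorm(12, 0, noise_sd)
          if (v != "pH") x <- pmax(0, x)
          bd <- if (ev$detectable_zero[vi]) {
            stats::runif(12) < config$below_detection_prob
          } else rep(FALSE, 12)
          df <- data.frame(month = months, measure_depth = 0,
                           value = x, below_detection = bd)
        }
        df$variable <- v
        parts[[vi]] <- df
      }
      ydf <- do.call(rbind, parts)
      keep <- stats::runif(nrow(ydf)) >= config$missing_month_prob
      ydf <- ydf[keep, , drop = FALSE]
      ydf$lake_id <- lakes$lake_id[li]
      ydf$year <- years[yi]
      idx <- idx + 1L
      out[[idx]] <- ydf[, c("lake_id", "year", "month", "variable",
                            "measure_depth", "value", "below_detection")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a multi-year series with injected trends
#'
#' Wraps [generate_lake_system()] for the time-series tier: at least three
#' survey years are required, niche optima and/or the species pool drift
#' linearly per year by the configured amounts, and the truth records the
#' injected sign per measure.
#'
#' @param config a [simulation_config()] with >= 3 years.
#' @return as [generate_lake_system()], with `truth$trend_signs`: named vector
#'   over `D_alpha_max` (+ = peak shifting shallower) and `total_gamma`
#'   (+ = more species), values in {-1, 0, 1}.
#' @export
generate_temporal_series <- function(config) {
  stopifnot(inherits(config, "ddg_sim_config"))
  if (length(config$years) < 3) stop("time-series tier needs at least 3 years")
  sys <- generate_lake_system(config)
  sys$truth$trend_signs <- c(
    D_alpha_max = sign(config$optimum_drift_per_year),
    total_gamma = sign(config$pool_drift_per_year)
  )
  sys
}

#' Write a synthetic system to CSV files plus a truth JSON
#'
#' @param system output of [generate_lake_system()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lake_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surveys(system$surveys, file.path(dir, "surveys.csv"))
  write.csv(system$lakes, file.path(dir, "lakes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(system$waterlevel, file.path(dir, "waterlevel.csv"), row.names = FALSE, quote = FALSE)
  write.csv(system$monthly, file.path(dir, "monthly.csv"), row.names = FALSE, quote = FALSE)
  truth <- system$truth
  truth$expected_alpha <- as.data.frame(truth$expected_alpha)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
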