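#' @importFrom utils read.csv write.csv
NULL

.survey_cols <- c("lake_id", "year", "transect_id", "depth_class", "taxon",
                  "rank", "growth_form", "kohler_freq")

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
}

#' Read a macrophyte survey table
#'
#' Reads a long-format survey CSV: one row per taxon observation in one depth
#' class of one transect in one field campaign (a lake mapped in one year).
#' Depth labels are validated against the four canonical classes and Kohler
#' frequencies against the five-step scale.
#'
#' @param path path to a UTF-8 CSV with header and columns `lake_id`, `year`,
#'   `transect_id`, `depth_class`, `taxon`, `rank`, `growth_form`,
#'   `kohler_freq`.
#' @return A data.frame of survey records with an added numeric `depth`
#'   column (the signed class midpoint in m).
#' @seealso [write_surveys()], [filter_records()]
#' @export
read_surveys <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_cols(df, .survey_cols, "survey file")
  as_survey_records(df[, .survey_cols, drop = FALSE])
}

#' Validate a survey table held in memory
#'
#' Applies the same depth-label and Kohler-frequency validation as
#' [read_surveys()] to a data.frame, and attaches the `depth` midpoint column.
#'
#' @param df data.frame with the survey columns.
#' @return validated data.frame of survey records.
#' @export
as_survey_records <- function(df) {
  .check_cols(df, .survey_cols, "survey table")
  if (nrow(df) == 0) {
    df$depth <- numeric(0)
    return(df)
  }
  known <- df$depth_class %in% depth_classes()$label
  if (!all(known)) {
    row <- which(!known)[1]
    stop("row ", row, ": unknown depth class label '", df$depth_class[row], "'")
  }
  kf <- df$kohler_freq
  ok <- !is.na(kf) & kf == as.integer(kf) & kf >= 1 & kf <= 5
  if (!all(ok)) {
    row <- which(!ok)[1]
    stop("row ", row, ": kohler_freq '", kf[row], "' outside the 1-5 Kohler scale")
  }
  df$kohler_freq <- as.integer(kf)
  df$year <- as.integer(df$year)
  df$depth <- depth_midpoint(df$depth_class)
  rownames(df) <- NULL
  df
}

#' Write a survey table in canonical form
#'
#' @param records survey records (see [read_surveys()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(records, path) {
  .check_cols(records, .survey_cols, "survey table")
  write.csv(records[, .survey_cols, drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lake metadata
#'
#' @param path CSV with columns `lake_id`, `area` (ha), `max_depth` (m),
#'   `mixing_regime`, `natural`, `natural_water_level`.
#' @return data.frame of lake metadata.
#' @export
read_lakes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("lake_id", "area", "max_depth", "mixing_regime",
                    "natural", "natural_water_level"), "lake metadata")
  stopifnot(all(df$area > 0), all(df$max_depth > 0))
  df$natural <- as.logical(df$natural)
  df$natural_water_level <- as.logical(df$natural_water_level)
  df
}

#' Read water-level statistics
#'
#' @param path CSV with columns `lake_id`, `MHW`, `MLW` (m). A `WLF` column
#'   is recomputed as MHW - MLW.
#' @return data.frame with `lake_id`, `MHW`, `MLW`, `WLF`.
#' @export
read_waterlevel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("lake_id", "MHW", "MLW"), "water-level file")
  if (any(df$MHW < df$MLW)) stop("MHW < MLW for lake(s): ",
                                 paste(df$lake_id[df$MHW < df$MLW], collapse = ", "))
  df$WLF <- df$MHW - df$MLW
  df
}

#' Read monthly physiochemical samples
#'
#' @param path CSV with columns `lake_id`, `year`, `month`, `variable`,
#'   `measure_depth` (m; 0 for surface, 0/-2/-4/-6 for temperature),
#'   `value`, `below_detection` (logical).
#' @return data.frame of monthly samples.
#' @export
read_monthly <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, c("lake_id", "year", "month", "variable", "measure_depth",
                    "value", "below_detection"), "monthly samples")
  df$below_detection <- as.logical(df$below_detection)
  key <- paste(df$lake_id, df$year, df$month, df$variable, df$measure_depth)
  if (anyDuplicated(key)) stop("duplicate (lake, month, variable, depth) sample(s)")
  df
}

#' Apply the record and lake selection rules
#'
#' Restricts a survey archive to the study population and protocol:
#' lakes must be deep (max depth > 10 m), natural, dimictic, with a natural
#' water-level dynamic, and mapped in at least two distinct years anywhere in
#' the archive; campaigns (lake x year) with a single transect are dropped;
#' only submerged growth forms identified to species rank are kept.
#'
#' The repeat-mapping rule counts a lake's distinct survey years over the
#' campaigns that survive the other rules, so the filter is idempotent: a
#' second application removes nothing.
#'
#' @param records survey records (see [read_surveys()]).
#' @param meta lake metadata (see [read_lakes()]).
#' @param min_repeat_years minimum number of distinct survey years a lake must
#'   have (default 2, i.e. at least one repetition).
#' @return the filtered records, with an `exclusion_log` attribute: a named
#'   list counting record removals per rule (`lake_gate` = records in lakes
#'   failing the metadata gate, `growth_form` = emergent/floating-leaved
#'   records, `rank` = records above species rank, `single_transect` = records
#'   in one-transect campaigns, `repeat_rule` = records in lakes without
#'   enough repeat years) plus `campaigns_dropped`, the number of campaigns
#'   lost to the single-transect rule.
#' @export
filter_records <- function(records, meta, min_repeat_years = 2) {
  .check_cols(records, .survey_cols, "survey table")
  log <- list(lake_gate = 0L, growth_form = 0L, rank = 0L,
              single_transect = 0L, repeat_rule = 0L, campaigns_dropped = 0L)
  r <- records
  if (nrow(r)) {
    midx <- match(r$lake_id, meta$lake_id)
    if (anyNA(midx)) {
      stop("no metadata for lake(s): ",
           paste(unique(r$lake_id[is.na(midx)]), collapse = ", "))
    }
    m <- meta[midx, ]
    lake_ok <- m$max_depth > 10 & m$natural & m$mixing_regime == "dimictic" &
      m$natural_water_level
    log$lake_gate <- sum(!lake_ok)
    r <- r[lake_ok, , drop = FALSE]

    gf_ok <- r$growth_form == "submerged"
    log$growth_form <- sum(!gf_ok)
    r <- r[gf_ok, , drop = FALSE]

    rank_ok <- r$rank == "species"
    log$rank <- sum(!rank_ok)
    r <- r[rank_ok, , drop = FALSE]

    if (nrow(r)) {
      camp <- paste(r$lake_id, r$year)
      ntr <- tapply(r$transect_id, camp, function(x) length(unique(x)))
      multi <- names(ntr)[ntr >= 2]
      keep <- camp %in% multi
      log$single_transect <- sum(!keep)
      log$campaigns_dropped <- length(ntr) - length(multi)
      r <- r[keep, , drop = FALSE]
    }

    if (nrow(r)) {
      nyr <- tapply(r$year, r$lake_id, function(y) length(unique(y)))
      ok_lakes <- names(nyr)[nyr >= min_repeat_years]
      keep <- r$lake_id %in% ok_lakes
      log$repeat_rule <- sum(!keep)
      r <- r[keep, , drop = FALSE]
    }
  }
  rownames(r) <- NULL
  attr(r, "exclusion_log") <- log
  r
}

#' Exclusion log of a filtered survey table
#' @param records output of [filter_records()].
#' @return named list of removal counts per rule.
#' @export
exclusion_log <- function(records) attr(records, "exclusion_log")

#' Dataset tier membership
#'
#' Campaigns (lake x year) are organised in three nested tiers: the full
#' biodiversity dataset; the environment-and-biodiversity subset, for which
#' complete annual environmental records exist; and the time-series subset of
#' lakes mapped in at least `min_years` years.
#'
#' @param records filtered survey records.
#' @param env_records optional data.frame of complete environmental records
#'   with `lake_id` and `year` columns (see [env_records()]).
#' @param min_years minimum distinct survey years for the time-series tier.
#' @return list of data.frames (`biodiversity`, `environment_biodiversity`,
#'   `time_series`), each with `lake_id`, `year`.
#' @export
dataset_tiers <- function(records, env_records = NULL, min_years = 3) {
  camps <- unique(records[, c("lake_id", "year")])
  camps <- camps[order(camps$lake_id, camps$year), , drop = FALSE]
  rownames(camps) <- NULL
  env <- camps[0, ]
  if (!is.null(env_records) && nrow(env_records)) {
    key <- paste(camps$lake_id, camps$year) %in%
      paste(env_records$lake_id, env_records$year)
    env <- camps[key, , drop = FALSE]
  }
  nyr <- tapply(camps$year, camps$lake_id, function(y) length(unique(y)))
  ts_lakes <- names(nyr)[nyr >= min_years]
  ts <- camps[camps$lake_id %in% ts_lakes, , drop = FALSE]
  rownames(env) <- rownames(ts) <- NULL
  list(biodiversity = camps, environment_biodiversity = env, time_series = ts)
}
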