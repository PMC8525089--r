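#' Peak of a per-depth richness curve
#'
#' Returns the maximal richness and the depth at which it occurs. When several
#' depth classes tie for the maximum, the peak depth is the arithmetic mean of
#' the tied class midpoints, which places it between classes.
#'
#' @param counts numeric vector of richness values at the four depth
#'   midpoints, in the order of [depth_midpoints()].
#' @return list with `peak_depth` (m) and `peak_count`; both `NA` for an
#'   all-zero curve (no peak is defined).
#' @examples
#' transect_peak(c(2, 5, 4, 1))   # unique peak at -1.5 m
#' transect_peak(c(1, 5, 5, 0))   # tie: peak at -2.25 m
#' @export
transect_peak <- function(counts) {
  mids <- depth_midpoints()
  stopifnot(length(counts) == length(mids))
  if (all(counts == 0)) return(list(peak_depth = NA_real_, peak_count = NA_real_))
  mx <- max(counts)
  list(peak_depth = mean(mids[counts == mx]), peak_count = mx)
}

#' Alpha-richness peak measures of one campaign
#'
#' The per-transect peak (depth of maximal species number, with ties averaged)
#' is computed first; D_max and R_max are then the means of peak depth and
#' peak count across transects. Transects with no species at any depth have
#' no defined peak and are excluded from the averages; their number is
#' returned for logging.
#'
#' @param records survey records of a single campaign.
#' @return list with `D_max` (m), `R_max`, `pattern` (see
#'   [classify_pattern()]) and `n_empty_transects`.
#' @export
ddg_alpha_measures <- function(records) {
  m <- .count_matrix(records)
  peaks <- apply(m, 1, transect_peak)
  depths <- vapply(peaks, `[[`, numeric(1), "peak_depth")
  counts <- vapply(peaks, `[[`, numeric(1), "peak_count")
  ok <- !is.na(depths)
  if (!any(ok)) stop("no non-empty transect in campaign; alpha peak undefined")
  d <- mean(depths[ok])
  list(D_max = d, R_max = mean(counts[ok]), pattern = classify_pattern(d),
       n_empty_transects = sum(!ok))
}

#' Peak measures of a campaign-level richness profile
#'
#' Campaign-level argmax of a beta or gamma profile, with the same
#' tie-averaging rule as [transect_peak()].
#'
#' @param profile named numeric vector over the four depth midpoints (from
#'   [gamma_profile()] or [beta_profile()]).
#' @param component label stored in the result ("beta" or "gamma").
#' @return list with `component`, `D_max`, `R_max`, `pattern`.
#' @export
ddg_profile_measures <- function(profile, component = "gamma") {
  if (all(profile == 0)) stop("all-zero ", component, " profile; peak undefined")
  pk <- transect_peak(as.numeric(profile))
  list(component = component, D_max = pk$peak_depth, R_max = pk$peak_count,
       pattern = classify_pattern(pk$peak_depth))
}

#' Classify a DDG curve by the depth of its richness maximum
#'
#' Four pattern types partition the depth axis: decreasing curves peak above
#' -1 m, shallow hump-shaped between -1 and -2 m, deep hump-shaped between -2
#' and -4 m, and increasing curves peak below -4 m. Boundaries are assigned to
#' the deeper class (a tie-averaged D_max of exactly -1 m is a shallow hump,
#' -2 m a deep hump, -4 m increasing).
#'
#' @param D_max peak depth in m, within the class-midpoint hull [-5, -0.5].
#' @return character: one of "decreasing", "shallow_hump", "deep_hump",
#'   "increasing".
#' @export
classify_pattern <- function(D_max) {
  stopifnot(all(D_max >= -5.0 & D_max <= -0.5))
  out <- ifelse(D_max > -1, "decreasing",
         ifelse(D_max > -2, "shallow_hump",
         ifelse(D_max > -4, "deep_hump", "increasing")))
  out
}

#' Pattern types, in surface-to-depth order
#' @return character vector of the four pattern type names.
#' @export
pattern_types <- function() c("decreasing", "shallow_hump", "deep_hump", "increasing")

#' DDG peak measures for every campaign and richness component
#'
#' @param records filtered survey records spanning any number of campaigns.
#' @return data.frame with columns `lake_id`, `year`, `component`
#'   (alpha/beta/gamma), `D_max`, `R_max`, `pattern`. Campaigns whose beta
#'   profile is all zero (no turnover anywhere) contribute no beta row; a
#'   warning reports their number.
#' @export
ddg_measures <- function(records) {
  key <- .campaign_key(records)
  skipped_beta <- 0L
  parts <- lapply(split(records, key), function(cr) {
    a <- ddg_alpha_measures(cr)
    g <- gamma_profile(cr)
    b <- beta_profile(alpha_profile(cr), g)
    rows <- list(data.frame(lake_id = cr$lake_id[1], year = cr$year[1],
                            component = "alpha", D_max = a$D_max,
                            R_max = a$R_max, pattern = a$pattern,
                            stringsAsFactors = FALSE))
    if (any(b > 0)) {
      pb <- ddg_profile_measures(b, "beta")
      rows <- c(rows, list(data.frame(lake_id = cr$lake_id[1], year = cr$year[1],
                                      component = "beta", D_max = pb$D_max,
                                      R_max = pb$R_max, pattern = pb$pattern,
                                      stringsAsFactors = FALSE)))
    } else {
      skipped_beta <<- skipped_beta + 1L
    }
    pg <- ddg_profile_measures(g, "gamma")
    rows <- c(rows, list(data.frame(lake_id = cr$lake_id[1], year = cr$year[1],
                                    component = "gamma", D_max = pg$D_max,
                                    R_max = pg$R_max, pattern = pg$pattern,
                                    stringsAsFactors = FALSE)))
    do.call(rbind, rows)
  })
  if (skipped_beta > 0) {
    warning(skipped_beta, " campaign(s) had an all-zero beta profile; no beta row emitted")
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$lake_id, out$year, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pattern-type frequencies across campaigns
#'
#' @param measures output of [ddg_measures()].
#' @param component one of "alpha", "beta", "gamma".
#' @return named numeric vector of percentages (summing to 100) over the four
#'   pattern types.
#' @export
pattern_frequencies <- function(measures, component = "alpha") {
  sel <- measures$pattern[measures$component == component]
  if (!length(sel)) stop("no campaigns for component ", component)
  tab <- table(factor(sel, levels = pattern_types()))
  stats::setNames(100 * as.vector(tab) / sum(tab), pattern_types())
}
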