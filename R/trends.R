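#' Invariability coefficient of a measure over years
#'
#' IC = mean / sd, the inverse of the coefficient of variation; a high IC
#' means a stable measure. A constant series has undefined (infinite) IC and
#' is flagged rather than erroring.
#'
#' @param values measure values across years (>= 3).
#' @return list with `mean`, `sd`, `cv`, `ic`, `infinite_stability` (logical).
#' @export
invariability <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 yearly values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for the invariability coefficient")
  s <- stats::sd(values)
  if (s == 0) {
    return(list(mean = m, sd = 0, cv = 0, ic = Inf, infinite_stability = TRUE))
  }
  list(mean = m, sd = s, cv = s / m, ic = m / s, infinite_stability = FALSE)
}

#' Invariability coefficients per lake and measure
#'
#' @param measures data.frame with `lake_id`, `year` and one column per
#'   measure (wide campaign-level table, see [measure_table()]).
#' @param min_years minimum yearly values per lake (default 3).
#' @return data.frame with `lake_id`, `measure`, `mean`, `sd`, `ic`,
#'   `infinite_stability`; lakes with fewer than `min_years` years are
#'   skipped.
#' @export
invariability_table <- function(measures, min_years = 3) {
  meas_cols <- setdiff(names(measures), c("lake_id", "year"))
  rows <- list()
  for (lk in unique(measures$lake_id)) {
    sel <- measures[measures$lake_id == lk, , drop = FALSE]
    for (mc in meas_cols) {
      v <- sel[[mc]][!is.na(sel[[mc]])]
      if (length(v) < min_years || mean(v) <= 0) next
      iv <- invariability(v)
      rows[[length(rows) + 1]] <- data.frame(
        lake_id = lk, measure = mc, mean = iv$mean, sd = iv$sd, ic = iv$ic,
        infinite_stability = iv$infinite_stability, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.signif_class <- function(p) {
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*",
  ifelse(p < 0.1, ".", "ns"))))
}

#' Per-lake and pooled linear trends of DDG measures
#'
#' Ordinary least-squares regression of each measure on calendar year, per
#' lake and pooled over all lakes ("ALL"). For D_max measures a positive slope
#' means the richness peak becomes shallower (depths are negative, moving
#' toward 0); for R_max and gamma richness it means more species.
#'
#' @param measures wide campaign-level table with `lake_id`, `year` and one
#'   column per measure (see [measure_table()]).
#' @param min_years minimum distinct years per lake; lakes below it are
#'   skipped (logged via attribute `skipped_lakes`).
#' @return data.frame with `lake_id` (or "ALL"), `measure`, `slope`, `p`,
#'   `sign` ("+"/"-"), `class` ("***", "**", "*", ".", "ns").
#' @export
trend_table <- function(measures, min_years = 3) {
  meas_cols <- setdiff(names(measures), c("lake_id", "year"))
  skipped <- character(0)
  fit_one <- function(df, lk) {
    rows <- list()
    for (mc in meas_cols) {
      sel <- df[!is.na(df[[mc]]), c("year", mc)]
      if (length(unique(sel$year)) < min_years) next
      fit <- stats::lm(stats::reformulate("year", mc), data = sel)
      # noiseless series fit perfectly; the summary warning is expected
      cf <- suppressWarnings(summary(fit))$coefficients
      slope <- cf["year", "Estimate"]
      p <- cf["year", "Pr(>|t|)"]
      if (is.nan(p)) p <- 1  # perfectly flat series
      rows[[length(rows) + 1]] <- data.frame(
        lake_id = lk, measure = mc, slope = slope, p = p,
        sign = ifelse(slope >= 0, "+", "-"), class = .signif_class(p),
        stringsAsFactors = FALSE)
    }
    rows
  }
  out <- list()
  for (lk in unique(measures$lake_id)) {
    sel <- measures[measures$lake_id == lk, , drop = FALSE]
    if (length(unique(sel$year)) < min_years) {
      skipped <- c(skipped, lk)
      next
    }
    out <- c(out, fit_one(sel, lk))
  }
  out <- c(out, fit_one(measures, "ALL"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped_lakes") <- skipped
  res
}

#' Wide campaign-level measure table
#'
#' Reshapes [ddg_measures()] output plus per-campaign total gamma richness
#' into one row per campaign with columns `total_gamma`, `D_alpha_max`,
#' `R_alpha_max`, `D_beta_max`, `R_beta_max`, `D_gamma_max`, `R_gamma_max` --
#' the measure set of the temporal analysis.
#'
#' @param measures output of [ddg_measures()].
#' @param profiles output of [richness_profiles()] (for `total_gamma`).
#' @return wide data.frame keyed by `lake_id`, `year`.
#' @export
measure_table <- function(measures, profiles) {
  camp <- unique(profiles[, c("lake_id", "year", "total_gamma")])
  for (comp in c("alpha", "beta", "gamma")) {
    sel <- measures[measures$component == comp, c("lake_id", "year", "D_max", "R_max")]
    names(sel)[3:4] <- paste0(c("D_", "R_"), comp, "_max")
    camp <- merge(camp, sel, by = c("lake_id", "year"), all.x = TRUE)
  }
  camp <- camp[order(camp$lake_id, camp$year), , drop = FALSE]
  rownames(camp) <- NULL
  camp
}

#' Format a trend table in the lakes x measures layout
#'
#' @param trends output of [trend_table()].
#' @return data.frame, one row per lake (pooled "ALL" last), one column per
#'   measure; cells like "+*" or "-ns" combine slope sign and significance.
#' @export
format_trend_table <- function(trends) {
  trends$cell <- paste0(trends$sign, ifelse(trends$class == "ns", "", trends$class))
  wide <- stats::reshape(trends[, c("lake_id", "measure", "cell")],
                         idvar = "lake_id", timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  ord <- order(wide$lake_id == "ALL", wide$lake_id)
  wide <- wide[ord, , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
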