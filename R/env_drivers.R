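#' Annual means of the physiochemical variables for one campaign
#'
#' Means of the monthly surface measurements per variable, with values flagged
#' below detection set to zero. A variable needs at least `min_months` monthly
#' values, otherwise it is reported missing (`NA`). Temperature enters both as
#' the surface annual mean (`Temp`) and as the stratification proxy `Tempsd`
#' (see [tempsd()]).
#'
#' @param monthly monthly samples (see [read_monthly()]).
#' @param lake,year campaign selector.
#' @param min_months minimum monthly values per variable (default 8).
#' @return named numeric vector over the 12 variables plus `Tempsd`; `NA`
#'   marks a variable without enough data.
#' @export
annual_means <- function(monthly, lake, year, min_months = 8) {
  vars <- .env_variables()$variable
  sel <- monthly[monthly$lake_id == lake & monthly$year == year, , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    s <- sel[sel$variable == v & sel$measure_depth == 0, , drop = FALSE]
    if (nrow(s) >= min_months) {
      vals <- ifelse(s$below_detection, 0, s$value)
      out[v] <- mean(vals)
    }
  }
  c(out, Tempsd = tempsd(monthly, lake, year, min_months = min_months))
}

#' Temperature stratification proxy for one campaign
#'
#' Standard deviation of the water temperature across the 0, -2, -4 and -6 m
#' measurement depths, computed per month and averaged over the months of the
#' year in which all four depths were measured.
#'
#' @inheritParams annual_means
#' @return mean monthly sd in degrees C, or `NA` if fewer than `min_months`
#'   months have all four depths.
#' @export
tempsd <- function(monthly, lake, year, min_months = 8) {
  depths <- c(0, -2, -4, -6)
  s <- monthly[monthly$lake_id == lake & monthly$year == year &
                 monthly$variable == "Temp", , drop = FALSE]
  sds <- vapply(sort(unique(s$month)), function(m) {
    sm <- s[s$month == m, , drop = FALSE]
    if (all(depths %in% sm$measure_depth)) {
      stats::sd(sm$value[match(depths, sm$measure_depth)])
    } else NA_real_
  }, numeric(1))
  sds <- sds[!is.na(sds)]
  if (length(sds) < min_months) return(NA_real_)
  mean(sds)
}

#' Water-level fluctuation
#'
#' WLF = MHW - MLW. Given a gauge series (data.frame with `year` and `level`),
#' MHW and MLW are the means of the annual maxima and minima.
#'
#' @param x either a list/data.frame row with `MHW` and `MLW`, or a gauge
#'   series data.frame with columns `year` and `level`.
#' @return WLF in m.
#' @export
wlf <- function(x) {
  if (is.data.frame(x) && all(c("year", "level") %in% names(x))) {
    mhw <- mean(tapply(x$level, x$year, max))
    mlw <- mean(tapply(x$level, x$year, min))
  } else {
    mhw <- x$MHW; mlw <- x$MLW
  }
  if (any(mhw < mlw)) stop("corrupt input: MHW < MLW")
  mhw - mlw
}

#' Assemble complete environmental records per campaign
#'
#' Joins the annual means, the stratification proxy, lake area and WLF for
#' every campaign in `campaigns`; only campaigns with every variable present
#' qualify for the environment-and-biodiversity tier.
#'
#' @param campaigns data.frame with `lake_id`, `year` (e.g. a tier table).
#' @param monthly monthly samples.
#' @param meta lake metadata.
#' @param waterlevel water-level statistics with `lake_id`, `WLF`.
#' @param complete_only drop campaigns with any missing variable (default).
#' @return data.frame with `lake_id`, `year`, the 12 variables, `Tempsd`,
#'   `Area`, `WLF`.
#' @export
env_records <- function(campaigns, monthly, meta, waterlevel,
                        complete_only = TRUE) {
  rows <- lapply(seq_len(nrow(campaigns)), function(i) {
    lk <- campaigns$lake_id[i]; yr <- campaigns$year[i]
    am <- annual_means(monthly, lk, yr)
    area <- meta$area[match(lk, meta$lake_id)]
    w <- waterlevel$WLF[match(lk, waterlevel$lake_id)]
    cbind(data.frame(lake_id = lk, year = yr, stringsAsFactors = FALSE),
          as.data.frame(as.list(am)), Area = area, WLF = w)
  })
  out <- do.call(rbind, rows)
  if (complete_only) {
    out <- out[stats::complete.cases(out), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Log-transform a table of environmental or biotic variables
#'
#' Natural log of (x + c) per column. For columns containing zeros, c is half
#' the smallest positive observed value of that column; otherwise c = 0. pH is
#' exempt (already a logarithmic quantity), as is any column named in
#' `exempt`.
#'
#' @param tab numeric data.frame.
#' @param exempt column names left untransformed (default "pH").
#' @return transformed data.frame.
#' @export
log_transform <- function(tab, exempt = "pH") {
  tab <- as.data.frame(tab)
  for (nm in names(tab)) {
    if (nm %in% exempt || !is.numeric(tab[[nm]])) next
    x <- tab[[nm]]
    if (any(x < 0, na.rm = TRUE)) stop("negative values in column ", nm)
    cc <- 0
    if (any(x == 0, na.rm = TRUE)) {
      pos <- x[x > 0 & !is.na(x)]
      if (!length(pos)) stop("column ", nm, " is all zero; cannot log-transform")
      cc <- min(pos) / 2
    }
    tab[[nm]] <- log(x + cc)
  }
  tab
}

#' PCA reduction of the environmental drivers
#'
#' Principal component analysis of the standardized, log-transformed
#' variables. The minimal prefix of axes whose cumulative explained variance
#' exceeds `cum_var` is retained; each axis is named by every variable whose
#' squared correlation with the axis exceeds `naming_share` (i.e. the axis
#' carries more than that share of the variable's variance). Axes are oriented
#' so their largest-magnitude loading is positive.
#'
#' @param records environmental records (see [env_records()]); `lake_id` and
#'   `year` columns are carried through to the scores.
#' @param cum_var cumulative-variance threshold for axis retention.
#' @param naming_share squared-correlation threshold for axis naming.
#' @param log whether to log-transform first (default TRUE).
#' @return object of class `ddg_pca`: list with `loadings`, `explained`
#'   (variance fractions), `retained`, `axis_names`, `scores` (data.frame with
#'   `lake_id`, `year`, PC columns), `center`, `scale`.
#' @export
pca_drivers <- function(records, cum_var = 0.80, naming_share = 0.40, log = TRUE) {
  keys <- records[, intersect(c("lake_id", "year"), names(records)), drop = FALSE]
  num <- records[, setdiff(names(records), c("lake_id", "year")), drop = FALSE]
  if (nrow(num) < 5) stop("need at least 5 complete records for a PCA")
  if (log) num <- log_transform(num)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(names(num)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  # orient each axis so its largest-magnitude loading is positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  retained <- which(cumsum(expl) > cum_var)[1]
  cors <- sweep(pc$rotation, 2, pc$sdev, "*")  # cor(variable, axis), scaled PCA
  axis_names <- lapply(seq_len(retained), function(k) {
    rownames(cors)[cors[, k]^2 > naming_share]
  })
  names(axis_names) <- colnames(pc$rotation)[seq_len(retained)]
  scores <- cbind(keys, as.data.frame(pc$x))
  structure(list(loadings = pc$rotation, explained = expl, retained = retained,
                 axis_names = axis_names, scores = scores,
                 center = pc$center, scale = pc$scale),
            class = "ddg_pca")
}

#' @export
print.ddg_pca <- function(x, ...) {
  cat("PCA of environmental drivers:", length(x$explained), "axes,",
      x$retained, "retained (cumulative variance",
      sprintf("%.1f%%)\n", 100 * sum(x$explained[seq_len(x$retained)])))
  for (k in seq_len(x$retained)) {
    cat(sprintf("  PC%d (%.1f%%): %s\n", k, 100 * x$explained[k],
                paste(x$axis_names[[k]], collapse = " & ")))
  }
  invisible(x)
}

# deviance explained by the fixed smooths, measured against the
# random-intercept-only baseline so that a single-term model's drop
# contribution equals its total explained deviance
.gamm_dev_expl <- function(dev_model, dev_baseline) {
  if (dev_baseline <= 0) return(0)
  max(0, 1 - dev_model / dev_baseline)
}

.gamm_formula <- function(response, terms, k, smooth) {
  rhs <- if (length(terms)) {
    if (smooth) paste(sprintf("s(%s, k = %d)", terms, k), collapse = " + ")
    else paste(terms, collapse = " + ")
  } else "1"
  stats::as.formula(paste(response, "~", rhs, "+ s(lake, bs = 're')"))
}

#' Additive mixed model for a DDG measure with backward selection
#'
#' Fits a generalized additive mixed model: one penalized-spline smooth per
#' candidate predictor (PCA axis scores) and a lake-level random intercept,
#' by REML. The least significant smooth is removed and the model refitted
#' until every remaining smooth is significant at `threshold` (the minimal
#' model; it may be empty). Reported per retained term is the drop
#' contribution: the decrease in deviance explained (relative to the
#' random-intercept-only baseline) when that term is removed from the
#' retained model.
#'
#' @param data data.frame with the response, predictor columns and a lake id.
#' @param response name of the response column (a DDG measure).
#' @param predictors character vector of candidate predictor columns.
#' @param lake name of the lake id column (random intercept).
#' @param threshold stepwise stopping p-value (default 0.05).
#' @param k spline basis dimension per smooth.
#' @param smooth fit penalized-spline smooths (default); `FALSE` uses linear
#'   terms, reducing the model to a linear mixed model.
#' @return list of class `ddg_gamm`: `response`, `retained` (term names),
#'   `p_values`, `edf`, `adj_r_squared`, `dev_explained` (of the retained
#'   model vs the random-intercept baseline), `drop_contribution` (named, %),
#'   `lake_variance`, `model` (the final mgcv fit), `eliminated` (in drop
#'   order).
#' @export
fit_gamm <- function(data, response, predictors, lake = "lake_id",
                     threshold = 0.05, k = 5, smooth = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  df <- data
  df$lake <- factor(df[[lake]])
  if (nrow(df) < 10 || nlevels(df$lake) < 3) {
    stop("need at least 10 campaigns across at least 3 lakes")
  }
  terms <- predictors
  eliminated <- character(0)
  fit_with <- function(tt) {
    mgcv::gam(.gamm_formula(response, tt, k, smooth), data = df, method = "REML")
  }
  term_p <- function(fit, tt) {
    if (!length(tt)) return(numeric(0))
    sm <- summary(fit)
    if (smooth) {
      st <- sm$s.table
      idx <- match(sprintf("s(%s)", tt), rownames(st))
      stats::setNames(st[idx, "p-value"], tt)
    } else {
      pt <- sm$p.table
      stats::setNames(pt[match(tt, rownames(pt)), "Pr(>|t|)"], tt)
    }
  }
  fit <- fit_with(terms)
  repeat {
    ps <- term_p(fit, terms)
    if (!length(ps) || all(ps < threshold)) break
    worst <- names(ps)[which.max(ps)]
    eliminated <- c(eliminated, worst)
    terms <- setdiff(terms, worst)
    fit <- fit_with(terms)
  }
  baseline <- fit_with(character(0))
  dev_base <- stats::deviance(baseline)
  dev_full <- stats::deviance(fit)
  dev_expl <- .gamm_dev_expl(dev_full, dev_base)
  drop <- stats::setNames(numeric(length(terms)), terms)
  for (tt in terms) {
    reduced <- fit_with(setdiff(terms, tt))
    drop[tt] <- 100 * (dev_expl - .gamm_dev_expl(stats::deviance(reduced), dev_base))
  }
  sm <- summary(fit)
  edf <- if (smooth && length(terms)) {
    st <- sm$s.table
    stats::setNames(st[match(sprintf("s(%s)", terms), rownames(st)), "edf"], terms)
  } else stats::setNames(rep(1, length(terms)), terms)
  re_var <- tryCatch({
    invisible(utils::capture.output(
      vc <- suppressWarnings(mgcv::gam.vcomp(fit, rescale = TRUE))))
    if (is.matrix(vc)) unname(vc["s(lake)", "std.dev"]^2)
    else unname(vc["s(lake)"]^2)
  }, error = function(e) NA_real_)
  structure(list(response = response, retained = terms,
                 p_values = term_p(fit, terms), edf = edf,
                 adj_r_squared = sm$r.sq,
                 dev_explained = dev_expl,
                 drop_contribution = pmax(drop, 0),
                 lake_variance = re_var,
                 model = fit, eliminated = eliminated),
            class = "ddg_gamm")
}

#' @export
print.ddg_gamm <- function(x, ...) {
  cat("GAMM for", x$response, "- retained term(s):",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  adj. R^2 = %.3f, deviance explained = %.1f%%\n",
              x$adj_r_squared, 100 * x$dev_explained))
  for (tt in x$retained) {
    cat(sprintf("  %s: edf = %.2f, p = %.3g, drop contribution = %.1f%%\n",
                tt, x$edf[tt], x$p_values[tt], x$drop_contribution[tt]))
  }
  invisible(x)
}

#' PERMANOVA representativeness check of a campaign subset
#'
#' Tests whether the diversity metrics of a subset of campaigns differ from
#' the remaining campaigns in centroid or dispersion, via PERMANOVA on
#' Euclidean distances of the standardized metrics. A nonsignificant result
#' (p > .05) supports treating the subset as representative.
#'
#' @param subset,full data.frames of campaign metrics sharing `lake_id` and
#'   `year` key columns plus numeric metric columns; `subset`'s campaigns must
#'   occur in `full`.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `pseudo_F`, `p`, `n_subset`, `n_rest`, `representative`
#'   (logical, p > .05).
#' @export
representativeness_check <- function(subset, full, n_perm = 999, seed = 1) {
  keys_full <- paste(full$lake_id, full$year)
  keys_sub <- paste(subset$lake_id, subset$year)
  if (!all(keys_sub %in% keys_full)) stop("subset contains campaigns absent from full")
  grp <- factor(ifelse(keys_full %in% keys_sub, "subset", "rest"))
  if (any(table(grp) < 2)) stop("each group needs at least 2 campaigns")
  metrics <- full[, setdiff(names(full), c("lake_id", "year")), drop = FALSE]
  metrics <- metrics[, vapply(metrics, is.numeric, logical(1)), drop = FALSE]
  z <- scale(as.matrix(metrics))
  z[is.nan(z)] <- 0  # constant metric carries no information
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d <- stats::dist(z)
  res <- vegan::adonis2(d ~ grp, permutations = n_perm)
  list(pseudo_F = res$F[1], p = res$`Pr(>F)`[1],
       n_subset = sum(grp == "subset"), n_rest = sum(grp == "rest"),
       representative = res$`Pr(>F)`[1] > 0.05)
}
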