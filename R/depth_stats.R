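#' Heteroscedasticity-robust simultaneous depth comparisons
#'
#' Compares a richness value across depth classes with all pairwise (Tukey)
#' contrasts, robust to non-normality, heteroscedasticity and unequal group
#' sizes. A cell-means linear model is fitted, its coefficient covariance is
#' estimated with the HC3 sandwich, and single-step adjusted p-values are
#' taken from the joint distribution of the maximum absolute t statistic,
#' approximated by seeded Monte-Carlo sampling of the multivariate normal with
#' the contrasts' correlation matrix.
#'
#' @param depth factor-like vector of depth classes (any labels).
#' @param value numeric richness values, same length as `depth`.
#' @param n_mc number of Monte-Carlo draws for the max-|t| distribution.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return data.frame with one row per contrast: `contrast`, `estimate`,
#'   `se` (HC3), `t`, `p` (unadjusted two-sided normal), `p_adj` (single-step
#'   max-t adjusted; always >= `p`).
#' @export
robust_depth_comparisons <- function(depth, value, n_mc = 100000, seed = 1) {
  depth <- factor(depth)
  stopifnot(length(depth) == length(value))
  counts <- table(depth)
  if (length(counts) < 2) stop("need at least two depth classes")
  if (any(counts < 2)) {
    stop("depth class(es) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  fit <- stats::lm(value ~ 0 + depth)
  # a saturated-fit warning from the sandwich bread is expected for
  # degenerate (constant) inputs
  V <- suppressWarnings(sandwich::vcovHC(fit, type = "HC3"))
  mu <- stats::coef(fit)
  lev <- levels(depth)
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  C <- matrix(0, ncol(pairs), k)
  lab <- character(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    C[i, b] <- 1; C[i, a] <- -1
    lab[i] <- paste(lev[b], "-", lev[a])
  }
  est <- as.vector(C %*% mu)
  est[abs(est) < 1e-10 * max(1, max(abs(mu)))] <- 0  # zap float dust in group means
  CV <- C %*% V %*% t(C)
  se <- sqrt(pmax(diag(CV), 0))
  se[se < 1e-12 * max(1, max(abs(mu)))] <- 0
  tstat <- ifelse(se > 0, est / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(tstat)), as.numeric(est != 0))
  p[se == 0 & est == 0] <- 1

  m <- length(est)
  if (m == 1 || all(se == 0)) {
    p_adj <- p
  } else {
    d <- sqrt(diag(CV))
    d[d == 0] <- 1
    R <- CV / tcrossprod(d)
    diag(R) <- 1
    # nearest-PD guard for numerically rank-deficient contrast sets
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    Z <- matrix(stats::rnorm(n_mc * nrow(R)), n_mc, nrow(R)) %*% t(L)
    maxabs <- apply(abs(Z), 1, max)
    p_mc <- vapply(abs(tstat), function(ti) mean(maxabs >= ti), numeric(1))
    p_adj <- pmax(p_mc, p)
  }
  data.frame(contrast = lab, estimate = est, se = se, t = tstat,
             p = p, p_adj = pmin(p_adj, 1), stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations among richness components or DDG measures
#'
#' @param tab data.frame or matrix of paired numeric observations (columns =
#'   components or measures, rows = campaigns or campaign x depth cells).
#' @return list with matrices `r` (Pearson correlation) and `p` (two-sided
#'   t-test p-values); entries involving a zero-variance column are `NA` and
#'   flagged with a warning.
#' @export
component_correlations <- function(tab) {
  tab <- as.data.frame(tab)
  nm <- names(tab)
  k <- length(nm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  diag(p) <- 0
  flagged <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- tab[[i]]; y <- tab[[j]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) stop("need at least 3 paired observations for ",
                            nm[i], " vs ", nm[j])
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        flagged <- c(flagged, paste(nm[i], nm[j], sep = ":"))
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(flagged)) {
    warning("zero variance; correlation undefined for: ",
            paste(flagged, collapse = ", "))
  }
  list(r = r, p = p)
}

#' Association between pattern types and richness components
#'
#' Classical Pearson chi-square test (no continuity correction) on the
#' component x pattern-type contingency table.
#'
#' @param tab nonnegative integer matrix or table, components in rows and
#'   pattern types in columns.
#' @return list with `statistic`, `df`, `p`.
#' @export
pattern_component_association <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table: a row or column margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}
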