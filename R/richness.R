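.campaign_key <- function(records) paste(records$lake_id, records$year, sep = "\r")

.one_campaign <- function(records) {
  k <- unique(.campaign_key(records))
  if (length(k) == 0) stop("campaign has no records")
  if (length(k) > 1) stop("records span more than one campaign (lake x year)")
  invisible(k)
}

# distinct-species count per transect x depth midpoint, including zeros for
# every (transect, depth) cell of the campaign
.count_matrix <- function(records) {
  .one_campaign(records)
  mids <- depth_midpoints()
  transects <- sort(unique(records$transect_id))
  m <- matrix(0, nrow = length(transects), ncol = length(mids),
              dimnames = list(transects, format(mids)))
  for (i in seq_along(transects)) {
    for (j in seq_along(mids)) {
      sel <- records$transect_id == transects[i] & records$depth == mids[j]
      m[i, j] <- length(unique(records$taxon[sel]))
    }
  }
  m
}

#' Alpha richness profile of one field campaign
#'
#' Mean over transects, at each of the four depth midpoints, of the number of
#' distinct species recorded in that transect and depth class. Every transect
#' contributes a count (possibly zero) at all four depths, so the mean is
#' always over the same number of transects.
#'
#' @param records survey records of a single campaign (one lake, one year).
#' @return named numeric vector over the four depth midpoints.
#' @export
alpha_profile <- function(records) {
  colMeans(.count_matrix(records))
}

#' Gamma richness profile of one field campaign
#'
#' Number of distinct species in the union of all transects, per depth class.
#'
#' @inheritParams alpha_profile
#' @return named integer vector over the four depth midpoints.
#' @export
gamma_profile <- function(records) {
  .one_campaign(records)
  mids <- depth_midpoints()
  out <- vapply(mids, function(d) {
    length(unique(records$taxon[records$depth == d]))
  }, integer(1))
  names(out) <- format(mids)
  out
}

#' Additive beta richness profile
#'
#' Beta richness is partitioned additively: gamma minus alpha, per depth.
#'
#' @param alpha,gamma profiles from [alpha_profile()] and [gamma_profile()]
#'   for the same campaign.
#' @return named numeric vector; never negative.
#' @export
beta_profile <- function(alpha, gamma) {
  if (!identical(names(alpha), names(gamma))) {
    stop("alpha and gamma profiles do not share depth classes (mismatched campaigns?)")
  }
  gamma - alpha
}

#' Depth-independent gamma richness of one campaign
#'
#' @inheritParams alpha_profile
#' @return integer count of distinct species across all transects and depths.
#' @export
total_gamma <- function(records) {
  if (nrow(records) == 0) {
    warning("campaign is empty after filtering; total gamma is 0")
    return(0L)
  }
  .one_campaign(records)
  length(unique(records$taxon))
}

#' Richness profiles for every campaign in a survey table
#'
#' @param records filtered survey records spanning any number of campaigns.
#' @return data.frame with one row per campaign x depth midpoint and columns
#'   `lake_id`, `year`, `depth`, `alpha`, `beta`, `gamma`, plus campaign-level
#'   `total_gamma` and `n_transects` repeated on each row.
#' @export
richness_profiles <- function(records) {
  key <- .campaign_key(records)
  parts <- lapply(split(records, key), function(cr) {
    a <- alpha_profile(cr)
    g <- gamma_profile(cr)
    data.frame(
      lake_id = cr$lake_id[1], year = cr$year[1],
      depth = depth_midpoints(),
      alpha = as.vector(a), beta = as.vector(g - a), gamma = as.vector(g),
      total_gamma = length(unique(cr$taxon)),
      n_transects = length(unique(cr$transect_id)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$lake_id, out$year, -out$depth), , drop = FALSE]
  rownames(out) <- NULL
  out
}
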