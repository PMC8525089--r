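# Builders and independent oracles shared across the suite.

# quick survey-record builder: one row per taxon observation
make_records <- function(lake = "L1", year = 2010, transect, depth_class, taxon,
                         rank = "species", growth_form = "submerged",
                         kohler = 3L) {
  n <- max(length(transect), length(depth_class), length(taxon))
  if (n == 0) {
    return(as_survey_records(data.frame(
      lake_id = character(0), year = integer(0), transect_id = character(0),
      depth_class = character(0), taxon = character(0), rank = character(0),
      growth_form = character(0), kohler_freq = integer(0),
      stringsAsFactors = FALSE)))
  }
  as_survey_records(data.frame(
    lake_id = lake, year = year, transect_id = transect,
    depth_class = depth_class, taxon = taxon, rank = rank,
    growth_form = growth_form, kohler_freq = kohler,
    stringsAsFactors = FALSE
  ))
}

default_meta <- function(lake_ids) {
  data.frame(lake_id = lake_ids, area = 500, max_depth = 40,
             mixing_regime = "dimictic", natural = TRUE,
             natural_water_level = TRUE, stringsAsFactors = FALSE)
}

# Brute-force richness oracle: set enumeration over raw rows, written
# independently of the package's profile code (no count matrix, no tapply).
brute_force_profiles <- function(records) {
  mids <- c(-0.5, -1.5, -3.0, -5.0)
  labels <- c("0-1", "1-2", "2-4", ">4")
  transects <- unique(records$transect_id)
  alpha <- gamma <- numeric(4)
  for (j in 1:4) {
    per_transect <- numeric(length(transects))
    union_set <- character(0)
    for (i in seq_along(transects)) {
      sp <- character(0)
      for (r in seq_len(nrow(records))) {
        if (records$transect_id[r] == transects[i] &&
            records$depth_class[r] == labels[j] &&
            !(records$taxon[r] %in% sp)) {
          sp <- c(sp, records$taxon[r])
        }
      }
      per_transect[i] <- length(sp)
      union_set <- union(union_set, sp)
    }
    alpha[j] <- sum(per_transect) / length(transects)
    gamma[j] <- length(union_set)
  }
  all_sp <- character(0)
  for (r in seq_len(nrow(records))) all_sp <- union(all_sp, records$taxon[r])
  list(alpha = alpha, gamma = gamma, beta = gamma - alpha,
       total_gamma = length(all_sp))
}

# random toy campaign: <= 4 transects, <= 6 species, random sparse occupancy
random_toy_campaign <- function() {
  nt <- sample(2:4, 1)
  ns <- sample(1:6, 1)
  rows <- expand.grid(transect = paste0("T", seq_len(nt)),
                      depth_class = c("0-1", "1-2", "2-4", ">4"),
                      taxon = paste0("sp", seq_len(ns)),
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.35, , drop = FALSE]
  if (nrow(rows) == 0) rows <- data.frame(transect = "T1", depth_class = "0-1",
                                          taxon = "sp1", stringsAsFactors = FALSE)
  make_records(transect = rows$transect, depth_class = rows$depth_class,
               taxon = rows$taxon)
}
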