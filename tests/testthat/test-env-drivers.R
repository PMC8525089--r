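monthly_fixture <- function(lake = "L1", year = 2015, variable = "P_tot",
                            months = 1:12, values = 2, below = FALSE,
                            depth = 0) {
  data.frame(lake_id = lake, year = year, month = months, variable = variable,
             measure_depth = depth, value = values, below_detection = below,
             stringsAsFactors = FALSE)
}

test_that("annual means respect the eight-month rule and detection limits", {
  m7 <- monthly_fixture(months = 1:7)
  expect_true(is.na(annual_means(m7, "L1", 2015)["P_tot"]))
  m12 <- monthly_fixture(values = 1.3, below = TRUE)
  expect_equal(unname(annual_means(m12, "L1", 2015)["P_tot"]), 0)
  m8 <- monthly_fixture(months = 1:8, values = 2.0)
  expect_equal(unname(annual_means(m8, "L1", 2015)["P_tot"]), 2.0)
  # order of months is irrelevant
  m_shuf <- m8[sample(8), ]
  expect_equal(annual_means(m_shuf, "L1", 2015), annual_means(m8, "L1", 2015))
  # an extra below-detection month can only pull the mean down
  m9 <- rbind(m8, monthly_fixture(months = 9, values = 5, below = TRUE))
  expect_lte(unname(annual_means(m9, "L1", 2015)["P_tot"]),
             unname(annual_means(m8, "L1", 2015)["P_tot"]))
})

test_that("the stratification proxy averages monthly depth sds", {
  temps <- do.call(rbind, lapply(1:8, function(mo)
    monthly_fixture(variable = "Temp", months = mo,
                    values = c(20, 18, 12, 10), depth = c(0, -2, -4, -6))))
  expect_equal(tempsd(temps, "L1", 2015), sd(c(20, 18, 12, 10)))
  expect_equal(round(tempsd(temps, "L1", 2015), 2), 4.76)
  flat <- do.call(rbind, lapply(1:8, function(mo)
    monthly_fixture(variable = "Temp", months = mo, values = 15,
                    depth = c(0, -2, -4, -6))))
  expect_equal(tempsd(flat, "L1", 2015), 0)
  # a missing depth series leaves the proxy undefined
  expect_true(is.na(tempsd(temps[temps$measure_depth != -6, ], "L1", 2015)))
  # stronger summer stratification raises the annual value
  summer <- temps
  summer$value[summer$month %in% 6:8 & summer$measure_depth == 0] <- 26
  expect_gt(tempsd(summer, "L1", 2015), tempsd(temps, "L1", 2015))
})

test_that("water-level fluctuation follows MHW - MLW, also from gauge series", {
  expect_equal(wlf(list(MHW = 2.0, MLW = 1.5)), 0.5)
  expect_equal(wlf(list(MHW = 1.0, MLW = 1.0)), 0)
  gauge <- data.frame(year = rep(2001:2003, each = 2),
                      level = c(2, 1, 3, 1, 4, 1))
  expect_equal(wlf(gauge), 2)
  expect_error(wlf(list(MHW = 1, MLW = 2)), "corrupt")
})

test_that("log transform offsets zero-containing columns and exempts pH", {
  tab <- data.frame(x = c(1, 1), z = c(0, 2), pH = c(8.1, 8.3))
  out <- log_transform(tab)
  expect_equal(out$x, c(0, 0))
  expect_equal(out$z, c(log(1), log(3)))  # offset c = 1 = half of min positive
  expect_equal(out$pH, tab$pH)
  expect_error(log_transform(data.frame(x = c(-1, 2))), "negative")
})

test_that("PCA splits variance evenly over independent variables and pools collinear ones", {
  set.seed(2)
  rec <- data.frame(lake_id = "L", year = 1:400,
                    v1 = exp(rnorm(400)), v2 = exp(rnorm(400)))
  pca <- pca_drivers(rec)
  expect_equal(sum(pca$explained), 1)
  expect_true(all(abs(pca$explained - 0.5) < 0.1))
  expect_equal(pca$retained, 2)

  # a block of collinear variables names its axis; an independent variable
  # names its own
  dup <- data.frame(lake_id = "L", year = 1:100, a = exp(rnorm(100)))
  dup$b <- dup$a
  dup$c <- exp(rnorm(100))
  pca2 <- pca_drivers(dup)
  expect_setequal(pca2$axis_names$PC1, c("a", "b"))
  expect_equal(pca2$axis_names$PC2, "c")
  # orientation convention: dominant loading of each axis is positive
  expect_true(all(apply(pca2$loadings, 2, function(v) v[which.max(abs(v))]) > 0))

  expect_error(pca_drivers(data.frame(lake_id = "L", year = 1:30,
                                      k = rep(2, 30), x = rnorm(30) + 5)),
               "constant")
  expect_error(pca_drivers(rec[1:4, ]), "at least 5")
})

test_that("PCA loadings reconstruct the standardized table", {
  set.seed(4)
  rec <- data.frame(lake_id = "L", year = 1:60,
                    a = exp(rnorm(60)), b = exp(rnorm(60)), c = exp(rnorm(60)))
  pca <- pca_drivers(rec)
  z <- scale(log_transform(rec[, c("a", "b", "c")]))
  recon <- as.matrix(pca$scores[, c("PC1", "PC2", "PC3")]) %*% t(pca$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
  # explained fractions are non-increasing and in (0, 1]
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_true(all(pca$explained > 0 & pca$explained <= 1))
})

gamm_fixture <- function(seed, f = function(x) 0, noise = 1, n_lakes = 12,
                         n_years = 5, lake_sd = 1) {
  set.seed(seed)
  lakes <- sprintf("L%02d", seq_len(n_lakes))
  d <- expand.grid(lake_id = lakes, year = seq_len(n_years),
                   stringsAsFactors = FALSE)
  d$PC1 <- rnorm(nrow(d)); d$PC2 <- rnorm(nrow(d)); d$PC3 <- rnorm(nrow(d))
  off <- rnorm(n_lakes, sd = lake_sd)
  d$y <- f(d$PC1) + off[match(d$lake_id, lakes)] + rnorm(nrow(d), sd = noise)
  d
}

test_that("a real smooth is retained and its lone drop contribution is the whole explained deviance", {
  d <- gamm_fixture(31, f = function(x) sin(2 * x), noise = 0.3)
  g <- fit_gamm(d, "y", c("PC1", "PC2", "PC3"))
  expect_true("PC1" %in% g$retained)
  if (identical(g$retained, "PC1")) {
    expect_equal(unname(g$drop_contribution["PC1"]), 100 * g$dev_explained,
                 tolerance = 1e-8)
  }
  expect_true(all(g$p_values < 0.05))
  expect_true(all(g$drop_contribution >= 0))
})

test_that("duplicated predictors cannot both survive selection", {
  d <- gamm_fixture(32, f = function(x) sin(2 * x), noise = 0.3)
  d$PC1b <- d$PC1 + rnorm(nrow(d), sd = 1e-3)
  g <- fit_gamm(d, "y", c("PC1", "PC1b", "PC2"))
  expect_lt(sum(c("PC1", "PC1b") %in% g$retained), 2)
})

test_that("with linear terms the model reduces to a linear mixed model", {
  d <- gamm_fixture(33, f = function(x) 0.8 * x, noise = 0.5)
  g <- fit_gamm(d, "y", "PC1", smooth = FALSE, threshold = 1)
  lmm <- lme4::lmer(y ~ PC1 + (1 | lake_id), data = d, REML = TRUE)
  expect_equal(unname(stats::coef(g$model)["PC1"]),
               unname(lme4::fixef(lmm)["PC1"]), tolerance = 1e-3)
})

test_that("GAMM preconditions are enforced", {
  d <- gamm_fixture(34)
  expect_error(fit_gamm(d[1:8, ], "y", "PC1"), "at least 10")
  expect_error(fit_gamm(d[d$lake_id %in% c("L01", "L02"), ], "y", "PC1"),
               "at least 3")
})

test_that("PERMANOVA flags a shifted subset and passes a random split", {
  set.seed(6)
  full <- data.frame(lake_id = sprintf("L%02d", 1:40), year = 2015,
                     m1 = rnorm(40), m2 = rnorm(40))
  sub <- full[1:15, ]
  sub_shift <- sub
  shifted_full <- full
  shifted_full$m1[1:15] <- shifted_full$m1[1:15] + 10
  sub_shift$m1 <- shifted_full$m1[1:15]
  res_shift <- representativeness_check(sub_shift, shifted_full,
                                        n_perm = 199, seed = 1)
  expect_equal(res_shift$p, 1 / 200)
  expect_false(res_shift$representative)

  res_null <- representativeness_check(sub, full, n_perm = 199, seed = 2)
  expect_lt(res_null$pseudo_F, 3)
  expect_gt(res_null$p, 0.05)
  expect_true(res_null$representative)

  expect_error(representativeness_check(full[1, , drop = FALSE], full), "at least 2")
  bad <- full[1:3, ]; bad$year <- 1999
  expect_error(representativeness_check(bad, full), "absent")
})
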