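test_that("temperature derivation is the midpoint/range pair", {
  d <- derive_climate(30, 20)
  expect_equal(d$tmean, 25)
  expect_equal(d$trange, 10)
  d2 <- derive_climate(c(18, 18), c(18, 10))
  expect_equal(d2$trange, c(0, 8))
  expect_error(derive_climate(10, 20), "tmax")
})

test_that("photoperiod behaves like the astronomical day-length model", {
  # equator: close to 12 h year round
  for (m in c(1, 4, 7, 10)) {
    expect_lt(abs(photoperiod(0, m) - 12), 0.2)
  }
  # austral seasons at latitude -30
  expect_gt(photoperiod(-30, 12), 12)
  expect_lt(photoperiod(-30, 6), 12)
  # equinox at latitude -23: declination near zero
  expect_lt(abs(photoperiod(-23, 3, 20) - 12), 0.2)
  # hemisphere antisymmetry: north winter = south summer
  expect_equal(photoperiod(35, 12), photoperiod(-35, 6), tolerance = 0.3)
  # annual mean near 12 h across the study's latitude band
  for (lat in c(0, -18, -30, -45)) {
    expect_lt(abs(mean(photoperiod(lat, 1:12)) - 12), 0.25)
  }
  expect_warning(p <- photoperiod(-80, 12), "clamped")
  expect_true(is.finite(p))
  expect_error(photoperiod(-30, 13), "1..12")
})

test_that("climate lookup is exact-keyed with explicit missing markers", {
  clim <- toy_climate()
  hit <- lookup_climate(clim, -23.5, -46.6, 1990, 3)
  expect_equal(hit$precip_mm, 90.03)
  expect_equal(hit$tmax_C, 25.3)
  miss <- lookup_climate(clim, -23.5, -46.6, 1800, 3)
  expect_true(is.na(miss$precip_mm))
  # nearest-site snapping
  near <- lookup_climate(clim, -23.4, -46.5, 1990, 3, match = "nearest")
  expect_equal(near$precip_mm, 90.03)
  expect_error(climate_table(data.frame(latitude = 1)), "missing column")
  expect_error(climate_table(data.frame(latitude = 0, longitude = 0,
                                        year = 2000, month = 1,
                                        precip_mm = -5, tmax_C = 20,
                                        tmin_C = 10)), "precipitation")
})

test_that("lagged design wraps years and drops incomplete records", {
  clim <- toy_climate(1988:1991)
  # record collected January 1990: lag 3 covariates come from October 1989
  rec <- make_records(1, year = 1990L, month = 1L)
  des <- build_lagged_design(rec, clim)
  expect_equal(des$precip_lag3[1], 89.10)  # encodes (1989, month 10)
  expect_equal(des$precip_lag0[1], 90.01)
  expect_equal(des$response[1], 0)
  # lag 0 photoperiod equals photoperiod at the record's own month
  expect_equal(des$photoperiod_lag0[1], photoperiod(-23.5, 1))
  expect_equal(des$photoperiod_lag3[1], photoperiod(-23.5, 10))
  # records whose lagged months precede coverage are dropped and counted
  rec10 <- make_records(10, year = c(rep(1990L, 8), 1988L, 1988L),
                        month = c(rep(6L, 8), 2L, 1L))
  des10 <- build_lagged_design(rec10, clim)
  expect_equal(nrow(des10), 8)
  expect_equal(attr(des10, "n_dropped"), 2)
})

test_that("design construction is consistent under a one-month shift", {
  clim <- toy_climate(1988:1991)
  rec <- make_records(4, year = 1990L, month = c(3L, 5L, 8L, 10L))
  des <- build_lagged_design(rec, clim)
  shifted <- rec
  shifted$month <- shifted$month + 1L
  # shift the climate table forward one month too
  clim2 <- clim
  nm <- clim2$month + 1L
  clim2$year <- clim2$year + (nm - 1L) %/% 12L
  clim2$month <- (nm - 1L) %% 12L + 1L
  des2 <- build_lagged_design(shifted, clim2)
  ccols <- grep("precip|tmean|trange", names(des), value = TRUE)
  expect_equal(des2[, ccols], des[, ccols], ignore_attr = TRUE)
})

test_that("collinearity screen computes VIF = 1/(1 - R2)", {
  set.seed(61)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sc <- collinearity_screen(X)
  expect_true(all(sc$vif < 1.2))
  expect_equal(unname(sc$vif), rep(1, 3), tolerance = 0.15)
  # duplicated covariate: infinite VIF
  X2 <- X; X2$d <- X2$a
  sc2 <- collinearity_screen(X2)
  expect_true(is.infinite(sc2$vif[["a"]]))
  expect_true("d" %in% sc2$flagged_vif)
  # near-duplicate tuned to R2 ~ 0.99 gives VIF ~ 100
  X3 <- X
  X3$e <- X3$a + rnorm(n, 0, sd(X3$a) / sqrt(99))
  sc3 <- collinearity_screen(X3)
  expect_gt(sc3$vif[["e"]], 30)
  r_ae <- sc3$correlation["a", "e"]
  expect_gt(abs(r_ae), 0.8)
  expect_true(any(sc3$flagged_pairs$var1 == "a" & sc3$flagged_pairs$var2 == "e"))
})

test_that("in-package VIF agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(62)
  n <- 150
  d <- data.frame(response = rnorm(n), a = rnorm(n), b = rnorm(n))
  d$c <- 0.6 * d$a + rnorm(n, 0, 0.5)
  ours <- collinearity_screen(d)$vif
  theirs <- car::vif(lm(response ~ a + b + c, data = d))
  expect_equal(unname(ours[c("a", "b", "c")]), unname(theirs),
               tolerance = 1e-8)
})

test_that("full-model OLS recovers noiseless truth exactly", {
  clim <- toy_climate(1985:1991)
  set.seed(63)
  rec <- make_records(40, year = sample(1988:1991, 40, replace = TRUE),
                      month = sample(2:11, 40, replace = TRUE))
  des <- build_lagged_design(rec, clim, lags = 0:1)
  des <- des[, c("response", "photoperiod_lag0", "photoperiod_lag1")]
  des$response <- 0.3 * des$photoperiod_lag0 - 0.4 * des$photoperiod_lag1 + 2
  fit <- suppressWarnings(fit_full_model(des))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  sl <- fit$terms$slope
  names(sl) <- fit$terms$term
  expect_equal(unname(sl["photoperiod_lag0"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(sl["photoperiod_lag1"]), -0.4, tolerance = 1e-6)
  # rank-deficient designs fail loudly with the aliased term named
  des$dup <- des$photoperiod_lag0
  expect_error(fit_full_model(des), "aliased")
})

test_that("backward selection drops noise terms and keeps real ones", {
  set.seed(64)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  d$response <- 1 + 2 * d$x1 - 1.5 * d$x2 + rnorm(n, 0, 0.7)
  fin <- backward_select(fit_full_model(d))
  kept <- fin$terms$term
  expect_true(all(c("x1", "x2") %in% kept))
  expect_false("noise" %in% kept)
  # single zero-effect covariate at large n: intercept-only final model
  set.seed(65)
  d2 <- data.frame(x = rnorm(500))
  d2$response <- 3 + rnorm(500)
  fin2 <- backward_select(fit_full_model(d2))
  expect_identical(fin2$terms$term, "(Intercept)")
})

test_that("one-way climate ANOVA matches classical identities", {
  # identical group means with nonzero within-group spread: F = 0
  sch2 <- interval_scheme(c("A", "B"), c(1960, 1980), c(1979, 1999))
  grid <- expand.grid(year = 1960:1999, month = 1:12)
  wiggle <- rep(seq(-1, 1, length.out = 20), 2)  # same pattern per interval
  clim <- climate_table(data.frame(latitude = -20, longitude = -45,
                                   year = grid$year, month = grid$month,
                                   precip_mm = 100,
                                   tmax_C = 25 + wiggle[grid$year - 1959],
                                   tmin_C = 15))
  a <- climate_anova(clim, scheme = sch2, variable = "tmean")
  expect_lt(a$f, 1e-12)
  # strong shift in the last interval
  clim2 <- clim
  clim2$tmax_C <- 25 + 5 * (clim2$year >= 1980) +
    0.01 * ((clim2$year * 7) %% 13)
  clim2 <- climate_table(as.data.frame(clim2))
  a2 <- climate_anova(clim2, scheme = sch2, variable = "tmean")
  expect_lt(a2$p_value, 0.001)
  # two-group ANOVA equals squared t-test
  ann <- aggregate((tmax_C + tmin_C) / 2 ~ year, data = clim2, FUN = mean)
  names(ann)[2] <- "v"
  tt <- t.test(ann$v[ann$year < 1980], ann$v[ann$year >= 1980],
               var.equal = TRUE)
  expect_equal(a2$f, unname(tt$statistic)^2, tolerance = 1e-8)
})
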