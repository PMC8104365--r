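test_that("record generation is deterministic and bookkeeps contaminants exactly", {
  spec <- phenology_preset()
  g1 <- gen_records(spec, seed = 5)
  g2 <- gen_records(spec, seed = 5)
  expect_identical(g1$records, g2$records)
  g3 <- gen_records(spec, seed = 6)
  expect_false(identical(g1$records, g3$records))
  # cleaning recovers the clean core and reports the injected contaminants
  cl <- clean_records(g1$records)
  expect_equal(cl$report$retained, g1$truth$n_clean)
  expect_equal(cl$report$duplicates_removed, g1$truth$n_duplicates)
  expect_equal(cl$report$sterile_removed, g1$truth$n_sterile)
  expect_equal(cl$report$missing_date_removed, g1$truth$n_missing_date)
})

test_that("degenerate and invalid generation specs are handled", {
  empty <- generation_spec(intervals = list(
    list(label = "I", first_year = 1950L, last_year = 1960L,
         model = "M1", params = list(), n = 0L)))
  g <- gen_records(empty, seed = 1)
  expect_equal(nrow(g$records), 0)
  expect_true(all(c("record_id", "year", "month", "flowering")
                  %in% names(g$records)))
  expect_error(generation_spec(intervals = list(
    list(label = "I", first_year = 1950L, last_year = 1960L,
         model = "M2A", params = list(q1 = 0, k1 = -2), n = 5L))), "kappa")
  expect_error(generation_spec(intervals = list(),
                               contamination = c(duplicates = 0.6,
                                                 sterile = 0.5)), "sum")
})

test_that("generated months concentrate where the mixture says they should", {
  spec <- generation_spec(intervals = list(
    list(label = "I", first_year = 1950L, last_year = 1999L,
         model = "M2A", params = list(q1 = month_to_angle(12), k1 = 5),
         n = 400L)))
  g <- gen_records(spec, seed = 9)
  frac_ndj <- mean(g$records$month %in% c(11, 12, 1))
  # quadrature oracle: mass of VM(Dec, k=5) over the Nov-Jan arcs
  mass <- sum(vapply(c(11, 12, 1), function(m) {
    arc_mass("M2A", list(q1 = month_to_angle(12), k1 = 5), m)
  }, numeric(1)))
  expect_gt(mass, 0.6)
  expect_gt(frac_ndj, 0.6)
  expect_lt(abs(frac_ndj - mass), 0.1)
})

test_that("generated angle histograms converge to the specified mixture", {
  params <- list(q1 = month_to_angle(3), k1 = 2, l1 = 0.6)
  spec <- generation_spec(intervals = list(
    list(label = "I", first_year = 1950L, last_year = 1999L,
         model = "M2C", params = params, n = 5000L)))
  g <- gen_records(spec, seed = 10)
  counts <- tabulate(g$records$month, 12)
  probs <- vapply(1:12, function(m) arc_mass("M2C", params, m), numeric(1))
  gof <- suppressWarnings(chisq.test(counts, p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
})

test_that("synthetic climate obeys its construction invariants", {
  spec <- climate_gen_spec()
  c1 <- gen_climate(spec, seed = 3)
  c2 <- gen_climate(spec, seed = 3)
  expect_identical(c1, c2)
  expect_true(all(c1$tmax_C >= c1$tmin_C))
  expect_true(all(c1$precip_mm >= 0))
  # zero trend and zero noise: every year identical
  flat <- climate_gen_spec(trend_per_decade = 0, temp_sd = 0,
                           precip_sdlog = 0, years = 2000:2005)
  cf <- gen_climate(flat, seed = 1)
  one_site <- cf[cf$latitude == cf$latitude[1], ]
  m1 <- one_site[one_site$month == 1, ]
  expect_equal(length(unique(round(m1$tmax_C, 10))), 1)
  expect_equal(length(unique(round(m1$precip_mm, 10))), 1)
})

test_that("the warming trend is recoverable from the generated series", {
  spec <- climate_gen_spec(trend_per_decade = 0.2, years = 1920:2016)
  clim <- gen_climate(spec, seed = 14)
  one <- clim[clim$latitude == spec$sites$latitude[1], ]
  ann <- aggregate((tmax_C + tmin_C) / 2 ~ year, data = one, FUN = mean)
  names(ann)[2] <- "tmean"
  slope <- coef(lm(tmean ~ year, data = ann))[["year"]] * 10
  expect_lt(abs(slope - 0.2), 0.05)
  # precipitation is the noisy variable: larger interannual CV
  annp <- aggregate(precip_mm ~ year, data = one, FUN = sum)
  cv <- function(v) sd(v) / mean(v)
  expect_gt(cv(annp$precip_mm), cv(ann$tmean + 273.15))
})

test_that("regression datasets carry the requested linear signal", {
  tr <- regression_preset()
  tr$sigma <- 0.2  # near-deterministic acceptance
  d <- gen_regression_dataset(tr, n = 120, seed = 21)
  des <- build_lagged_design(d$records, d$climate)
  fit <- fit_full_model(des)
  expect_gt(fit$r_squared, 0.9)
  expect_gt(d$truth$generating_r2, 0.9)
  # determinism
  d2 <- gen_regression_dataset(tr, n = 120, seed = 21)
  expect_identical(d$records, d2$records)
  # unknown covariates rejected
  bad <- tr; names(bad$slopes)[1] <- "sunspots_lag0"
  expect_error(gen_regression_dataset(bad, n = 30, seed = 1), "unknown")
})

test_that("an overparameterized design fails loudly", {
  tr <- regression_preset()
  d <- gen_regression_dataset(tr, n = 12, seed = 22)
  des <- build_lagged_design(d$records, d$climate)
  expect_error(fit_full_model(des), "covariates")
})
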