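#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to uniform sampling at
#' `kappa = 0`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Sample from one of the ten circular mixture models
#'
#' @param n Number of draws.
#' @param model_code One of [model_codes()].
#' @param params Free parameters of the model (see [mixture_logpdf()]);
#'   constrained entries are filled in.
#' @return Angles in `[0, 2*pi)`.
#' @export
rmixture <- function(n, model_code, params = list()) {
  code <- match_model(model_code)
  p <- expand_params(code, params)
  validate_params(p)
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(p$l1, p$l2, max(1 - p$l1 - p$l2, 0)))
  out <- numeric(n)
  if (any(comp == 1L)) out[comp == 1L] <- rvonmises(sum(comp == 1L), p$q1, p$k1)
  if (any(comp == 2L)) out[comp == 2L] <- rvonmises(sum(comp == 2L), p$q2, p$k2)
  if (any(comp == 3L)) out[comp == 3L] <- stats::runif(sum(comp == 3L), 0, 2 * pi)
  out
}

angle_to_month <- function(a) pmin(12L, as.integer(floor(wrap_angle(a) / (pi / 6))) + 1L)

make_records_skeleton <- function() {
  data.frame(record_id = character(0), species = character(0),
             collector = character(0), collector_number = character(0),
             year = integer(0), month = integer(0), day = integer(0),
             locality = character(0), latitude = numeric(0),
             longitude = numeric(0), flowering = logical(0),
             fruiting = logical(0), sterile = logical(0),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic herbarium record set
#'
#' Defines, per time interval, the circular model and parameters that
#' collection months are drawn from, plus contamination fractions and
#' collection sites, emulating the structure of a digitized specimen
#' dataset (about 100-200 records per species spread over three intervals).
#'
#' @param species Species label.
#' @param intervals List of lists with `label`, `first_year`, `last_year`,
#'   `model`, `params`, `n`.
#' @param contamination Named fractions `duplicates`, `sterile`,
#'   `missing_date` in `[0, 1)` (applied on top of the clean records, so
#'   ground-truth counts are exact).
#' @param sites Data frame with `latitude`, `longitude` and optional
#'   `weight`.
#' @param phase `"flowering"` or `"fruiting"`: which phenophase flag the
#'   generated specimens carry.
#' @return A `generation_spec` list.
#' @export
generation_spec <- function(species = "Synthetica exempli",
                            intervals,
                            contamination = c(duplicates = 0, sterile = 0,
                                              missing_date = 0),
                            sites = data.frame(latitude = c(-18.3, -22.5, -25.0,
                                                            -28.0, -30.4),
                                               longitude = c(-39.9, -43.2, -47.0,
                                                             -49.5, -51.3)),
                            phase = c("flowering", "fruiting")) {
  phase <- match.arg(phase)
  frac <- c(duplicates = 0, sterile = 0, missing_date = 0)
  frac[names(contamination)] <- contamination
  if (any(frac < 0) || sum(frac) >= 1) {
    stop("contamination fractions must be in [0,1) and sum below 1",
         call. = FALSE)
  }
  for (iv in intervals) {
    match_model(iv$model)
    if (iv$n < 0) stop("n_records must be >= 0", call. = FALSE)
    if (iv$model != "M1") {
      mixture_logpdf(0, iv$model, iv$params)  # validates params
    }
  }
  if (is.null(sites$weight)) sites$weight <- 1
  structure(list(species = species, intervals = intervals,
                 contamination = frac, sites = sites, phase = phase),
            class = "generation_spec")
}

#' The default "study-scale" record generation preset
#'
#' Three intervals (1920-1979, 1980-1999, 2000-2018) totalling about 180
#' records, unimodal early phenology drifting to a later unimodal pattern,
#' sites spanning latitudes -18 to -30, and mild contamination, emulating
#' the scale and structure of a cleaned long-term herbarium dataset.
#'
#' @param phase Phenophase flag carried by the records.
#' @return A `generation_spec`.
#' @export
phenology_preset <- function(phase = "flowering") {
  generation_spec(
    species = "Synthetica exempli",
    intervals = list(
      list(label = "I", first_year = 1920L, last_year = 1979L,
           model = "M2A", params = list(q1 = month_to_angle(12), k1 = 2.5),
           n = 50L),
      list(label = "II", first_year = 1980L, last_year = 1999L,
           model = "M2C", params = list(q1 = month_to_angle(1), k1 = 3,
                                        l1 = 0.7), n = 60L),
      list(label = "III", first_year = 2000L, last_year = 2018L,
           model = "M2A", params = list(q1 = month_to_angle(2), k1 = 2.5),
           n = 70L)
    ),
    contamination = c(duplicates = 0.10, sterile = 0.15, missing_date = 0.05),
    phase = phase
  )
}

#' Generate a synthetic herbarium record set with known ground truth
#'
#' Collection months are drawn from each interval's circular mixture
#' (angle mapped to month by 30-degree arc membership, day set to 15),
#' years uniformly within the interval, and sites by weight. Contaminant
#' rows (exact duplicates, sterile specimens, missing-date records) are
#' injected after the clean records are formed, so the returned truth
#' counts are exact.
#'
#' @param spec A [generation_spec()].
#' @param seed Integer seed; the output is fully deterministic given it.
#' @return A list with `records` (data frame in [parse_records()] layout)
#'   and `truth` (per-interval model/params/counts and contaminant counts).
#' @export
gen_records <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generation_spec"))
  set.seed(seed)
  rows <- list()
  idc <- 0L
  for (iv in spec$intervals) {
    if (iv$n == 0) next
    ang <- rmixture(iv$n, iv$model, iv$params)
    site <- sample.int(nrow(spec$sites), iv$n, replace = TRUE,
                       prob = spec$sites$weight)
    idc_new <- idc + seq_len(iv$n)
    rows[[length(rows) + 1]] <- data.frame(
      record_id = sprintf("SYN%05d", idc_new),
      species = spec$species,
      collector = sprintf("Collector %04d", idc_new),
      collector_number = as.character(1000L + idc_new),
      year = sample(seq(iv$first_year, iv$last_year), iv$n, replace = TRUE),
      month = angle_to_month(ang),
      day = 15L,
      locality = sprintf("Site %02d", site),
      latitude = spec$sites$latitude[site],
      longitude = spec$sites$longitude[site],
      flowering = spec$phase == "flowering",
      fruiting = spec$phase == "fruiting",
      sterile = FALSE,
      stringsAsFactors = FALSE
    )
    idc <- idc + iv$n
  }
  clean <- do.call(rbind, rows)
  if (is.null(clean)) {
    clean <- make_records_skeleton()
  }
  n_clean <- nrow(clean)
  frac <- spec$contamination
  n_dup <- round(frac["duplicates"] * n_clean)
  n_ster <- round(frac["sterile"] * n_clean)
  n_miss <- round(frac["missing_date"] * n_clean)
  contam <- list()
  if (n_dup > 0) {
    src <- clean[sample.int(n_clean, n_dup, replace = TRUE), , drop = FALSE]
    src$record_id <- sprintf("DUP%05d", seq_len(n_dup))
    contam[[length(contam) + 1]] <- src
  }
  if (n_ster > 0) {
    src <- clean[sample.int(n_clean, n_ster, replace = TRUE), , drop = FALSE]
    src$record_id <- sprintf("STE%05d", seq_len(n_ster))
    src$collector <- sprintf("Collector S%04d", seq_len(n_ster))
    src$flowering <- FALSE; src$fruiting <- FALSE; src$sterile <- TRUE
    contam[[length(contam) + 1]] <- src
  }
  if (n_miss > 0) {
    src <- clean[sample.int(n_clean, n_miss, replace = TRUE), , drop = FALSE]
    src$record_id <- sprintf("MIS%05d", seq_len(n_miss))
    src$collector <- sprintf("Collector M%04d", seq_len(n_miss))
    src$month <- NA_integer_; src$day <- NA_integer_
    contam[[length(contam) + 1]] <- src
  }
  records <- rbind(clean, do.call(rbind, contam))
  if (nrow(records) > 0) {
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
  }
  truth <- list(
    species = spec$species,
    intervals = lapply(spec$intervals, function(iv) {
      iv[c("label", "first_year", "last_year", "model", "params", "n")]
    }),
    n_clean = n_clean,
    n_duplicates = unname(n_dup), n_sterile = unname(n_ster),
    n_missing_date = unname(n_miss),
    seed = seed
  )
  list(records = records, truth = truth)
}

#' Specify a synthetic monthly climate series
#'
#' Monthly mean temperature is a baseline plus a linear warming trend, a
#' seasonal harmonic (warm austral summer, peaking in January) and Gaussian
#' noise; the diurnal range has its own harmonic; precipitation is a
#' seasonal harmonic scaled by lognormal noise, so interannual variation in
#' precipitation is much larger than in temperature.
#'
#' @param sites Data frame with `latitude`, `longitude`.
#' @param years Integer vector of years covered.
#' @param tmean_base Baseline mean temperature, degrees C.
#' @param trend_per_decade Linear warming, degrees C per decade.
#' @param seasonal_amp Seasonal temperature amplitude, degrees C.
#' @param temp_sd Monthly temperature noise SD, degrees C.
#' @param trange_base,trange_amp Mean and seasonal amplitude of the
#'   temperature range, degrees C.
#' @param precip_base Mean monthly precipitation, mm.
#' @param precip_amp Relative seasonal precipitation amplitude in `[0, 1)`.
#' @param precip_sdlog Lognormal sigma of monthly precipitation noise.
#' @return A `climate_gen_spec` list.
#' @export
climate_gen_spec <- function(sites = data.frame(latitude = c(-18.3, -22.5, -25.0,
                                                             -28.0, -30.4),
                                                longitude = c(-39.9, -43.2, -47.0,
                                                              -49.5, -51.3)),
                             years = 1920:2016,
                             tmean_base = 21, trend_per_decade = 0.15,
                             seasonal_amp = 3, temp_sd = 0.6,
                             trange_base = 9, trange_amp = 1.5,
                             precip_base = 120, precip_amp = 0.55,
                             precip_sdlog = 0.45) {
  structure(as.list(environment()), class = "climate_gen_spec")
}

#' Generate a synthetic monthly climate table
#'
#' @param spec A [climate_gen_spec()].
#' @param seed Integer seed.
#' @return A [climate_table()] with one row per site, year and month;
#'   `tmax_C >= tmin_C` holds by construction and precipitation is
#'   nonnegative.
#' @export
gen_climate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "climate_gen_spec"))
  set.seed(seed)
  grid <- expand.grid(site = seq_len(nrow(spec$sites)),
                      year = spec$years, month = 1:12)
  grid <- grid[order(grid$site, grid$year, grid$month), ]
  y0 <- min(spec$years)
  seas <- cos(2 * pi * (grid$month - 1) / 12)  # peaks in January (austral summer)
  tmean <- spec$tmean_base +
    spec$trend_per_decade * (grid$year - y0) / 10 +
    spec$seasonal_amp * seas +
    stats::rnorm(nrow(grid), 0, spec$temp_sd)
  trange <- pmax(0.5, spec$trange_base - spec$trange_amp * seas +
                   stats::rnorm(nrow(grid), 0, spec$temp_sd / 2))
  precip <- spec$precip_base * (1 + spec$precip_amp * seas) *
    stats::rlnorm(nrow(grid), -spec$precip_sdlog^2 / 2, spec$precip_sdlog)
  climate_table(data.frame(
    latitude = spec$sites$latitude[grid$site],
    longitude = spec$sites$longitude[grid$site],
    year = grid$year, month = grid$month,
    precip_mm = precip,
    tmax_C = tmean + trange / 2,
    tmin_C = tmean - trange / 2
  ))
}

#' Default slopes for the synthetic regression preset
#'
#' Photoperiod-dominated effects with mixed signs at lags 0, 1 and 3
#' months, sized so the linear predictor tracks the collection-month angle
#' over the phenologically active part of the year (see the methods
#' vignette for the derivation).
#'
#' @return A list with `intercept`, named `slopes` (units: radians per hour
#'   of photoperiod) and noise `sigma` (radians) targeting a generating R2
#'   of about 0.8.
#' @export
regression_preset <- function() {
  list(
    intercept = -8.6358,
    slopes = c(photoperiod_lag0 = 4.7842,
               photoperiod_lag1 = -5.3290,
               photoperiod_lag3 = 1.4964),
    sigma = 1.2
  )
}

#' Generate a regression dataset with known active climate terms
#'
#' Builds a synthetic climate table, then assembles records whose
#' collection months are consistent with the linear model
#' `angle(month) = intercept + sum(slope_j * covariate_j) + noise`:
#' candidate records (site, year, month) are screened by Gaussian
#' acceptance on the wrapped difference between their month angle and their
#' linear predictor, so the design built downstream carries the requested
#' signal. The realized generating R2 is reported in the truth.
#'
#' @param truth List with `intercept`, named `slopes` over the lag-0..3
#'   covariate set, and `sigma`; defaults to [regression_preset()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @param climate_spec A [climate_gen_spec()]; its sites are the candidate
#'   collection sites.
#' @param years Candidate collection years (must leave 3 months of climate
#'   history available).
#' @return A list with `records`, `climate`, and `truth` (inputs plus the
#'   realized `generating_r2` and residual SD).
#' @export
gen_regression_dataset <- function(truth = regression_preset(), n = 150L,
                                   seed = 1L,
                                   climate_spec = climate_gen_spec(),
                                   years = 1950:2015) {
  set.seed(seed)
  climate <- gen_climate(climate_spec, seed = seed + 1L)
  active <- names(truth$slopes)
  bad <- setdiff(active, covariate_names(0:3))
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sites <- climate_spec$sites
  accepted <- list()
  n_acc <- 0L
  batch <- max(4L * n, 200L)
  tries <- 0L
  while (n_acc < n && tries < 60L) {
    tries <- tries + 1L
    site <- sample.int(nrow(sites), batch, replace = TRUE)
    cand <- data.frame(
      year = sample(years, batch, replace = TRUE),
      month = sample.int(12L, batch, replace = TRUE),
      latitude = sites$latitude[site],
      longitude = sites$longitude[site]
    )
    design <- build_lagged_design(cand, climate, lags = 0:3)
    if (attr(design, "n_dropped") > 0) {
      stop("candidate years must lie fully inside climate coverage",
           call. = FALSE)
    }
    X <- as.matrix(design[, active, drop = FALSE])
    pred <- truth$intercept + drop(X %*% truth$slopes)
    resid <- design$response - pred
    resid <- ((resid + pi) %% (2 * pi)) - pi  # wrapped to (-pi, pi]
    keep <- stats::runif(nrow(design)) < exp(-resid^2 / (2 * truth$sigma^2))
    idx <- which(keep)
    if (length(idx)) {
      accepted[[length(accepted) + 1]] <- cand[idx, , drop = FALSE]
      n_acc <- n_acc + length(idx)
    }
  }
  if (n_acc < n) stop("acceptance sampling starved; widen sigma", call. = FALSE)
  acc <- do.call(rbind, accepted)[seq_len(n), , drop = FALSE]
  m <- nrow(acc)
  records <- data.frame(
    record_id = sprintf("REG%05d", seq_len(m)),
    species = "Synthetica exempli",
    collector = sprintf("Collector R%04d", seq_len(m)),
    collector_number = as.character(seq_len(m)),
    year = acc$year, month = acc$month, day = 15L,
    locality = sprintf("Site %.1f %.1f", acc$latitude, acc$longitude),
    latitude = acc$latitude, longitude = acc$longitude,
    flowering = TRUE, fruiting = FALSE, sterile = FALSE,
    stringsAsFactors = FALSE
  )
  design <- build_lagged_design(records, climate, lags = 0:3)
  X <- as.matrix(design[, active, drop = FALSE])
  pred <- truth$intercept + drop(X %*% truth$slopes)
  resid <- ((design$response - pred + pi) %% (2 * pi)) - pi
  r2 <- 1 - stats::var(resid) / stats::var(design$response)
  truth_out <- c(truth, list(active = active,
                             generating_r2 = r2,
                             resid_sd = stats::sd(resid),
                             seed = seed, n = m))
  list(records = records, climate = climate, truth = truth_out)
}
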