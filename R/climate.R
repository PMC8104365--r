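#' Derive mean temperature and temperature range
#'
#' Monthly mean temperature is the midpoint of the monthly maximum and
#' minimum; the range is their difference.
#'
#' @param tmax,tmin Numeric vectors (degrees C), `tmax >= tmin`.
#' @return Data frame with columns `tmean` and `trange`.
#' @export
derive_climate <- function(tmax, tmin) {
  if (length(tmax) != length(tmin)) stop("length mismatch", call. = FALSE)
  if (any(!is.na(tmax) & !is.na(tmin) & tmax < tmin)) {
    stop("tmax must be >= tmin", call. = FALSE)
  }
  data.frame(tmean = (tmax + tmin) / 2, trange = tmax - tmin)
}

#' Day length (photoperiod) for a latitude and date
#'
#' Daylight hours from the standard astronomical day-length model (solar
#' declination with sunrise/sunset at the conventional zenith of about
#' 90.83 degrees), via `geosphere::daylength`. Latitudes beyond +/-66
#' degrees (polar day/night regimes) are clamped with a warning.
#'
#' @param latitude Decimal degrees, negative south.
#' @param month Integer month 1..12.
#' @param day Day of month used for the within-month reference date
#'   (default 15, mid-month).
#' @return Day length in hours.
#' @export
photoperiod <- function(latitude, month, day = 15L) {
  month_to_angle(month)  # validates month
  if (any(abs(latitude) > 90)) stop("invalid latitude", call. = FALSE)
  if (any(abs(latitude) > 66)) {
    warning("latitude beyond +/-66 degrees clamped for day-length model")
    latitude <- pmin(pmax(latitude, -66), 66)
  }
  cum <- c(0L, cumsum(days_in_month(1:11, 2001L)))
  doy <- cum[month] + day
  geosphere::daylength(latitude, doy)
}

#' Construct a monthly climate table
#'
#' Long-format monthly climate keyed by site coordinates, year and month,
#' as extracted from gridded climatologies: monthly precipitation sum and
#' mean monthly maximum/minimum temperatures.
#'
#' @param df Data frame with columns `latitude`, `longitude`, `year`,
#'   `month`, `precip_mm`, `tmax_C`, `tmin_C`.
#' @return The validated data frame with class `climate_table`.
#' @export
climate_table <- function(df) {
  need <- c("latitude", "longitude", "year", "month",
            "precip_mm", "tmax_C", "tmin_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("climate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(df$precip_mm) & df$precip_mm < 0)) {
    stop("precipitation must be >= 0", call. = FALSE)
  }
  if (any(!is.na(df$tmax_C) & !is.na(df$tmin_C) & df$tmax_C < df$tmin_C)) {
    stop("tmax_C must be >= tmin_C", call. = FALSE)
  }
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Read a climate table from a delimited file
#' @param path Path to a comma- or tab-separated file with the
#'   [climate_table()] columns.
#' @return A `climate_table`.
#' @export
read_climate <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  climate_table(utils::read.table(path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE))
}

#' Look up monthly climate for a location and month
#'
#' Exact-key lookup by default; `match = "nearest"` snaps to the nearest
#' climate site (squared-degree distance), the table analogue of
#' nearest-cell raster extraction. A missing key yields `NA` values (an
#' explicit missing marker), never zero.
#'
#' @param climate A `climate_table`.
#' @param latitude,longitude Coordinates of the record.
#' @param year,month Collection year and month.
#' @param match `"exact"` or `"nearest"` (site snapping; year/month remain
#'   exact).
#' @param tol Coordinate tolerance for exact matching, degrees.
#' @return One-row data frame with `precip_mm`, `tmax_C`, `tmin_C` (all `NA`
#'   if not covered).
#' @export
lookup_climate <- function(climate, latitude, longitude, year, month,
                           match = c("exact", "nearest"), tol = 1e-6) {
  match <- base::match.arg(match)
  stopifnot(inherits(climate, "climate_table"))
  if (match == "nearest") {
    sites <- unique(climate[, c("latitude", "longitude")])
    d2 <- (sites$latitude - latitude)^2 + (sites$longitude - longitude)^2
    best <- which.min(d2)
    latitude <- sites$latitude[best]
    longitude <- sites$longitude[best]
    tol <- 1e-9
  }
  hit <- abs(climate$latitude - latitude) <= tol &
    abs(climate$longitude - longitude) <= tol &
    climate$year == year & climate$month == month
  if (!any(hit)) {
    return(data.frame(precip_mm = NA_real_, tmax_C = NA_real_,
                      tmin_C = NA_real_))
  }
  climate[which(hit)[1], c("precip_mm", "tmax_C", "tmin_C"), drop = FALSE]
}

lag_month <- function(year, month, k) {
  m <- month - k
  y <- year + (m - 1) %/% 12
  m <- (m - 1) %% 12 + 1
  list(year = y, month = m)
}

covariate_names <- function(lags = 0:3) {
  vars <- c("photoperiod", "precip", "tmean", "trange")
  as.vector(t(outer(vars, lags, function(v, l) paste0(v, "_lag", l))))
}

#' Build the lagged climate design for phenology regression
#'
#' For every record, the response is the circular angle of the collection
#' month (radians, month-arc convention) and the covariates are photoperiod
#' (hours), monthly precipitation (mm), mean temperature and temperature
#' range (degrees C), each at lags 0 to `max(lags)` months before
#' collection (year-wrapping). Records with any missing climate month are
#' dropped and counted.
#'
#' @param records Cleaned records data frame (needs `year`, `month`,
#'   `latitude`, `longitude`).
#' @param climate A `climate_table`.
#' @param lags Integer lags in months (default `0:3`).
#' @param match Site matching mode for [lookup_climate()].
#' @return Data frame with `response` plus one column per covariate-lag;
#'   attribute `n_dropped` counts records lost to missing climate.
#' @export
build_lagged_design <- function(records, climate, lags = 0:3,
                                match = c("exact", "nearest")) {
  match <- base::match.arg(match)
  n <- nrow(records)
  if (n == 0) stop("no records", call. = FALSE)
  lat <- records$latitude
  lon <- records$longitude
  if (match == "nearest") {
    sites <- unique(climate[, c("latitude", "longitude")])
    snap <- vapply(seq_len(n), function(i) {
      which.min((sites$latitude - lat[i])^2 + (sites$longitude - lon[i])^2)
    }, integer(1))
    lat <- sites$latitude[snap]
    lon <- sites$longitude[snap]
  }
  cols <- covariate_names(lags)
  X <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  ckey <- paste(climate$latitude, climate$longitude, climate$year,
                climate$month)
  for (k in lags) {
    lm_ <- lag_month(records$year, records$month, k)
    idx <- base::match(paste(lat, lon, lm_$year, lm_$month), ckey)
    X[, paste0("photoperiod_lag", k)] <- photoperiod(lat, lm_$month)
    X[, paste0("precip_lag", k)] <- climate$precip_mm[idx]
    tmax <- climate$tmax_C[idx]; tmin <- climate$tmin_C[idx]
    X[, paste0("tmean_lag", k)] <- (tmax + tmin) / 2
    X[, paste0("trange_lag", k)] <- tmax - tmin
  }
  design <- data.frame(response = month_to_angle(records$month), X)
  complete <- stats::complete.cases(design)
  out <- design[complete, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no records with complete climate covariates", call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Collinearity screen: Pearson correlations and variance-inflation factors
#'
#' Computes the pairwise Pearson correlation matrix of the covariates and,
#' for each covariate, the VIF `1/(1 - R2_j)` from regressing it on all the
#' others. Covariates whose |r| or VIF exceed the thresholds are flagged; a
#' constant or aliased covariate reports an infinite VIF.
#'
#' @param design Design data frame (a `response` column, if present, is
#'   ignored).
#' @param r_threshold Flag threshold on |pairwise r| (default 0.8).
#' @param vif_threshold Flag threshold on VIF (default 10).
#' @return A list with `correlation` (matrix), `vif` (named vector),
#'   `flagged_pairs` (data frame) and `flagged_vif` (character vector).
#' @export
collinearity_screen <- function(design, r_threshold = 0.8,
                                vif_threshold = 10) {
  X <- design[, setdiff(names(design), "response"), drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 covariates", call. = FALSE)
  C <- stats::cor(X)
  vif <- vapply(names(X), function(j) {
    xj <- X[[j]]
    if (stats::var(xj) == 0) return(Inf)
    aux <- stats::lm(xj ~ ., data = X[setdiff(names(X), j)])
    r2 <- suppressWarnings(summary(aux)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  pairs <- which(abs(C) > r_threshold & upper.tri(C), arr.ind = TRUE)
  flagged_pairs <- data.frame(var1 = rownames(C)[pairs[, 1]],
                              var2 = colnames(C)[pairs[, 2]],
                              r = C[pairs], stringsAsFactors = FALSE)
  list(correlation = C, vif = vif, flagged_pairs = flagged_pairs,
       flagged_vif = names(vif)[vif > vif_threshold])
}

regression_summary <- function(fit, n) {
  s <- summary(fit)
  co <- s$coefficients
  terms <- data.frame(term = rownames(co), slope = co[, 1], se = co[, 2],
                      t = co[, 3], p = co[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  fstat <- s$fstatistic
  structure(list(terms = terms,
                 r_squared = s$r.squared,
                 f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
                 f_p = if (is.null(fstat)) NA_real_ else {
                   stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
                 },
                 n = n, fit = fit),
            class = "pheno_regression")
}

#' @export
print.pheno_regression <- function(x, ...) {
  cat(sprintf("Phenology-climate regression: R2 = %.3f, F = %.2f, n = %d\n",
              x$r_squared, x$f, x$n))
  print(transform(x$terms, slope = round(slope, 4), se = round(se, 4),
                  t = round(t, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Fit the full phenology-climate regression model
#'
#' Ordinary least squares of the collection-month angle on every climate
#' covariate at every lag, with per-term slope, SE, t and p, plus R2, F
#' and n. A rank-deficient design is an error naming the aliased terms.
#'
#' @param design Output of [build_lagged_design()].
#' @return A `pheno_regression` object.
#' @export
fit_full_model <- function(design) {
  p <- ncol(design) - 1
  if (nrow(design) <= p + 1) {
    stop("need n > number of covariates + 1", call. = FALSE)
  }
  # embed the data in the call so stepAIC can re-evaluate it later
  fit <- do.call(stats::lm, list(formula = response ~ ., data = design))
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  regression_summary(fit, nrow(design))
}

#' Backward stepwise model selection by AIC
#'
#' Starting from the full model, iteratively drops the term whose removal
#' most decreases AIC until no removal does (classic backward `stepAIC`),
#' then refits and summarizes the final model.
#'
#' @param full A `pheno_regression` from [fit_full_model()], or an `lm`.
#' @return A `pheno_regression` for the selected model.
#' @export
backward_select <- function(full) {
  fit <- if (inherits(full, "pheno_regression")) full$fit else full
  final <- MASS::stepAIC(fit, direction = "backward", trace = 0)
  regression_summary(final, length(stats::residuals(final)))
}

#' One-way ANOVA of a climate variable across time intervals
#'
#' Aggregates the monthly series at a site to annual means (annual sums for
#' precipitation), groups years by the interval scheme, and runs a standard
#' one-way ANOVA.
#'
#' @param climate A `climate_table` restricted to one site (or any subset).
#' @param scheme An [interval_scheme()].
#' @param variable One of `"tmean"`, `"trange"`, `"tmax"`, `"tmin"`,
#'   `"precip"`.
#' @return A list with `f`, `df` (numerator, denominator), `p_value` and the
#'   per-interval annual means (`groups`).
#' @export
climate_anova <- function(climate, scheme = default_intervals(),
                          variable = c("tmean", "trange", "tmax", "tmin",
                                       "precip")) {
  variable <- base::match.arg(variable)
  stopifnot(inherits(climate, "climate_table"))
  val <- switch(variable,
    tmean = (climate$tmax_C + climate$tmin_C) / 2,
    trange = climate$tmax_C - climate$tmin_C,
    tmax = climate$tmax_C,
    tmin = climate$tmin_C,
    precip = climate$precip_mm)
  agg_fun <- if (variable == "precip") sum else mean
  ann <- stats::aggregate(val, by = list(year = climate$year),
                          FUN = agg_fun, na.rm = TRUE)
  names(ann)[2] <- "value"
  ann$interval <- assign_interval(ann$year, scheme)
  ann <- ann[!is.na(ann$interval), ]
  sizes <- table(ann$interval)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("each interval needs >= 2 annual values and >= 2 intervals",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ interval, data = ann)
  s <- summary(fit)[[1]]
  list(f = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = s[["Pr(>F)"]][1],
       groups = stats::aggregate(value ~ interval, data = ann, FUN = mean))
}
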