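#' Convert a calendar month to a circular angle
#'
#' Months are encoded on the circle with one 30-degree arc per month:
#' January maps to 0, February to 30 degrees, ..., December to 330 degrees.
#' Angles are returned in radians.
#'
#' @param month Integer vector of months in 1..12.
#' @return Numeric vector of angles in radians, in `[0, 2*pi)`.
#' @examples
#' month_to_angle(1)          # 0
#' month_to_angle(12) * 180 / pi  # 330
#' @export
month_to_angle <- function(month) {
  if (!is.numeric(month) || any(is.na(month)) ||
      any(month != round(month)) || any(month < 1 | month > 12)) {
    stop("`month` must be integer(s) in 1..12", call. = FALSE)
  }
  (month - 1) * pi / 6
}

days_in_month <- function(month, year) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2 & leap] <- 29L
  d
}

#' Convert a collection date to a circular angle
#'
#' Two conventions are supported. `"month_arc"` (the default used throughout
#' the seasonality analysis) assigns each month a 30-degree arc and ignores
#' the day. `"day_of_year"` maps day-of-year `d` in a year of `D` days to
#' `2*pi*(d-1)/D`, leap-aware; when the day is missing it falls back to the
#' 15th with a warning.
#'
#' @param year Integer year (used only for leap-year handling).
#' @param month Integer month 1..12.
#' @param day Integer day of month, or `NA` if unrecorded.
#' @param convention `"month_arc"` or `"day_of_year"`.
#' @return Angle in radians in `[0, 2*pi)`.
#' @export
date_to_angle <- function(year, month, day = NA,
                          convention = c("month_arc", "day_of_year")) {
  convention <- match.arg(convention)
  if (convention == "month_arc") {
    return(month_to_angle(month))
  }
  month_to_angle(month)  # validates month
  if (any(is.na(day))) {
    warning("day missing for day_of_year convention; using mid-month day 15")
    day[is.na(day)] <- 15L
  }
  dim <- days_in_month(month, year)
  if (any(day < 1 | day > dim)) {
    stop("day out of range for month", call. = FALSE)
  }
  cum <- c(0L, cumsum(days_in_month(1:11, year)))
  doy <- cum[month] + day
  year_len <- ifelse(days_in_month(rep(2L, length(year)), year) == 29L, 366L, 365L)
  2 * pi * (doy - 1) / year_len
}

#' Convert a circular angle back to a calendar date
#'
#' Inverse of [date_to_angle()]. Under `"month_arc"` the month is the arc
#' containing the angle and the day is placed linearly within the month;
#' under `"day_of_year"` the angle maps back to a day of a 365-day year.
#'
#' @param angle Angle in radians (wrapped into `[0, 2*pi)`).
#' @param convention `"month_arc"` or `"day_of_year"`.
#' @return A list with components `month` and `day`.
#' @export
angle_to_date <- function(angle, convention = c("month_arc", "day_of_year")) {
  convention <- match.arg(convention)
  a <- angle %% (2 * pi)
  if (convention == "month_arc") {
    arc <- a / (pi / 6)
    month <- pmin(12L, as.integer(floor(arc)) + 1L)
    frac <- arc - (month - 1)
    nd <- days_in_month(month, 2001L)
    day <- pmin(nd, pmax(1L, as.integer(round(frac * nd + 0.5))))
  } else {
    doy <- as.integer(floor(a / (2 * pi) * 365)) + 1L
    cum <- cumsum(days_in_month(1:12, 2001L))
    month <- as.integer(findInterval(doy - 1L, c(0L, cum[-12])))
    day <- doy - c(0L, cum)[month]
  }
  list(month = month, day = day)
}

wrap_angle <- function(a) a %% (2 * pi)

#' Construct a circular sample
#'
#' A lightweight container for angles in radians with optional provenance
#' (species, phenophase, time interval), as produced when a set of cleaned
#' specimen records is encoded on the circle.
#'
#' @param angles Numeric vector of angles; wrapped into `[0, 2*pi)`.
#' @param species,phase,interval Optional provenance strings.
#' @return An object of class `circular_sample` (numeric vector with
#'   attributes).
#' @export
circular_sample <- function(angles, species = NA_character_,
                            phase = NA_character_, interval = NA_character_) {
  if (length(angles) < 1 || any(!is.finite(angles))) {
    stop("angles must be a non-empty finite numeric vector", call. = FALSE)
  }
  structure(wrap_angle(as.numeric(angles)),
            species = species, phase = phase, interval = interval,
            class = "circular_sample")
}

as_angles <- function(x) {
  a <- as.numeric(unclass(x))
  if (length(a) < 1 || any(!is.finite(a))) {
    stop("expected a non-empty finite vector of angles", call. = FALSE)
  }
  wrap_angle(a)
}

#' Circular summary statistics
#'
#' Mean direction and mean resultant (vector) length of a circular sample,
#' plus the mean calendar date implied by the mean direction under the
#' active encoding convention.
#'
#' @param x Angles in radians (numeric vector or `circular_sample`).
#' @param convention Date convention passed to [angle_to_date()].
#' @return A list of class `circ_summary` with `n`, `mean_angle` (radians;
#'   `NA` when the resultant length is exactly 0), `r` (mean vector length in
#'   `[0,1]`) and `mean_date` (list with month, day; `NA` when undefined).
#' @export
circ_summary <- function(x, convention = c("month_arc", "day_of_year")) {
  convention <- match.arg(convention)
  a <- as_angles(x)
  n <- length(a)
  C <- sum(cos(a))
  S <- sum(sin(a))
  r <- sqrt(C^2 + S^2) / n
  if (r < .Machine$double.eps * n) {
    mu <- NA_real_
    md <- list(month = NA_integer_, day = NA_integer_)
  } else {
    mu <- wrap_angle(atan2(S, C))
    md <- angle_to_date(mu, convention)
  }
  structure(list(n = n, mean_angle = mu, r = r, mean_date = md,
                 convention = convention),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat("Circular summary (n =", x$n, ")\n")
  cat("  mean vector length r =", format(x$r, digits = 4), "\n")
  if (is.na(x$mean_angle)) {
    cat("  mean angle undefined (r = 0)\n")
  } else {
    cat("  mean angle =", format(x$mean_angle, digits = 4), "rad;",
        "mean date =", sprintf("%02d/%02d", x$mean_date$day, x$mean_date$month),
        "(day/month)\n")
  }
  invisible(x)
}
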