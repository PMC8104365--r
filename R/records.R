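#' Default column mapping for occurrence files
#'
#' Maps the standard internal field names to the column names of a
#' Darwin-Core-like delimited file. Override entries to match your file.
#'
#' @param ... Named overrides, e.g. `year = "yearCollected"`.
#' @return Named character vector mapping internal names to file columns.
#' @export
default_column_map <- function(...) {
  map <- c(record_id = "record_id", species = "species",
           collector = "collector", collector_number = "collector_number",
           year = "year", month = "month", day = "day",
           locality = "locality", latitude = "latitude",
           longitude = "longitude", flowering = "flowering",
           fruiting = "fruiting", sterile = "sterile")
  over <- c(...)
  map[names(over)] <- over
  map
}

req_fields <- c("record_id", "species", "collector", "year", "month",
                "locality", "latitude", "longitude",
                "flowering", "fruiting", "sterile")

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("1", "true", "t", "yes", "y")
}

#' Read and validate herbarium occurrence records
#'
#' Reads a delimited text file (comma or tab separated, one header row) of
#' digitized specimen records, maps its columns to the standard fields, and
#' validates each row. Rows that fail validation (month outside 1..12, day
#' invalid for the month, coordinates out of range, sterile specimens marked
#' as flowering/fruiting) are excluded and reported in the diagnostics, not
#' silently dropped. Missing day, year or month are retained as `NA` (later
#' cleaning decides their fate).
#'
#' @param path Path to the delimited file (UTF-8; `,` or tab inferred from
#'   the header, or set `sep`).
#' @param column_map Mapping from internal field names to file columns, see
#'   [default_column_map()]. `collector_number` and `day` may be absent from
#'   the file.
#' @param sep Field separator; `NULL` to infer.
#' @return A list with `records` (validated data frame) and `diagnostics`
#'   (data frame with row number and reason for each excluded row).
#' @export
parse_records <- function(path, column_map = default_column_map(), sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           fill = TRUE, fileEncoding = "UTF-8")
  optional <- c("collector_number", "day")
  needed <- setdiff(names(column_map), optional)
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get_col <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA
  }
  rec <- data.frame(
    record_id = as.character(get_col("record_id")),
    species = as.character(get_col("species")),
    collector = as.character(get_col("collector")),
    collector_number = as.character(get_col("collector_number")),
    year = suppressWarnings(as.integer(get_col("year"))),
    month = suppressWarnings(as.integer(get_col("month"))),
    day = suppressWarnings(as.integer(get_col("day"))),
    locality = as.character(get_col("locality")),
    latitude = suppressWarnings(as.numeric(get_col("latitude"))),
    longitude = suppressWarnings(as.numeric(get_col("longitude"))),
    flowering = as_flag(get_col("flowering")),
    fruiting = as_flag(get_col("fruiting")),
    sterile = as_flag(get_col("sterile")),
    stringsAsFactors = FALSE
  )
  reasons <- character(nrow(rec))
  bad_month <- !is.na(rec$month) & (rec$month < 1 | rec$month > 12)
  reasons[bad_month] <- "month outside 1..12"
  ok_month <- !is.na(rec$month) & !bad_month
  has_day <- ok_month & !is.na(rec$day) & !is.na(rec$year)
  bad_day <- rep(FALSE, nrow(rec))
  bad_day[has_day] <- rec$day[has_day] < 1 |
    rec$day[has_day] > days_in_month(rec$month[has_day], rec$year[has_day])
  reasons[bad_day & reasons == ""] <- "day invalid for month"
  bad_coord <- (!is.na(rec$latitude) & abs(rec$latitude) > 90) |
    (!is.na(rec$longitude) & abs(rec$longitude) > 180)
  reasons[bad_coord & reasons == ""] <- "coordinates out of range"
  bad_phase <- rec$sterile & (rec$flowering | rec$fruiting)
  reasons[bad_phase & reasons == ""] <- "sterile specimen flagged as fertile"
  bad <- reasons != ""
  diagnostics <- data.frame(row = which(bad),
                            record_id = rec$record_id[bad],
                            reason = reasons[bad],
                            stringsAsFactors = FALSE)
  list(records = rec[!bad, , drop = FALSE], diagnostics = diagnostics)
}

norm_key <- function(x) tolower(trimws(x))

#' Clean herbarium occurrence records
#'
#' Applies the standard cleaning rules in a fixed order so the report is
#' unambiguous: (1) exact-duplicate groups (same collector, full date and
#' locality) reduced to one representative; (2) sterile specimens removed;
#' (3) records lacking a collection date (year or month) or locality
#' removed. By default collector and locality strings are whitespace-trimmed
#' and case-folded before duplicate matching, to tolerate transcription
#' variants.
#'
#' @param records Data frame as returned by [parse_records()].
#' @param normalize Normalize collector/locality before duplicate matching
#'   (set `FALSE` for strict byte equality).
#' @return A list with `records` (retained rows, original order) and
#'   `report`, a `cleaning_report` whose counts sum to the input size.
#' @export
clean_records <- function(records, normalize = TRUE) {
  n_in <- nrow(records)
  report <- function(dups, ster, mdate, mloc, kept) {
    structure(list(input = n_in, duplicates_removed = dups,
                   sterile_removed = ster, missing_date_removed = mdate,
                   missing_locality_removed = mloc, retained = kept),
              class = "cleaning_report")
  }
  if (n_in == 0) {
    return(list(records = records, report = report(0L, 0L, 0L, 0L, 0L)))
  }
  keyfun <- if (normalize) norm_key else identity
  key <- paste(keyfun(records$collector), records$year, records$month,
               records$day, keyfun(records$locality), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  r <- records[!dup, , drop = FALSE]
  ster <- r$sterile %in% TRUE
  n_ster <- sum(ster)
  r <- r[!ster, , drop = FALSE]
  mdate <- is.na(r$year) | is.na(r$month)
  n_mdate <- sum(mdate)
  r <- r[!mdate, , drop = FALSE]
  mloc <- is.na(r$locality) | trimws(r$locality) == ""
  n_mloc <- sum(mloc)
  r <- r[!mloc, , drop = FALSE]
  list(records = r,
       report = report(n_dup, n_ster, n_mdate, n_mloc, nrow(r)))
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat("  input records        ", x$input, "\n")
  cat("  duplicates removed   ", x$duplicates_removed, "\n")
  cat("  sterile removed      ", x$sterile_removed, "\n")
  cat("  missing date removed ", x$missing_date_removed, "\n")
  cat("  missing locality rm. ", x$missing_locality_removed, "\n")
  cat("  retained             ", x$retained, "\n")
  invisible(x)
}

#' Define an analysis time-interval scheme
#'
#' @param labels Character labels, one per interval.
#' @param first_year,last_year Integer vectors of inclusive bounds.
#' @return A data frame of class `interval_scheme`. Overlapping intervals
#'   are a configuration error.
#' @seealso [default_intervals()]
#' @export
interval_scheme <- function(labels, first_year, last_year) {
  if (length(labels) != length(first_year) ||
      length(labels) != length(last_year)) {
    stop("labels and year bounds must have equal length", call. = FALSE)
  }
  if (any(last_year < first_year)) {
    stop("last_year must be >= first_year", call. = FALSE)
  }
  o <- order(first_year)
  s <- data.frame(label = as.character(labels)[o],
                  first_year = as.integer(first_year)[o],
                  last_year = as.integer(last_year)[o],
                  stringsAsFactors = FALSE)
  if (nrow(s) > 1 && any(s$first_year[-1] <= s$last_year[-nrow(s)])) {
    stop("intervals must not overlap", call. = FALSE)
  }
  class(s) <- c("interval_scheme", "data.frame")
  s
}

#' Default time intervals for the long-term phenology analysis
#'
#' Three intervals: I 1920-1979 (long, reflecting sparser early
#' collections), II 1980-1999, III 2000-2018.
#'
#' @return An `interval_scheme`.
#' @export
default_intervals <- function() {
  interval_scheme(c("I", "II", "III"),
                  c(1920L, 1980L, 2000L),
                  c(1979L, 1999L, 2018L))
}

#' Assign records to time intervals by collection year
#'
#' @param year Integer vector of years (or a records data frame, in which
#'   case its `year` column is used).
#' @param scheme An [interval_scheme()].
#' @return Character vector of interval labels; `NA` for years outside all
#'   intervals.
#' @export
assign_interval <- function(year, scheme = default_intervals()) {
  if (is.data.frame(year)) year <- year$year
  if (!inherits(scheme, "interval_scheme")) {
    stop("`scheme` must be an interval_scheme", call. = FALSE)
  }
  out <- rep(NA_character_, length(year))
  for (i in seq_len(nrow(scheme))) {
    hit <- !is.na(year) & year >= scheme$first_year[i] &
      year <= scheme$last_year[i]
    out[hit] <- scheme$label[i]
  }
  out
}

#' Subset records by phenophase
#'
#' A specimen bearing both open flowers and fruits appears in both the
#' flowering and fruiting subsets.
#'
#' @param records Cleaned records data frame.
#' @param phase `"flowering"` or `"fruiting"`.
#' @return The subset of rows with that phenophase, original order kept.
#' @export
phenophase_subset <- function(records, phase = c("flowering", "fruiting")) {
  phase <- match.arg(phase)
  records[records[[phase]] %in% TRUE, , drop = FALSE]
}

#' Split collection months by interval for one phenophase
#'
#' Convenience bridge from cleaned records to the grouped two-sample tests:
#' returns the months of the records of the given phenophase, split by
#' assigned interval.
#'
#' @param records Cleaned records data frame.
#' @param scheme An [interval_scheme()].
#' @param phase `"flowering"` or `"fruiting"`.
#' @return Named list of integer month vectors, one per interval label (in
#'   scheme order); records outside the scheme are dropped.
#' @export
months_by_interval <- function(records, scheme = default_intervals(),
                               phase = c("flowering", "fruiting")) {
  phase <- match.arg(phase)
  sub <- phenophase_subset(records, phase)
  lab <- assign_interval(sub$year, scheme)
  out <- lapply(scheme$label, function(l) sub$month[!is.na(lab) & lab == l])
  names(out) <- scheme$label
  out
}

#' Write records to a delimited file
#'
#' @param records Records data frame.
#' @param path Output path; tab-separated when the extension is `.tsv`,
#'   otherwise comma-separated.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
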