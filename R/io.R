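# Input/output: CSV readers and writers for the pipeline's canonical dialect
# (comma-separated, UTF-8, ISO 8601 second-resolution timestamps, naive local
# time handled in a fixed UTC frame).

parse_timestamp <- function(x) {
  ts <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  retry <- is.na(ts) & !is.na(x)
  if (any(retry)) {
    ts[retry] <- as.POSIXct(x[retry], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  ts
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

require_columns <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Read an RFID reading stream
#'
#' Reads a detection log — one row per registration of one ear-tag
#' transponder by one antenna, at most one per second — and returns a clean,
#' globally ordered reading set. Rows are sorted by (animal, timestamp,
#' location); exact duplicate rows are dropped. Rows whose `location_id` is
#' not in `layout`, or whose timestamp cannot be parsed, are rejected and
#' counted; rejection counts are reported on stderr and attached as the
#' `"rejected"` attribute so that filtering is never silent.
#'
#' Two different locations may register the same animal in the same second
#' (adjacent reading areas); such rows are physically dubious but kept,
#' ordered by location id — the run-collapsing step bounds their effect.
#'
#' @param path CSV file with header columns `timestamp` (ISO 8601 seconds),
#'   `animal_id`, `location_id`, `pen_id`.
#' @param layout A [pen_layout()]; rows referencing locations outside it are
#'   rejected.
#' @return A `data.table` with columns `animal_id`, `timestamp` (POSIXct),
#'   `location_id`, `pen_id`, keyed by the sort order above. Attribute
#'   `rejected`: named integer vector with counts `bad_timestamp` and
#'   `unknown_location`.
#' @export
read_readings <- function(path, layout) {
  stopifnot(inherits(layout, "pen_layout"))
  if (!file.exists(path)) stop("readings file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", encoding = "UTF-8")
  require_columns(dt, c("timestamp", "animal_id", "location_id", "pen_id"),
                  "readings file")
  rejected <- c(bad_timestamp = 0L, unknown_location = 0L)
  if (nrow(dt)) {
    ts <- parse_timestamp(dt$timestamp)
    bad_ts <- which(is.na(ts))
    if (length(bad_ts)) {
      rejected["bad_timestamp"] <- length(bad_ts)
      message(sprintf(
        "read_readings: rejected %d row(s) with unparseable timestamp (line %s%s)",
        length(bad_ts),
        paste(utils::head(bad_ts, 5L) + 1L, collapse = ", "),
        if (length(bad_ts) > 5L) ", ..." else ""))
    }
    unknown <- which(!(dt$location_id %in% layout$locations))
    if (length(unknown)) {
      rejected["unknown_location"] <- length(unknown)
      message(sprintf(
        "read_readings: rejected %d row(s) with location_id outside the layout (%s)",
        length(unknown),
        paste(unique(dt$location_id[utils::head(unknown, 5L)]), collapse = ", ")))
    }
    keep <- setdiff(seq_len(nrow(dt)), union(bad_ts, unknown))
    dt <- dt[keep]
    dt[, timestamp := ts[keep]]
  } else {
    dt[, timestamp := as.POSIXct(character(), tz = "UTC")]
  }
  dt <- dt[, .(animal_id, timestamp, location_id, pen_id)]
  data.table::setorder(dt, animal_id, timestamp, location_id)
  dt <- unique(dt)
  data.table::setattr(dt, "rejected", rejected)
  dt[]
}

#' Read locomotion-score health records
#'
#' Health inspections record a locomotion score per animal and observation
#' date on a 0--3 scale (0 = no signs of lameness, 1 = visible signs,
#' 2 = lame with compensatory behavior, 3 = reluctant to walk). Rows with a
#' score outside 0--3 or an unparseable date are rejected and counted.
#'
#' @param path CSV file with header columns `animal_id`, `date`
#'   (`YYYY-MM-DD`), `locomotion_score`.
#' @return A `data.table` with columns `animal_id`, `date` (Date),
#'   `locomotion_score` (integer), sorted by (animal, date). Attribute
#'   `rejected`: count of dropped rows.
#' @export
read_health <- function(path) {
  if (!file.exists(path)) stop("health file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", encoding = "UTF-8")
  require_columns(dt, c("animal_id", "date", "locomotion_score"), "health file")
  rejected <- 0L
  if (nrow(dt)) {
    d <- as.Date(dt$date, format = "%Y-%m-%d")
    score <- suppressWarnings(as.numeric(dt$locomotion_score))
    ok_score <- !is.na(score) & score == round(score) & score >= 0 & score <= 3
    bad <- which(is.na(d) | !ok_score)
    if (length(bad)) {
      rejected <- length(bad)
      message(sprintf(
        "read_health: rejected %d row(s) with invalid date or locomotion score (line %s%s)",
        length(bad),
        paste(utils::head(bad, 5L) + 1L, collapse = ", "),
        if (length(bad) > 5L) ", ..." else ""))
    }
    keep <- setdiff(seq_len(nrow(dt)), bad)
    dt <- data.table::data.table(
      animal_id = dt$animal_id[keep],
      date = d[keep],
      locomotion_score = as.integer(score[keep]))
  } else {
    dt <- data.table::data.table(
      animal_id = character(), date = as.Date(character()),
      locomotion_score = integer())
  }
  data.table::setorder(dt, animal_id, date)
  data.table::setattr(dt, "rejected", rejected)
  dt[]
}

#' Read cohort metadata (fattening-period start dates)
#'
#' Fattening days are counted from the day the pigs move into the pen
#' (fattening day 1), so every pen needs a start date.
#'
#' @param path CSV file with header columns `pen_id`, `start_date`
#'   (`YYYY-MM-DD`).
#' @return A `data.table` with columns `pen_id`, `start_date` (Date).
#' @seealso [cohort_meta()] to build the same table in code.
#' @export
read_cohort_meta <- function(path) {
  if (!file.exists(path)) stop("cohort metadata file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", encoding = "UTF-8")
  require_columns(dt, c("pen_id", "start_date"), "cohort metadata file")
  cohort_meta(dt$pen_id, as.Date(dt$start_date, format = "%Y-%m-%d"))
}

#' Build cohort metadata in code
#'
#' @param pen_id Character vector of pen ids.
#' @param start_date Date vector (recycled if length 1): fattening day 1 of
#'   each pen.
#' @return A `data.table` with columns `pen_id`, `start_date`.
#' @export
cohort_meta <- function(pen_id, start_date) {
  start_date <- as.Date(start_date)
  if (anyNA(start_date)) stop("unparseable start_date", call. = FALSE)
  dt <- data.table::data.table(pen_id = as.character(pen_id),
                               start_date = start_date)
  if (anyDuplicated(dt$pen_id)) stop("duplicate pen_id in cohort metadata", call. = FALSE)
  dt[]
}

#' Write a result table as canonical CSV
#'
#' Writes any pipeline table with a header row, the columns in their current
#' order, timestamps as ISO 8601 seconds and dates as `YYYY-MM-DD`. Numeric
#' values are written at full precision (15 significant digits), so a write
#' followed by [read_table()] round-trips distances to well below 1e-9 m.
#'
#' @param x A data.frame / data.table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- data.table::as.data.table(x)
  for (col in names(x)) {
    if (inherits(x[[col]], "POSIXct")) {
      data.table::set(x, j = col, value = format_timestamp(x[[col]]))
    } else if (inherits(x[[col]], "Date")) {
      data.table::set(x, j = col, value = format(x[[col]], "%Y-%m-%d"))
    }
  }
  ok <- tryCatch({
    data.table::fwrite(x, path, quote = "auto")
    TRUE
  }, error = function(e) {
    stop("cannot write table to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Re-read a table written by [write_table()]
#'
#' Columns named `timestamp` are parsed back to POSIXct and columns named
#' `date` or `start_date` back to Date; everything else keeps fread's type
#' inference.
#'
#' @param path CSV file path.
#' @return A `data.table`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, encoding = "UTF-8")
  if ("timestamp" %in% names(dt) && !inherits(dt$timestamp, "POSIXct")) {
    dt[, timestamp := parse_timestamp(as.character(timestamp))]
  }
  for (col in intersect(c("date", "start_date"), names(dt))) {
    # plain Date (fread yields IDate for ISO dates)
    data.table::set(dt, j = col, value = as.Date(as.character(dt[[col]])))
  }
  dt[]
}
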