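# Core virtual-walking-distance (VWD) computation.
#
# The VWD of one animal-day is the sum of center-to-center distances between
# consecutively visited antenna locations, in visiting order. Consecutive
# readings at the same antenna imply no inter-antenna movement, so runs of
# identical locations are collapsed first (equivalently, d(x, x) = 0 makes
# collapsing a no-op for the total). Each calendar day is computed in
# isolation: the first reading of a day opens a new path and no transition
# spans midnight.

#' Collapse same-location runs of a reading sequence
#'
#' Reduces a time-ordered sequence of detections to the sequence of distinct
#' location visits: maximal runs of consecutive readings at one location
#' become a single visit carrying the timestamps of its first and last
#' reading.
#'
#' @param location_id Character vector of locations, in time order.
#' @param timestamp POSIXct vector parallel to `location_id`, non-decreasing.
#' @return A `data.table` with columns `location_id`, `t_first`, `t_last`,
#'   `n` (readings in the run); no two consecutive rows share a location.
#' @examples
#' ts <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + 0:5
#' collapse_runs(c("T", "T", "T", "P", "P", "T"), ts)$location_id # T P T
#' @export
collapse_runs <- function(location_id, timestamp) {
  stopifnot(length(location_id) == length(timestamp))
  if (!length(location_id)) {
    return(data.table::data.table(
      location_id = character(),
      t_first = as.POSIXct(character(), tz = "UTC"),
      t_last = as.POSIXct(character(), tz = "UTC"),
      n = integer()))
  }
  r <- rle(as.character(location_id))
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.table::data.table(
    location_id = r$values,
    t_first = timestamp[first],
    t_last = timestamp[last],
    n = r$lengths)
}

check_locations <- function(locs, m) {
  miss <- setdiff(unique(locs), rownames(m))
  if (length(miss)) {
    stop("location(s) absent from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

lookup_dist <- function(m, from, to) {
  check_locations(c(from, to), m)
  if (!length(from)) return(numeric())
  m[cbind(from, to)]
}

as_dist_matrix <- function(x) {
  if (inherits(x, "pen_layout")) x$dist else x
}

date_utc <- function(ts) as.Date(ts, tz = "UTC")

#' Daily virtual walking distance of one animal-day
#'
#' @param readings A data.frame / data.table with columns `timestamp` and
#'   `location_id` (plus optionally `animal_id`), all rows belonging to one
#'   animal and one calendar date.
#' @param dist A distance matrix (or a [pen_layout()], whose matrix is used)
#'   covering every location present.
#' @return A one-row `data.table` with `animal_id`, `date`, `vwd_m`,
#'   `n_readings`, `n_transitions`. A day with readings at a single location
#'   has `vwd_m = 0`; an empty input yields `n_readings = 0` and `vwd_m = NA`
#'   (no detections is missing data, not zero activity).
#' @examples
#' lay <- table2_layout()
#' ts <- as.POSIXct("2024-01-01", tz = "UTC") + c(3600 * 7, 3600 * 12, 3600 * 18)
#' rd <- data.frame(animal_id = "p1", timestamp = ts,
#'                  location_id = c("trough", "playing_device", "trough"))
#' daily_vwd(rd, lay)$vwd_m # 5.2 + 5.2 = 10.4
#' @export
daily_vwd <- function(readings, dist) {
  m <- as_dist_matrix(dist)
  readings <- data.table::as.data.table(readings)
  aid <- if ("animal_id" %in% names(readings) && nrow(readings)) {
    u <- unique(readings$animal_id)
    if (length(u) > 1L) stop("readings span more than one animal", call. = FALSE)
    u
  } else NA_character_
  if (!nrow(readings)) {
    return(data.table::data.table(
      animal_id = aid, date = as.Date(NA), vwd_m = NA_real_,
      n_readings = 0L, n_transitions = 0L))
  }
  if (length(unique(date_utc(readings$timestamp))) > 1L) {
    stop("readings span more than one calendar date", call. = FALSE)
  }
  check_locations(readings$location_id, m)
  readings <- readings[order(timestamp, location_id)]
  v <- collapse_runs(readings$location_id, readings$timestamp)
  d <- lookup_dist(m, utils::head(v$location_id, -1L), v$location_id[-1L])
  data.table::data.table(
    animal_id = aid,
    date = date_utc(readings$timestamp[1L]),
    vwd_m = sum(d),
    n_readings = nrow(readings),
    n_transitions = length(d))
}

#' Hour-of-day virtual walking distances of one animal-day
#'
#' Splits the day's distance over 24 hour bins, bin `h` covering
#' `[h:00, h+1:00)`. Each transition's distance is assigned to the hour of
#' the arriving visit's first detection (the latest defensible completion
#' time of the movement). The 24 bins always sum to the day's total.
#'
#' @inheritParams daily_vwd
#' @return A named numeric vector of length 24 (`h00` ... `h23`), meters.
#' @export
hourly_vwd <- function(readings, dist) {
  m <- as_dist_matrix(dist)
  readings <- data.table::as.data.table(readings)
  bins <- stats::setNames(numeric(24), sprintf("h%02d", 0:23))
  if (!nrow(readings)) return(bins)
  if (length(unique(date_utc(readings$timestamp))) > 1L) {
    stop("readings span more than one calendar date", call. = FALSE)
  }
  check_locations(readings$location_id, m)
  readings <- readings[order(timestamp, location_id)]
  v <- collapse_runs(readings$location_id, readings$timestamp)
  if (nrow(v) < 2L) return(bins)
  d <- lookup_dist(m, utils::head(v$location_id, -1L), v$location_id[-1L])
  arrive_hour <- as.integer(format(v$t_first[-1L], "%H", tz = "UTC"))
  for (i in seq_along(d)) {
    bins[arrive_hour[i] + 1L] <- bins[arrive_hour[i] + 1L] + d[i]
  }
  bins
}

#' Compute daily and hourly VWD tables for a whole reading set
#'
#' Vectorized over all animals and dates: produces one daily row per
#' (animal, date) with at least one reading — reading-free days are absent,
#' not zero — and a parallel wide hourly table whose 24 bins sum to the daily
#' total. Fattening day 1 is the pen's start date from `meta`.
#'
#' @param readings A reading set from [read_readings()] (columns `animal_id`,
#'   `timestamp`, `location_id`, `pen_id`).
#' @param layout A [pen_layout()] covering every location in `readings`.
#' @param meta Cohort metadata from [cohort_meta()] / [read_cohort_meta()];
#'   every pen in `readings` must have a start date.
#' @return A list with elements `daily` (columns `animal_id`, `pen_id`,
#'   `date`, `fattening_day`, `vwd_m`, `n_readings`, `n_transitions`) and
#'   `hourly` (columns `animal_id`, `date`, `h00` ... `h23`), both sorted by
#'   (animal, date).
#' @export
compute_vwd <- function(readings, layout, meta) {
  m <- as_dist_matrix(layout)
  dt <- data.table::as.data.table(readings)
  require_columns(dt, c("animal_id", "timestamp", "location_id", "pen_id"),
                  "reading set")
  empty_daily <- data.table::data.table(
    animal_id = character(), pen_id = character(), date = as.Date(character()),
    fattening_day = integer(), vwd_m = numeric(), n_readings = integer(),
    n_transitions = integer())
  empty_hourly <- data.table::data.table(animal_id = character(),
                                         date = as.Date(character()))
  for (h in sprintf("h%02d", 0:23)) empty_hourly[, (h) := numeric()]
  if (!nrow(dt)) return(list(daily = empty_daily, hourly = empty_hourly[]))

  miss <- setdiff(unique(dt$location_id), rownames(m))
  if (length(miss)) {
    stop("location(s) absent from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pens <- unique(dt$pen_id)
  no_meta <- setdiff(pens, meta$pen_id)
  if (length(no_meta)) {
    stop("pen(s) without a fattening start date: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  }

  dt <- dt[order(animal_id, timestamp, location_id)]
  dt[, date := date_utc(timestamp)]
  new_day <- c(TRUE, dt$animal_id[-1L] != dt$animal_id[-nrow(dt)] |
                 dt$date[-1L] != dt$date[-nrow(dt)])
  new_run <- new_day | c(TRUE, dt$location_id[-1L] != dt$location_id[-nrow(dt)])
  dt[, visit_id := cumsum(new_run)]

  visits <- dt[, .(animal_id = animal_id[1L], pen_id = pen_id[1L],
                   date = date[1L], location_id = location_id[1L],
                   t_first = timestamp[1L]), by = visit_id]
  first_of_day <- c(TRUE, visits$animal_id[-1L] != visits$animal_id[-nrow(visits)] |
                      visits$date[-1L] != visits$date[-nrow(visits)])
  visits[, prev_loc := data.table::shift(location_id)]
  visits[first_of_day, prev_loc := NA_character_]
  visits[, dist_m := 0]
  has_prev <- !is.na(visits$prev_loc)
  visits[has_prev, dist_m := m[cbind(prev_loc, location_id)]]
  visits[, hour := as.integer(format(t_first, "%H", tz = "UTC"))]

  daily <- visits[, .(pen_id = pen_id[1L],
                      vwd_m = sum(dist_m),
                      n_transitions = sum(!is.na(prev_loc))),
                  by = .(animal_id, date)]
  counts <- dt[, .(n_readings = .N), by = .(animal_id, date)]
  daily <- counts[daily, on = c("animal_id", "date")]
  daily <- meta[daily, on = "pen_id"]
  daily[, fattening_day := as.integer(date - start_date) + 1L]
  daily <- daily[, .(animal_id, pen_id, date, fattening_day, vwd_m,
                     n_readings, n_transitions)]
  data.table::setorder(daily, animal_id, date)

  trans <- visits[has_prev, .(vwd_m = sum(dist_m)),
                  by = .(animal_id, date, hour)]
  hcols <- sprintf("h%02d", 0:23)
  hourly <- daily[, .(animal_id, date)]
  if (nrow(trans)) {
    trans[, hour := sprintf("h%02d", hour)]
    wide <- data.table::dcast(trans, animal_id + date ~ hour,
                              value.var = "vwd_m", fill = 0)
    hourly <- wide[hourly, on = c("animal_id", "date")]
  }
  for (col in hcols) {
    if (!col %in% names(hourly)) hourly[, (col) := 0]
    hourly[is.na(hourly[[col]]), (col) := 0]
  }
  data.table::setcolorder(hourly, c("animal_id", "date", hcols))
  data.table::setorder(hourly, animal_id, date)
  list(daily = daily[], hourly = hourly[])
}
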