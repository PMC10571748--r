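# Synthetic barn simulator.
#
# Pigs are simulated as a renewal (semi-Markov) process over the pen's
# antenna locations plus an implicit resting state: visit start times follow
# an inhomogeneous Poisson process whose hourly intensity encodes the
# feeding-driven diurnal rhythm and the nocturnal rest window, visit
# locations are drawn from fixed preference weights, and dwell times are
# exponential with per-location means. Transit between locations is
# instantaneous at the reading level (detections only happen inside reading
# areas), so travel time is folded into the resting state. Detection then
# thins each visit-second independently with the location's sensitivity.
# A single root seed drives deterministic per-pig/per-day substreams, so the
# same scenario replayed under different sensitivities reuses identical
# trajectories.

#' Define a simulation scenario
#'
#' All behavioral and detection parameters of the synthetic barn, with
#' defaults emulating an instrumented conventional fattening pen: six
#' feedings between 6 a.m. and 10 p.m., artificial light and activity in the
#' same window, a nocturnal rest phase, per-antenna sensitivity of about 0.9
#' at the trough, 0.6 at the drinkers and 0.75 at the playing device, and
#' activity declining across the fattening period.
#'
#' @param n_pigs Number of pigs.
#' @param n_days Number of fattening days simulated (day 1 = move-in).
#' @param layout A [pen_layout()]; defaults to the bundled five-location pen.
#' @param pens Character vector of pen ids; pigs are assigned round-robin.
#' @param start_date Calendar date of fattening day 1.
#' @param feeding_hours Hours (0--23) at which a feeding starts; activity is
#'   boosted during the hour following each feeding start.
#' @param feeding_boost Multiplicative intensity boost in feeding hours.
#' @param afternoon_hours Hours of elevated late-afternoon/evening activity.
#' @param afternoon_boost Multiplicative boost in those hours.
#' @param rest_hours Hours of the nocturnal rest window (default 22:00--06:00).
#' @param rest_suppression Multiplicative intensity factor in rest hours
#'   (0 = no nocturnal visits at all).
#' @param visits_per_day Expected location visits per day for a pig with unit
#'   activity multiplier in the first fattening stage. The default (78),
#'   together with the location preference weights and the pen distances,
#'   puts simulated daily VWD in the observed 10--800 m range.
#' @param location_weights Named nonnegative visit preference weights, one
#'   per layout location.
#' @param dwell_mean_s Named mean visit durations in seconds (exponential).
#' @param sensitivity Named per-location detection probabilities in `[0, 1]`
#'   (chance that a present animal is registered in a given second).
#' @param pig_sdlog Log-sd of the per-pig lognormal activity multiplier
#'   (median 1).
#' @param stage_multipliers One activity multiplier per fattening stage;
#'   the default 1.0/0.8/0.6/0.5 encodes declining activity over fattening.
#' @param stage_breaks Stage boundaries, as in [assign_stage()].
#' @param lameness Optional `data.frame` with columns `pig` (1-based index),
#'   `onset_day`, `factor` (activity multiplier while lame, e.g. 0.3) and
#'   `duration` (days).
#' @param seed Root RNG seed (integer); every random draw in the simulator
#'   derives from it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pigs = 25L, n_days = 120L,
                         layout = table2_layout(),
                         pens = "pen1",
                         start_date = as.Date("2024-01-01"),
                         feeding_hours = c(6, 9, 12, 15, 18, 22),
                         feeding_boost = 1.9,
                         afternoon_hours = 16:21,
                         afternoon_boost = 1.6,
                         rest_hours = c(22, 23, 0:5),
                         rest_suppression = 0.05,
                         visits_per_day = 78,
                         location_weights = c(trough = 0.35, drinker1 = 0.15,
                                              drinker2 = 0.15, drinker3 = 0.15,
                                              playing_device = 0.20),
                         dwell_mean_s = c(trough = 25, drinker1 = 10,
                                          drinker2 = 10, drinker3 = 10,
                                          playing_device = 15),
                         sensitivity = c(trough = 0.9, drinker1 = 0.6,
                                         drinker2 = 0.6, drinker3 = 0.6,
                                         playing_device = 0.75),
                         pig_sdlog = 0.35,
                         stage_multipliers = c(1.0, 0.8, 0.6, 0.5),
                         stage_breaks = c(30L, 60L, 90L),
                         lameness = NULL,
                         seed = 1L) {
  stopifnot(inherits(layout, "pen_layout"),
            n_pigs >= 1L, n_days >= 1L, length(pens) >= 1L)
  locs <- layout$locations
  for (nm in c("location_weights", "dwell_mean_s", "sensitivity")) {
    v <- get(nm)
    miss <- setdiff(locs, names(v))
    if (length(miss)) {
      stop(nm, " missing location(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(sensitivity < 0 | sensitivity > 1)) {
    stop("sensitivities must lie in [0, 1]", call. = FALSE)
  }
  if (any(location_weights < 0) || sum(location_weights[locs]) <= 0) {
    stop("location weights must be nonnegative with positive sum", call. = FALSE)
  }
  if (any(dwell_mean_s <= 0)) stop("dwell means must be positive", call. = FALSE)
  if (any(feeding_hours < 0 | feeding_hours >= 24)) {
    stop("feeding hours must lie in [0, 24)", call. = FALSE)
  }
  if (length(stage_multipliers) != length(stage_breaks) + 1L) {
    stop("need one stage multiplier per stage", call. = FALSE)
  }
  if (any(stage_multipliers < 0) || rest_suppression < 0 ||
      visits_per_day < 0 || pig_sdlog < 0) {
    stop("rates and multipliers must be nonnegative", call. = FALSE)
  }
  if (!is.null(lameness)) {
    lameness <- data.table::as.data.table(lameness)
    require_columns(lameness, c("pig", "onset_day", "factor", "duration"),
                    "lameness table")
    stopifnot(all(lameness$pig >= 1L & lameness$pig <= n_pigs),
              all(lameness$factor >= 0), all(lameness$duration >= 1L))
  }
  structure(list(
    n_pigs = as.integer(n_pigs), n_days = as.integer(n_days),
    layout = layout, pens = as.character(pens),
    start_date = as.Date(start_date),
    feeding_hours = feeding_hours, feeding_boost = feeding_boost,
    afternoon_hours = afternoon_hours, afternoon_boost = afternoon_boost,
    rest_hours = rest_hours, rest_suppression = rest_suppression,
    visits_per_day = visits_per_day,
    location_weights = location_weights[locs],
    dwell_mean_s = dwell_mean_s[locs],
    sensitivity = sensitivity[locs],
    pig_sdlog = pig_sdlog,
    stage_multipliers = stage_multipliers,
    stage_breaks = as.integer(stage_breaks),
    lameness = lameness,
    seed = as.integer(seed)), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d pigs x %d days, %d locations, seed %d\n",
              x$n_pigs, x$n_days, length(x$layout$locations), x$seed))
  invisible(x)
}

# deterministic substream seeds; all arithmetic exact in doubles, result < 2^31
derive_seed <- function(root, pig = 0L, day = 0L, stream = 0L) {
  as.integer((abs(as.numeric(root)) * 1009 + as.numeric(pig) * 1000003 +
                as.numeric(day) * 7919 + as.numeric(stream)) %% 2147483647)
}

#' Relative hourly visit intensity of a scenario
#'
#' @param scenario A [sim_scenario()].
#' @return Numeric vector of length 24 (unnormalized weights): base 1,
#'   multiplied by the afternoon boost, the feeding boost and the rest-window
#'   suppression where those apply.
#' @export
diurnal_weights <- function(scenario) {
  r <- rep(1, 24)
  hrs <- 0:23
  r[hrs %in% scenario$afternoon_hours] <-
    r[hrs %in% scenario$afternoon_hours] * scenario$afternoon_boost
  r[hrs %in% floor(scenario$feeding_hours)] <-
    r[hrs %in% floor(scenario$feeding_hours)] * scenario$feeding_boost
  r[hrs %in% scenario$rest_hours] <-
    r[hrs %in% scenario$rest_hours] * scenario$rest_suppression
  r
}

#' Per-pig activity multipliers of a scenario
#'
#' Drawn once per scenario (lognormal, median 1, log-sd `pig_sdlog`) from a
#' dedicated substream of the root seed, so they are identical for every
#' replay of the scenario.
#'
#' @param scenario A [sim_scenario()].
#' @return Numeric vector of length `n_pigs`.
#' @export
pig_multipliers <- function(scenario) {
  set.seed(derive_seed(scenario$seed, stream = 1L))
  stats::rlnorm(scenario$n_pigs, meanlog = 0, sdlog = scenario$pig_sdlog)
}

stage_multiplier_for_day <- function(scenario, day) {
  idx <- findInterval(day, c(1L, scenario$stage_breaks + 1L))
  scenario$stage_multipliers[idx]
}

lameness_factor <- function(scenario, pig, day) {
  lm <- scenario$lameness
  if (is.null(lm) || !nrow(lm)) return(1)
  f <- 1
  for (i in seq_len(nrow(lm))) {
    if (lm$pig[i] == pig && day >= lm$onset_day[i] &&
        day < lm$onset_day[i] + lm$duration[i]) {
      f <- f * lm$factor[i]
    }
  }
  f
}

# sequential path length over a visit-location sequence (same-location
# repeats contribute 0; summation order matches compute_vwd's)
path_length <- function(locs, m) {
  r <- rle(as.character(locs))$values
  if (length(r) < 2L) return(0)
  sum(m[cbind(utils::head(r, -1L), r[-1L])])
}

#' Simulate one pig-day trajectory
#'
#' Draws the day's visit log from the scenario's inhomogeneous Poisson visit
#' process (per-hour counts, uniform placement within the hour), fixed
#' location preference weights and exponential dwell times. Visits are
#' integer-second intervals `[entry_s, exit_s)`, at least 1 s long, truncated
#' so they never overlap and never cross midnight; the trajectory starts and
#' ends in the resting state. The ground-truth path length is the sequential
#' sum of inter-location distances over the actual visit sequence, detected
#' or not.
#'
#' @param scenario A [sim_scenario()].
#' @param pig 1-based pig index.
#' @param day 1-based fattening day.
#' @param pig_mult Optional precomputed [pig_multipliers()] vector (avoids
#'   recomputation in cohort loops).
#' @return A list: `visits` (`data.table` with `location_id`, `entry_s`,
#'   `exit_s`), `truth_m` (meters), `n_visits`.
#' @export
simulate_day <- function(scenario, pig, day, pig_mult = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(pig_mult)) pig_mult <- pig_multipliers(scenario)
  set.seed(derive_seed(scenario$seed, pig, day, stream = 2L))
  mult <- pig_mult[pig] * stage_multiplier_for_day(scenario, day) *
    lameness_factor(scenario, pig, day)
  r <- diurnal_weights(scenario)
  lambda <- if (sum(r) > 0) scenario$visits_per_day * mult * r / sum(r) else rep(0, 24)
  n_h <- stats::rpois(24, lambda)
  empty <- data.table::data.table(location_id = character(),
                                  entry_s = integer(), exit_s = integer())
  if (sum(n_h) == 0L) {
    return(list(visits = empty, truth_m = 0, n_visits = 0L))
  }
  entry <- floor((rep(0:23, n_h) + stats::runif(sum(n_h))) * 3600)
  entry <- sort(as.integer(entry))
  n <- length(entry)
  locs <- sample(names(scenario$location_weights), n, replace = TRUE,
                 prob = scenario$location_weights)
  dwell <- stats::rexp(n, rate = 1 / scenario$dwell_mean_s[locs])
  exit <- entry + pmax(1L, as.integer(ceiling(dwell)))
  # visits may not overlap (one animal is in one place) nor cross midnight
  exit <- pmin(exit, c(entry[-1L], 86400L))
  keep <- exit > entry
  visits <- data.table::data.table(location_id = locs[keep],
                                   entry_s = entry[keep],
                                   exit_s = exit[keep])
  list(visits = visits,
       truth_m = path_length(visits$location_id, scenario$layout$dist),
       n_visits = nrow(visits))
}

#' Thin a visit log into detected per-second readings
#'
#' Every whole second an animal spends inside a reading area is a potential
#' reading; each is realized independently with the location's sensitivity.
#' The detection substream depends only on the root seed and (pig, day), not
#' on the sensitivity values, so replays under different sensitivities share
#' the underlying uniform draws: lowering a sensitivity can only remove
#' readings, never add or move them.
#'
#' @param visits Visit log from [simulate_day()].
#' @param scenario A [sim_scenario()].
#' @param pig,day Indices identifying the detection substream.
#' @param sensitivity Optional named override of the scenario's per-location
#'   sensitivities.
#' @return A `data.table` with `sec` (integer second of day) and
#'   `location_id`, one row per realized reading.
#' @export
apply_detection <- function(visits, scenario, pig, day,
                            sensitivity = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sens <- if (is.null(sensitivity)) scenario$sensitivity else sensitivity
  miss <- setdiff(unique(visits$location_id), names(sens))
  if (length(miss)) {
    stop("sensitivity missing for location(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  set.seed(derive_seed(scenario$seed, pig, day, stream = 3L))
  if (!nrow(visits)) {
    return(data.table::data.table(sec = integer(), location_id = character()))
  }
  len <- visits$exit_s - visits$entry_s
  sec <- rep(visits$entry_s, len) + (sequence(len) - 1L)
  loc <- rep(visits$location_id, len)
  u <- stats::runif(length(sec))
  keep <- u < sens[loc]
  data.table::data.table(sec = sec[keep], location_id = loc[keep])
}

#' Simulate a full cohort: readings, ground truth and health records
#'
#' Runs [simulate_day()] and [apply_detection()] for every pig and fattening
#' day and assembles (i) a reading set in the exact shape [read_readings()]
#' produces, (ii) the ground-truth table of true center-path lengths, and
#' (iii) twice-weekly locomotion-score health records (score 0 outside
#' lameness events; score 2 in the first half of an event, 1 in the second).
#' Everything is reproducible from the scenario's root seed.
#'
#' @param scenario A [sim_scenario()].
#' @param sensitivity Optional named override passed to [apply_detection()];
#'   because trajectories and detection draws are seed-derived, two calls
#'   differing only in `sensitivity` replay identical trajectories.
#' @return A list: `readings` (sorted reading set), `ground_truth`
#'   (`animal_id`, `pen_id`, `day_index`, `date`, `truth_m`, `n_visits`),
#'   `health` (`animal_id`, `date`, `locomotion_score`), `meta`
#'   ([cohort_meta()] table), `scenario`.
#' @export
simulate_cohort <- function(scenario, sensitivity = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  pm <- pig_multipliers(scenario)
  animal_ids <- sprintf("pig%03d", seq_len(scenario$n_pigs))
  pen_ids <- scenario$pens[((seq_len(scenario$n_pigs) - 1L) %%
                              length(scenario$pens)) + 1L]
  origin <- as.POSIXct(paste0(format(scenario$start_date), " 00:00:00"),
                       tz = "UTC")
  acc_ts <- vector("list", scenario$n_pigs * scenario$n_days)
  acc_loc <- vector("list", length(acc_ts))
  acc_n <- integer(length(acc_ts))
  truth <- vector("list", length(acc_ts))
  k <- 0L
  for (pig in seq_len(scenario$n_pigs)) {
    for (day in seq_len(scenario$n_days)) {
      k <- k + 1L
      sim <- simulate_day(scenario, pig, day, pig_mult = pm)
      det <- apply_detection(sim$visits, scenario, pig, day,
                             sensitivity = sensitivity)
      acc_ts[[k]] <- (day - 1L) * 86400 + det$sec
      acc_loc[[k]] <- det$location_id
      acc_n[k] <- nrow(det)
      truth[[k]] <- list(pig = pig, day = day, truth_m = sim$truth_m,
                         n_visits = sim$n_visits)
    }
  }
  idx <- rep.int(seq_len(scenario$n_pigs),
                 rep(scenario$n_days, scenario$n_pigs))  # pig of each k
  readings <- data.table::data.table(
    animal_id = rep(animal_ids[idx], acc_n),
    timestamp = origin + unlist(acc_ts),
    location_id = unlist(acc_loc),
    pen_id = rep(pen_ids[idx], acc_n))
  data.table::setorder(readings, animal_id, timestamp, location_id)
  gt <- data.table::rbindlist(truth)
  gt <- data.table::data.table(
    animal_id = animal_ids[gt$pig], pen_id = pen_ids[gt$pig],
    day_index = gt$day,
    date = scenario$start_date + gt$day - 1L,
    truth_m = gt$truth_m, n_visits = gt$n_visits)
  data.table::setorder(gt, animal_id, date)
  health <- sim_health(scenario, animal_ids)
  meta <- cohort_meta(unique(pen_ids),
                      rep(scenario$start_date, length(unique(pen_ids))))
  list(readings = readings, ground_truth = gt, health = health,
       meta = meta, scenario = scenario)
}

# twice-weekly inspections on fattening days 1, 4, 8, 11, ...
sim_health <- function(scenario, animal_ids) {
  obs_days <- sort(unique(c(
    seq.int(1L, scenario$n_days, by = 7L),
    if (scenario$n_days >= 4L) seq.int(4L, scenario$n_days, by = 7L))))
  rows <- data.table::CJ(pig = seq_len(scenario$n_pigs), day = obs_days)
  rows[, locomotion_score := 0L]
  lm <- scenario$lameness
  if (!is.null(lm) && nrow(lm)) {
    for (i in seq_len(nrow(lm))) {
      on <- lm$onset_day[i]; dur <- lm$duration[i]
      active <- rows$pig == lm$pig[i] & rows$day >= on & rows$day < on + dur
      first_half <- rows$day < on + ceiling(dur / 2)
      rows[active & first_half, locomotion_score := pmax(locomotion_score, 2L)]
      rows[active & !first_half, locomotion_score := pmax(locomotion_score, 1L)]
    }
  }
  out <- data.table::data.table(
    animal_id = animal_ids[rows$pig],
    date = scenario$start_date + rows$day - 1L,
    locomotion_score = rows$locomotion_score)
  data.table::setorder(out, animal_id, date)
  out[]
}

#' Write a simulated cohort to disk
#'
#' Writes `readings.csv`, `ground_truth.csv`, `health.csv`, `cohort_meta.csv`
#' and `scenario.json` (scenario parameters, layout as a distance-matrix
#' block) into `dir`, in the same CSV dialect the pipeline readers consume.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
sim_write <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(readings = file.path(dir, "readings.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"),
             health = file.path(dir, "health.csv"),
             meta = file.path(dir, "cohort_meta.csv"),
             scenario = file.path(dir, "scenario.json"))
  write_table(cohort$readings, paths["readings"])
  write_table(cohort$ground_truth, paths["ground_truth"])
  write_table(cohort$health, paths["health"])
  write_table(cohort$meta, paths["meta"])
  sc <- cohort$scenario
  sc_json <- sc[setdiff(names(sc), "layout")]
  sc_json$start_date <- format(sc$start_date)
  sc_json$layout <- list(distance_matrix = list(
    ids = sc$layout$locations,
    meters = unname(as.matrix(sc$layout$dist))))
  jsonlite::write_json(sc_json, paths["scenario"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
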