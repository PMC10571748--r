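# Cohort summary layers over the daily/hourly VWD tables: fattening-stage
# means (per pig-day and per pig), per-pig summaries, hour-of-day profiles,
# and the locomotion-score overlay used to inspect lameness episodes.

stage_labels <- function(breaks) {
  breaks <- as.integer(breaks)
  if (length(breaks) < 1L || any(breaks < 1L) || is.unsorted(breaks, strictly = TRUE)) {
    stop("stage breaks must be strictly increasing positive integers", call. = FALSE)
  }
  lo <- c(1L, breaks + 1L)
  hi <- breaks
  c(sprintf("d%d_%d", utils::head(lo, -1L), hi),
    sprintf("d_gt%d", breaks[length(breaks)]))
}

#' Map a fattening day to its fattening stage
#'
#' Fattening periods are binned into stages for analysis; with the default
#' breaks the stages are days 1--30, 31--60, 61--90 and >90 (labels
#' `d1_30`, `d31_60`, `d61_90`, `d_gt90`). Stages are closed on both ends:
#' day 30 is in the first stage, day 31 in the second.
#'
#' @param fattening_day Integer vector, all values >= 1.
#' @param breaks Strictly increasing positive integers; upper bounds of all
#'   stages but the open-ended last one. Default `c(30, 60, 90)`.
#' @return A factor with one level per stage, in stage order.
#' @examples
#' assign_stage(c(30, 31, 91))
#' @export
assign_stage <- function(fattening_day, breaks = c(30L, 60L, 90L)) {
  labs <- stage_labels(breaks)
  fattening_day <- as.integer(fattening_day)
  if (anyNA(fattening_day) || any(fattening_day < 1L)) {
    stop("fattening_day must be an integer >= 1", call. = FALSE)
  }
  idx <- findInterval(fattening_day, c(1L, as.integer(breaks) + 1L))
  factor(labs[idx], levels = labs)
}

#' Fattening-stage mean VWD, per pig-day or per pig
#'
#' Two descriptive variants of the stage means. `all_days`: the mean over
#' every observed pig-day in the stage (`n` counts pig-days). `per_pig_means`:
#' each pig's days in the stage are first averaged, then the per-pig means are
#' averaged (`n` counts pigs). The variants coincide exactly when every pig
#' contributes the same number of days to a stage and diverge toward the
#' over-represented pigs otherwise. Pigs or days with no data in a stage are
#' excluded from that stage's `n` (missing is not zero).
#'
#' @param daily A daily VWD table from [compute_vwd()].
#' @param variant `"all_days"` or `"per_pig_means"`.
#' @param breaks Stage breaks, as in [assign_stage()].
#' @return A `data.table` with one row per stage: `stage`, `variant`,
#'   `mean_vwd_m` (`NA` where `n = 0`), `n`.
#' @export
stage_means <- function(daily, variant = c("all_days", "per_pig_means"),
                        breaks = c(30L, 60L, 90L)) {
  variant <- match.arg(variant)
  daily <- data.table::as.data.table(daily)
  require_columns(daily, c("animal_id", "fattening_day", "vwd_m"), "daily table")
  labs <- stage_labels(breaks)
  dd <- daily[!is.na(vwd_m)]
  dd[, stage := assign_stage(fattening_day, breaks)]
  if (variant == "all_days") {
    agg <- dd[, .(mean_vwd_m = mean(vwd_m), n = .N), by = stage]
  } else {
    per_pig <- dd[, .(mean_vwd_m = mean(vwd_m)), by = .(animal_id, stage)]
    agg <- per_pig[, .(mean_vwd_m = mean(mean_vwd_m), n = .N), by = stage]
  }
  out <- data.table::data.table(stage = factor(labs, levels = labs))
  out <- agg[out, on = "stage"]
  out[is.na(n), n := 0L]
  out[, variant := variant]
  out[, .(stage, variant, mean_vwd_m, n)][]
}

#' Per-pig VWD summaries
#'
#' One row per animal: mean, minimum and maximum daily VWD, the number of
#' observed days, and the per-stage mean (`NA` for stages without data).
#'
#' @inheritParams stage_means
#' @return A `data.table` sorted by `animal_id` with columns `animal_id`,
#'   `mean_vwd_m`, `min_vwd_m`, `max_vwd_m`, `days_observed`, then one
#'   `mean_<stage>` column per stage.
#' @export
pig_summaries <- function(daily, breaks = c(30L, 60L, 90L)) {
  daily <- data.table::as.data.table(daily)
  require_columns(daily, c("animal_id", "fattening_day", "vwd_m"), "daily table")
  if (!nrow(daily)) stop("daily table is empty", call. = FALSE)
  labs <- stage_labels(breaks)
  dd <- daily[!is.na(vwd_m)]
  out <- dd[, .(mean_vwd_m = mean(vwd_m), min_vwd_m = min(vwd_m),
                max_vwd_m = max(vwd_m), days_observed = .N),
            by = animal_id]
  dd[, stage := assign_stage(fattening_day, breaks)]
  per_stage <- dd[, .(m = mean(vwd_m)), by = .(animal_id, stage)]
  for (s in labs) {
    col <- paste0("mean_", s)
    sub <- per_stage[stage == s, .(animal_id, m)]
    out <- sub[out, on = "animal_id"]
    data.table::setnames(out, "m", col)
  }
  data.table::setcolorder(out, c("animal_id", "mean_vwd_m", "min_vwd_m",
                                 "max_vwd_m", "days_observed",
                                 paste0("mean_", labs)))
  data.table::setorder(out, animal_id)
  out[]
}

#' Hour-of-day activity profile, per stage and overall
#'
#' For each fattening stage (and pooled over all stages, labelled
#' `"overall"`), the mean over all pig-days of the distance walked in each
#' hour bin. Bin `h00` covers midnight to 1 a.m. Only observed pig-days
#' enter the means; a row's 24 bins sum to the mean daily VWD of the
#' pig-days it covers.
#'
#' @param hourly A wide hourly table from [compute_vwd()].
#' @param daily The matching daily table (provides `fattening_day`); the two
#'   tables must cover exactly the same (animal, date) pairs.
#' @param breaks Stage breaks, as in [assign_stage()].
#' @return A `data.table` with columns `stage` (stage labels plus
#'   `"overall"`), `n_days` (pig-days averaged) and `h00` ... `h23`.
#' @export
hourly_profile <- function(hourly, daily, breaks = c(30L, 60L, 90L)) {
  hourly <- data.table::as.data.table(hourly)
  daily <- data.table::as.data.table(daily)
  hcols <- sprintf("h%02d", 0:23)
  require_columns(hourly, c("animal_id", "date", hcols), "hourly table")
  require_columns(daily, c("animal_id", "date", "fattening_day"), "daily table")
  keyed <- daily[, .(animal_id, date, fattening_day)]
  joined <- keyed[hourly, on = c("animal_id", "date")]
  if (nrow(joined) != nrow(daily) || anyNA(joined$fattening_day)) {
    stop("hourly and daily tables cover different animal-days", call. = FALSE)
  }
  joined[, stage := assign_stage(fattening_day, breaks)]
  by_stage <- joined[, c(list(n_days = .N), lapply(.SD, mean)),
                     by = stage, .SDcols = hcols]
  overall <- joined[, c(list(stage = factor("overall"), n_days = .N),
                        lapply(.SD, mean)), .SDcols = hcols]
  out <- rbind(by_stage, overall)
  out[, stage := as.character(stage)]
  data.table::setcolorder(out, c("stage", "n_days", hcols))
  out[]
}

#' Overlay locomotion scores on per-pig daily VWD series
#'
#' Left-joins health observations onto the daily table by (animal, date).
#' Scores are attached only on their observation dates — no imputation or
#' carry-forward between twice-weekly inspections. Health rows that match no
#' observed pig-day (unknown animal, or a date without readings) are counted,
#' reported on stderr and attached as the `"unmatched_health"` attribute.
#'
#' @param daily A daily VWD table from [compute_vwd()].
#' @param health Health records from [read_health()].
#' @return The daily table with an added integer `locomotion_score` column
#'   (`NA` on days without an observation), sorted by (animal, date).
#' @export
overlay_health <- function(daily, health) {
  daily <- data.table::as.data.table(daily)
  health <- data.table::as.data.table(health)
  require_columns(daily, c("animal_id", "date", "vwd_m"), "daily table")
  out <- data.table::copy(daily)
  if (!nrow(health)) {
    out[, locomotion_score := NA_integer_]
  } else {
    require_columns(health, c("animal_id", "date", "locomotion_score"),
                    "health table")
    h <- health[, .(animal_id, date, locomotion_score)]
    matched <- out[h, on = c("animal_id", "date"), which = TRUE]
    n_unmatched <- sum(is.na(matched))
    if (n_unmatched) {
      message(sprintf(
        "overlay_health: %d health row(s) match no observed pig-day; excluded",
        n_unmatched))
    }
    out <- h[out, on = c("animal_id", "date")]
    data.table::setattr(out, "unmatched_health", n_unmatched)
    data.table::setcolorder(out, c(setdiff(names(out), "locomotion_score"),
                                   "locomotion_score"))
  }
  data.table::setorder(out, animal_id, date)
  out[]
}
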