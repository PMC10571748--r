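test_that("scenario validation enforces parameter ranges", {
  expect_error(sim_scenario(sensitivity = c(trough = 1.5, drinker1 = 0.6,
                                            drinker2 = 0.6, drinker3 = 0.6,
                                            playing_device = 0.75)),
               "\\[0, 1\\]")
  expect_error(sim_scenario(feeding_hours = c(6, 25)), "\\[0, 24\\)")
  expect_error(sim_scenario(stage_multipliers = c(1, 0.8)), "per stage")
  expect_error(sim_scenario(dwell_mean_s = c(trough = 0, drinker1 = 10,
                                             drinker2 = 10, drinker3 = 10,
                                             playing_device = 15)),
               "positive")
  expect_s3_class(sim_scenario(n_pigs = 2, n_days = 3), "sim_scenario")
})

test_that("diurnal intensity encodes feeding bumps, afternoon rise and rest", {
  sc <- sim_scenario(n_pigs = 1, n_days = 1)
  r <- diurnal_weights(sc)
  expect_length(r, 24)
  expect_true(all(r[c(23, 24, 1:6)] < min(r[8:22])))      # rest window lowest
  expect_gt(r[7], r[8])                                   # 6 a.m. feeding bump
  expect_gt(r[19], r[17])                                 # feeding on top of afternoon rise
})

test_that("day trajectories are reproducible, diurnal and start/end in rest", {
  sc <- sim_scenario(n_pigs = 3, n_days = 5, seed = 99)
  a <- simulate_day(sc, 2, 3)
  b <- simulate_day(sc, 2, 3)
  expect_identical(a, b)                                  # bit-identical replay
  expect_true(all(a$visits$exit_s > a$visits$entry_s))
  expect_true(all(a$visits$entry_s >= 0 & a$visits$exit_s <= 86400))
  # non-overlap: the pig is in at most one reading area at a time
  expect_true(all(diff(a$visits$entry_s) >= 0))
  expect_true(all(utils::head(a$visits$exit_s, -1) <= a$visits$entry_s[-1]))

  # zero rest-phase intensity: no visits between 22:00 and 06:00
  sc0 <- sim_scenario(n_pigs = 2, n_days = 2, rest_suppression = 0, seed = 5)
  v <- simulate_day(sc0, 1, 1)$visits
  hrs <- floor(v$entry_s / 3600)
  expect_false(any(hrs %in% c(22, 23, 0:5)))

  # zero stage multiplier: empty day, zero truth
  scz <- sim_scenario(n_pigs = 1, n_days = 1,
                      stage_multipliers = c(0, 0, 0, 0), seed = 5)
  z <- simulate_day(scz, 1, 1)
  expect_identical(z$n_visits, 0L)
  expect_identical(z$truth_m, 0)
})

test_that("detection thins visit-seconds at the location's sensitivity", {
  sc <- sim_scenario(n_pigs = 1, n_days = 1, seed = 7)
  visits <- data.table::data.table(location_id = "trough",
                                   entry_s = 1000L, exit_s = 1010L)
  full <- apply_detection(visits, sc, 1, 1,
                          sensitivity = c(trough = 1))
  expect_identical(nrow(full), 10L)                       # one reading per second
  expect_identical(full$sec, 1000:1009)

  none <- apply_detection(visits, sc, 1, 1, sensitivity = c(trough = 0))
  expect_identical(nrow(none), 0L)

  # 10,000 visit-seconds at 0.6: detected fraction inside binomial 99% CI
  long <- data.table::data.table(location_id = "drinker1",
                                 entry_s = 0L, exit_s = 10000L)
  det <- apply_detection(long, sc, 1, 1, sensitivity = c(drinker1 = 0.6))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.6)
  expect_gte(nrow(det), ci[1])
  expect_lte(nrow(det), ci[2])

  expect_error(apply_detection(long, sc, 1, 1, sensitivity = c(trough = 1)),
               "drinker1")
})

test_that("lowering sensitivity only removes readings (coupled substreams)", {
  sc <- sim_scenario(n_pigs = 2, n_days = 2, seed = 31)
  v <- simulate_day(sc, 1, 1)$visits
  hi <- apply_detection(v, sc, 1, 1,
                        sensitivity = c(trough = 0.9, drinker1 = 0.9,
                                        drinker2 = 0.9, drinker3 = 0.9,
                                        playing_device = 0.9))
  lo <- apply_detection(v, sc, 1, 1,
                        sensitivity = c(trough = 0.5, drinker1 = 0.5,
                                        drinker2 = 0.5, drinker3 = 0.5,
                                        playing_device = 0.5))
  expect_true(all(paste(lo$sec, lo$location_id) %in%
                    paste(hi$sec, hi$location_id)))
})

test_that("simulated cohorts run the whole pipeline and respect the
           ground-truth lower bound", {
  sc <- sim_scenario(n_pigs = 6, n_days = 12, seed = 12)
  co <- simulate_cohort(sc)
  expect_identical(nrow(co$ground_truth), 6L * 12L)
  res <- compute_vwd(co$readings, sc$layout, co$meta)
  expect_identical(length(unique(res$daily$animal_id)), 6L)
  expect_identical(nrow(pig_summaries(res$daily)), 6L)

  j <- merge(res$daily, co$ground_truth, by = c("animal_id", "date"))
  expect_identical(nrow(j), nrow(res$daily))
  expect_true(all(j$vwd_m <= j$truth_m + 1e-9))
})

test_that("lameness events shape health records and activity", {
  lame <- data.frame(pig = 2, onset_day = 10, factor = 0.3, duration = 10)
  sc <- sim_scenario(n_pigs = 3, n_days = 25, lameness = lame, seed = 4)
  co <- simulate_cohort(sc)
  h <- co$health
  expect_true(all(h$locomotion_score %in% 0:3))
  # twice-weekly inspection dates: days 1, 4, 8, 11, ...
  obs_days <- sort(unique(as.integer(h$date - sc$start_date) + 1L))
  expect_identical(obs_days,
                   as.integer(sort(unique(c(seq(1, 25, 7), seq(4, 25, 7))))))
  in_event <- h$animal_id == "pig002" &
    h$date >= sc$start_date + 9 & h$date < sc$start_date + 19
  expect_true(all(h$locomotion_score[in_event] >= 1L))
  expect_true(all(h$locomotion_score[!in_event] == 0L))

  # the lame pig's visit rate drops by roughly the lameness factor
  pm <- pig_multipliers(sc)
  before <- simulate_day(sc, 2, 9, pm)$n_visits
  during <- mean(vapply(10:14, function(d) simulate_day(sc, 2, d, pm)$n_visits,
                        numeric(1)))
  expect_lt(during, before)
})

test_that("cohort files round-trip through the pipeline readers", {
  sc <- sim_scenario(n_pigs = 2, n_days = 3, seed = 8)
  co <- simulate_cohort(sc)
  dir <- file.path(tempdir(), "simcheck")
  paths <- sim_write(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_readings(paths[["readings"]], sc$layout)
  expect_identical(nrow(back), nrow(co$readings))
  expect_equal(back$timestamp, co$readings$timestamp)
  h <- read_health(paths[["health"]])
  expect_identical(nrow(h), nrow(co$health))
  m <- read_cohort_meta(paths[["meta"]])
  expect_identical(m$start_date, sc$start_date)
})
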