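test_that("same-location runs collapse to distinct visits", {
  ts <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC") + 0:5
  v <- collapse_runs(c("T", "T", "T", "P", "P", "T"), ts)
  expect_identical(v$location_id, c("T", "P", "T"))
  expect_identical(v$n, c(3L, 2L, 1L))
  expect_identical(v$t_first[1], ts[1])
  expect_identical(v$t_last[1], ts[3])
  expect_identical(v$t_first[3], ts[6])

  empty <- collapse_runs(character(), as.POSIXct(character(), tz = "UTC"))
  expect_identical(nrow(empty), 0L)
})

test_that("daily VWD reproduces hand-computed days", {
  lay <- table2_layout()
  # the minimal observed day: trough -> playing device -> trough = 10.4 m
  d <- daily_vwd(readings_from_seq(c("trough", "playing_device", "trough")), lay)
  expect_equal(d$vwd_m, 10.4)
  expect_identical(d$n_transitions, 2L)

  # manual sum of published entries: 7.0 + 1.6
  d2 <- daily_vwd(readings_from_seq(c("trough", "drinker1", "drinker2")), lay)
  expect_equal(d2$vwd_m, 8.6)

  # one reading: zero distance, zero transitions, but an observed day
  d3 <- daily_vwd(readings_from_seq("trough"), lay)
  expect_equal(d3$vwd_m, 0)
  expect_identical(d3$n_transitions, 0L)
  expect_identical(d3$n_readings, 1L)

  # no readings: missing, not zero
  d4 <- daily_vwd(readings_from_seq(character()), lay)
  expect_identical(d4$n_readings, 0L)
  expect_true(is.na(d4$vwd_m))

  expect_error(daily_vwd(readings_from_seq("nowhere"), lay), "nowhere")
  two_dates <- rbind(readings_from_seq("trough", date = "2024-03-01"),
                     readings_from_seq("trough", date = "2024-03-02"))
  expect_error(daily_vwd(two_dates, lay), "more than one calendar date")
})

test_that("daily VWD equals the brute-force pairwise oracle on random days", {
  lay <- table2_layout()
  set.seed(101)
  for (i in 1:200) {
    n <- sample(0:200, 1)
    locs <- sample(lay$locations, n, replace = TRUE)
    d <- daily_vwd(readings_from_seq(locs), lay)
    if (n == 0) {
      expect_true(is.na(d$vwd_m))
    } else {
      expect_identical(d$vwd_m, vwd_bruteforce(locs, lay$dist))
      expect_lte(d$n_transitions, max(n - 1L, 0L))
    }
  }
})

test_that("VWD is nonnegative, zero iff one distinct location, and
           reversal-invariant", {
  lay <- table2_layout()
  set.seed(202)
  for (i in 1:100) {
    locs <- sample(lay$locations, sample(1:60, 1), replace = TRUE)
    v <- daily_vwd(readings_from_seq(locs), lay)$vwd_m
    expect_gte(v, 0)
    expect_identical(v == 0, length(unique(locs)) == 1L)
    vr <- daily_vwd(readings_from_seq(rev(locs)), lay)$vwd_m
    expect_equal(vr, v, tolerance = 1e-12)
  }
})

test_that("order-preserving subsampling never increases VWD", {
  lay <- table2_layout()
  expect_identical(nrow(validate_distance_matrix(lay$dist)), 0L)
  set.seed(303)
  for (i in 1:200) {
    n <- sample(2:120, 1)
    locs <- sample(lay$locations, n, replace = TRUE)
    keep <- sort(sample(n, sample(1:n, 1)))
    full <- daily_vwd(readings_from_seq(locs), lay)$vwd_m
    sub <- daily_vwd(readings_from_seq(locs[keep], start_s = 10), lay)$vwd_m
    expect_lte(sub, full + 1e-9)
  }
})

test_that("hourly bins receive transitions by arrival hour and conserve the
           daily total", {
  lay <- table2_layout()
  origin <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  rd <- data.frame(
    animal_id = "pigA",
    timestamp = origin + c(7 * 3600, 8 * 3600 + 600, 20 * 3600 + 1800),
    location_id = c("trough", "playing_device", "trough"),
    pen_id = "pen1")
  h <- hourly_vwd(rd, lay)
  expect_equal(unname(h["h08"]), 5.2)
  expect_equal(unname(h["h20"]), 5.2)
  expect_equal(sum(h), daily_vwd(rd, lay)$vwd_m)
  expect_equal(sum(h != 0), 2)

  # a day without transitions is 24 zeros
  expect_identical(unname(hourly_vwd(readings_from_seq("trough"), lay)),
                   rep(0, 24))

  set.seed(404)
  for (i in 1:50) {
    locs <- sample(lay$locations, sample(2:300, 1), replace = TRUE)
    rd <- readings_from_seq(locs, start_s = sample(0:80000, 1))
    rd <- rd[rd$timestamp < as.POSIXct("2024-03-02", tz = "UTC"), ]
    expect_equal(sum(hourly_vwd(rd, lay)), daily_vwd(rd, lay)$vwd_m,
                 tolerance = 1e-12)
  }
})

test_that("compute_vwd builds one row per observed animal-day", {
  lay <- table2_layout()
  rows <- rbind(
    readings_from_seq(c("trough", "drinker1"), "2024-03-01", "pigA"),
    readings_from_seq(c("trough", "playing_device"), "2024-03-02", "pigA"),
    readings_from_seq("drinker2", "2024-03-03", "pigA"),
    readings_from_seq(c("drinker1", "drinker2"), "2024-03-01", "pigB"),
    readings_from_seq("trough", "2024-03-02", "pigB"),
    readings_from_seq(c("trough", "drinker3"), "2024-03-03", "pigB"))
  meta <- cohort_meta("pen1", as.Date("2024-03-01"))
  res <- compute_vwd(read_readings(write_readings_csv(rows), lay), lay, meta)
  expect_identical(nrow(res$daily), 6L)
  expect_identical(res$daily$fattening_day, rep(1:3, 2))
  expect_identical(nrow(res$hourly), 6L)

  # a reading-free day in the middle stays absent, not zero
  gap <- rbind(readings_from_seq("trough", "2024-03-01"),
               readings_from_seq("trough", "2024-03-03"))
  res2 <- compute_vwd(read_readings(write_readings_csv(gap), lay), lay, meta)
  expect_identical(nrow(res2$daily), 2L)
  expect_false(as.Date("2024-03-02") %in% res2$daily$date)

  # unknown pen is an error
  expect_error(
    compute_vwd(read_readings(write_readings_csv(rows), lay), lay,
                cohort_meta("pen9", as.Date("2024-03-01"))),
    "pen")
})

test_that("compute_vwd agrees with the per-day functions and never bridges
           midnight", {
  lay <- table2_layout()
  set.seed(505)
  rows <- do.call(rbind, lapply(1:3, function(p) {
    do.call(rbind, lapply(1:4, function(d) {
      locs <- sample(lay$locations, sample(1:80, 1), replace = TRUE)
      readings_from_seq(locs, sprintf("2024-03-%02d", d), paste0("pig", p),
                        start_s = sample(0:80000, 1))
    }))
  }))
  rows <- rows[format(rows$timestamp, "%d", tz = "UTC") %in%
                 sprintf("%02d", 1:4), ]
  meta <- cohort_meta("pen1", as.Date("2024-03-01"))
  rs <- read_readings(write_readings_csv(rows), lay)
  res <- compute_vwd(rs, lay, meta)
  for (i in seq_len(nrow(res$daily))) {
    one <- rs[rs$animal_id == res$daily$animal_id[i] &
                as.Date(rs$timestamp, tz = "UTC") == res$daily$date[i], ]
    expect_equal(res$daily$vwd_m[i], daily_vwd(one, lay)$vwd_m)
    hb <- as.numeric(res$hourly[i, sprintf("h%02d", 0:23), with = FALSE])
    expect_equal(hb, unname(hourly_vwd(one, lay)), tolerance = 1e-12)
  }
  # explicit two-day stream: day 2 opens a new path, so ending day 1 at the
  # trough and opening day 2 at drinker1 adds no 7.0 m bridge
  two <- rbind(readings_from_seq(c("drinker1", "trough"), "2024-04-01"),
               readings_from_seq(c("drinker1", "trough"), "2024-04-02"))
  meta2 <- cohort_meta("pen1", as.Date("2024-04-01"))
  r2 <- compute_vwd(read_readings(write_readings_csv(two), lay), lay, meta2)
  expect_equal(r2$daily$vwd_m, c(7.0, 7.0))
})
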