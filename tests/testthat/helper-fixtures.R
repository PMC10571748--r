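# Shared fixtures and independent oracles, built in code at test time.

# the published five-location matrix, restated by hand as the reference
table2_matrix <- function() {
  locs <- c("trough", "drinker1", "drinker2", "drinker3", "playing_device")
  m <- matrix(0, 5, 5, dimnames = list(locs, locs))
  m["trough", "drinker1"] <- 7.0
  m["trough", "drinker2"] <- 7.5
  m["trough", "drinker3"] <- 7.3
  m["trough", "playing_device"] <- 5.2
  m["drinker1", "drinker2"] <- 1.6
  m["drinker1", "drinker3"] <- 2.7
  m["drinker1", "playing_device"] <- 3.0
  m["drinker2", "drinker3"] <- 1.3
  m["drinker2", "playing_device"] <- 2.6
  m["drinker3", "playing_device"] <- 2.1
  m + t(m)
}

# independent brute-force oracle: pairwise sum over the RAW (uncollapsed)
# location sequence, no run collapsing
vwd_bruteforce <- function(locs, m) {
  if (length(locs) < 2L) return(0)
  sum(m[cbind(locs[-length(locs)], locs[-1L])])
}

# one animal-day of readings from a bare location sequence, 1 s apart
readings_from_seq <- function(locs, date = "2024-03-01", animal = "pigA",
                              pen = "pen1", start_s = 8 * 3600) {
  origin <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(animal_id = rep(animal, length(locs)),
             timestamp = origin + start_s + seq_along(locs) - 1,
             location_id = locs,
             pen_id = rep(pen, length(locs)),
             stringsAsFactors = FALSE)
}

write_readings_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write_table(rows, path)
  path
}

tiny_layout <- function() {
  pen_layout(coords = list(A = c(0, 0), B = c(3, 4), C = c(6, 0)))
}
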