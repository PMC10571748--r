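Package: penwalk
Title: Virtual Walking Distances for RFID-Tagged Pen-Housed Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the virtual walking distance (VWD) activity measure for
    individually RFID-tagged, group-housed fattening pigs from raw per-second
    antenna reading streams. The VWD of an animal-day is the sum of
    center-to-center Euclidean distances between consecutively visited antenna
    reading areas, a lower-bound proxy for the distance actually walked.
    Provides readers for reading streams, pen layouts and locomotion-score
    health records; distance-matrix construction and validation; daily and
    hourly VWD computation; fattening-stage, per-pig and hour-of-day
    aggregation with health-record overlay; and a stochastic barn simulator
    (semi-Markov visit model with diurnal feeding structure, nocturnal rest,
    per-antenna detection sensitivity and optional lameness events) that
    produces reading streams with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
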