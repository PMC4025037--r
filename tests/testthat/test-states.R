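test_that("blood-pressure staging follows the most-severe-component rule", {
  expect_identical(classify_blood_pressure(165, 85), "BP_H2")
  expect_identical(classify_blood_pressure(110, 70), "N")
  # diastolic stage 1 dominates systolic prehypertension
  expect_identical(classify_blood_pressure(125, 92), "BP_H1")
  expect_error(classify_blood_pressure(-5, 80), "positive")
  expect_error(classify_blood_pressure(Inf, 80), "positive")

  # oracle: classify each component against its own bands, take max severity
  grid <- expand.grid(sys = 80:180, dia = 50:120)
  comp_rank <- function(x, bands) {
    r <- integer(length(x))
    r[x >= bands[1]] <- 1L; r[x >= bands[2]] <- 2L; r[x >= bands[3]] <- 3L
    r
  }
  expected <- c("N", "BP_HB", "BP_H1", "BP_H2")[
    pmax(comp_rank(grid$sys, c(120, 140, 160)),
         comp_rank(grid$dia, c(80, 90, 100))) + 1L]
  expect_identical(classify_blood_pressure(grid$sys, grid$dia), expected)
})

test_that("oxygen bands resolve most-severe-first with half-open bounds", {
  expect_identical(classify_oxygen(c(93, 100, 74.9)),
                   c("SpO2_Lmicro", "N", "SpO2_Lhard"))
  expect_identical(classify_oxygen(c(94, 89, 88.99, 75)),
                   c("N", "SpO2_Lmicro", "SpO2_Lmid", "SpO2_Lmid"))
  expect_error(classify_oxygen(101), "\\[0, 100\\]")
  expect_error(classify_oxygen(-1), "\\[0, 100\\]")
})

test_that("heart-rate thresholds are strict", {
  expect_identical(classify_heart_rate(c(101, 100, 60, 59)),
                   c("Pulse_H", "N", "N", "Pulse_L"))
  expect_error(classify_heart_rate(0), "positive")
})

test_that("severity is monotone in the driving vital", {
  sys <- seq(90, 180, by = 1)
  rank <- match(classify_blood_pressure(sys, 70),
                c("N", "BP_HB", "BP_H1", "BP_H2"))
  expect_true(all(diff(rank) >= 0))
  spo2 <- seq(100, 50, by = -0.5)
  orank <- match(classify_oxygen(spo2),
                 c("N", "SpO2_Lmicro", "SpO2_Lmid", "SpO2_Lhard"))
  expect_true(all(diff(orank) >= 0))
})

test_that("discretization bins, classifies jointly and drops normals", {
  s <- data.frame(subject = "p", timestamp = c(0, 0, 0),
                  signal = c("HR", "SYS_BP", "DIA_BP"),
                  value = c(120, 130, 85))
  seq <- discretize_stream(s, tick_width = 60)
  expect_identical(seq$tick, 1L)
  expect_identical(seq$events[[1]], c("BP_HB", "Pulse_H"))

  empty <- discretize_stream(s[0, ], tick_width = 60)
  expect_identical(length(empty), 0L)

  norm <- data.frame(subject = "p", timestamp = 0, signal = "HR", value = 80)
  expect_identical(length(discretize_stream(norm)), 0L)
  with_n <- discretize_stream(norm, include_normal = TRUE)
  expect_identical(with_n$events[[1]], "N")
})

test_that("within a tick the last sample of a signal wins", {
  s <- data.frame(subject = "p", timestamp = c(0, 30, 59),
                  signal = "HR", value = c(120, 80, 55))
  seq <- discretize_stream(s, tick_width = 60)
  expect_identical(seq$events[[1]], "Pulse_L")
})

test_that("discretization is invariant to input row order", {
  set.seed(7)
  sig <- sample(c("HR", "SYS_BP", "DIA_BP", "SPO2"), 40, replace = TRUE)
  s <- data.frame(subject = "p",
                  timestamp = sample(0:599, 40, replace = TRUE),
                  signal = sig,
                  value = ifelse(sig == "SPO2", stats::runif(40, 70, 100),
                                 stats::runif(40, 40, 170)))
  a <- discretize_stream(s, tick_width = 60, include_normal = TRUE)
  b <- discretize_stream(s[order(s$value), ], tick_width = 60,
                         include_normal = TRUE)
  expect_identical(a$tick, b$tick)
  # ties inside a (tick, signal) pair may legitimately resolve by row order;
  # with distinct timestamps per pair the sequences must be identical
  s2 <- s[!duplicated(paste(floor(s$timestamp / 60), s$signal)), ]
  a2 <- discretize_stream(s2, include_normal = TRUE)
  b2 <- discretize_stream(s2[rev(seq_len(nrow(s2))), ], include_normal = TRUE)
  expect_identical(a2, b2)
})

test_that("mixed subjects and malformed inputs are rejected", {
  s <- data.frame(subject = c("a", "b"), timestamp = 0:1,
                  signal = "HR", value = 80)
  expect_error(discretize_stream(s), "single subject")
  bad <- data.frame(subject = "a", timestamp = 0, signal = "ECG", value = 1)
  expect_error(discretize_stream(bad), "unknown signal")
})

test_that("event sequences validate, round-trip JSON and restrict", {
  expect_error(event_sequence(c(2, 1), list("A", "B")), "increasing")
  expect_error(event_sequence(0, list("A")), "positive")
  s <- event_sequence(c(1, 3, 7), list(c("B", "A"), character(0), "C"))
  expect_identical(s$tick, c(1L, 7L))      # empty tick dropped
  expect_identical(s$events[[1]], c("A", "B"))

  path <- withr::local_tempfile(fileext = ".json")
  write_event_sequence(s, path)
  expect_identical(read_event_sequence(path), s)
  expect_identical(read_event_sequence(path)$tick,
                   window_sequence(s, 1, 7)$tick)
  expect_identical(window_sequence(s, 2, 7)$tick, 7L)
})

test_that("sample tables read from CSV and TSV with ISO timestamps", {
  df <- data.frame(subject = "p",
                   timestamp = c("1970-01-01T00:00:00", "1970-01-01T00:01:00"),
                   signal = c("HR", "HR"), value = c(120, 55))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, row.names = FALSE, sep = "\t")
  for (p in c(csv, tsv)) {
    seq <- discretize_stream(read_vital_samples(p), tick_width = 60)
    expect_identical(seq$tick, c(1L, 2L))
    expect_identical(seq$events, list("Pulse_H", "Pulse_L"))
  }
})
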