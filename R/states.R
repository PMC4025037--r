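#' Vital-sign state labels
#'
#' The nine discrete states a vital-sign measurement can map to: three
#' hypertension stages (`BP_HB` prehypertension, `BP_H1` stage 1, `BP_H2`
#' stage 2), three hypoxemia grades (`SpO2_Lmicro` mild, `SpO2_Lmid`
#' moderate, `SpO2_Lhard` severe), tachycardia (`Pulse_H`), bradycardia
#' (`Pulse_L`) and normal (`N`).
#'
#' @format A character vector of length 9.
#' @export
VITAL_STATES <- c("BP_HB", "BP_H1", "BP_H2",
                  "SpO2_Lmicro", "SpO2_Lmid", "SpO2_Lhard",
                  "Pulse_H", "Pulse_L", "N")

#' Recognised signal codes in raw sample tables
#' @keywords internal
VITAL_SIGNALS <- c("SYS_BP", "DIA_BP", "SPO2", "HR")

# severity ladders used by the classifiers; rank 0 is normal
.bp_labels <- c("N", "BP_HB", "BP_H1", "BP_H2")
.ox_labels <- c("N", "SpO2_Lmicro", "SpO2_Lmid", "SpO2_Lhard")

#' Classify a blood-pressure reading
#'
#' Maps a systolic/diastolic pair to a hypertension stage. The thresholds are
#' the standard staging bands: prehypertension 120-139 / 80-89 mmHg, stage 1
#' hypertension 140-159 / 90-99 mmHg, stage 2 hypertension >= 160 / >= 100
#' mmHg (range bounds inclusive). A reading is assigned the most severe stage
#' whose systolic *or* diastolic criterion it meets, so e.g. 125/92 is stage 1
#' even though the systolic value alone is only prehypertensive. Below all
#' thresholds the state is `"N"`.
#'
#' If one component is `NA` the other alone decides (monitoring streams do not
#' always carry both channels in a bin); both `NA` is an error.
#'
#' @param systolic systolic pressure, mmHg (finite, positive).
#' @param diastolic diastolic pressure, mmHg (finite, positive).
#' @return A character vector of state labels (`"N"`, `"BP_HB"`, `"BP_H1"`,
#'   `"BP_H2"`), recycled to the longer input.
#' @examples
#' classify_blood_pressure(165, 85)  # "BP_H2"
#' classify_blood_pressure(125, 92)  # "BP_H1"
#' classify_blood_pressure(110, 70)  # "N"
#' @seealso [classify_oxygen()], [classify_heart_rate()], [discretize_stream()]
#' @export
classify_blood_pressure <- function(systolic, diastolic) {
  n <- max(length(systolic), length(diastolic))
  systolic <- rep_len(as.numeric(systolic), n)
  diastolic <- rep_len(as.numeric(diastolic), n)
  if (any(is.na(systolic) & is.na(diastolic)))
    stop("blood pressure reading needs at least one of systolic/diastolic")
  bad <- function(x) !is.na(x) & (!is.finite(x) | x <= 0)
  if (any(bad(systolic)) || any(bad(diastolic)))
    stop("blood pressure values must be finite and positive")
  rank_sys <- ifelse(is.na(systolic), 0L,
              ifelse(systolic >= 160, 3L,
              ifelse(systolic >= 140, 2L,
              ifelse(systolic >= 120, 1L, 0L))))
  rank_dia <- ifelse(is.na(diastolic), 0L,
              ifelse(diastolic >= 100, 3L,
              ifelse(diastolic >= 90, 2L,
              ifelse(diastolic >= 80, 1L, 0L))))
  .bp_labels[pmax(rank_sys, rank_dia) + 1L]
}

#' Classify a pulse-oximetry reading
#'
#' Grades oxygen saturation into hypoxemia severities using overlapping
#' "below" thresholds resolved most-severe-first: SpO2 < 75% is severe
#' (`SpO2_Lhard`), 75-88.99% moderate (`SpO2_Lmid`), 89-93.99% mild
#' (`SpO2_Lmicro`), and >= 94% normal.
#'
#' @param spo2 oxygen saturation, percent, in \[0, 100\].
#' @return A character vector of state labels.
#' @examples
#' classify_oxygen(93)    # "SpO2_Lmicro"
#' classify_oxygen(74.9)  # "SpO2_Lhard"
#' @export
classify_oxygen <- function(spo2) {
  spo2 <- as.numeric(spo2)
  if (any(!is.finite(spo2) | spo2 < 0 | spo2 > 100))
    stop("SpO2 must lie in [0, 100]")
  ifelse(spo2 < 75, "SpO2_Lhard",
  ifelse(spo2 < 89, "SpO2_Lmid",
  ifelse(spo2 < 94, "SpO2_Lmicro", "N")))
}

#' Classify a heart-rate reading
#'
#' Strict thresholds: above 100 bpm is tachycardia (`Pulse_H`), below 60 bpm
#' bradycardia (`Pulse_L`); 60 and 100 themselves are normal.
#'
#' @param hr heart rate, beats per minute (finite, positive).
#' @return A character vector of state labels.
#' @examples
#' classify_heart_rate(c(101, 100, 59))
#' @export
classify_heart_rate <- function(hr) {
  hr <- as.numeric(hr)
  if (any(!is.finite(hr) | hr <= 0))
    stop("heart rate must be finite and positive")
  ifelse(hr > 100, "Pulse_H", ifelse(hr < 60, "Pulse_L", "N"))
}

#' Construct a complex event sequence
#'
#' A complex event sequence is an ordered series of integer time points
#' (ticks), each carrying a set of simultaneous state events. Ticks must be
#' strictly increasing; empty event sets are dropped (empty ticks are simply
#' absent from the sequence). Events within a tick are stored sorted and
#' de-duplicated.
#'
#' @param tick integer vector of 1-based time points, strictly increasing.
#' @param events list of character vectors, one per tick.
#' @param tick_width width of one tick in seconds (metadata only; default 60).
#' @return An object of class `event_sequence` with fields `tick` and
#'   `events`.
#' @examples
#' event_sequence(c(1, 2), list(c("Pulse_H", "BP_HB"), "BP_HB"))
#' @export
event_sequence <- function(tick, events, tick_width = 60) {
  tick <- as.integer(tick)
  if (length(tick) != length(events))
    stop("tick and events lengths differ")
  if (anyNA(tick) || any(tick < 1L))
    stop("ticks must be positive integers")
  if (is.unsorted(tick, strictly = TRUE))
    stop("ticks must be strictly increasing")
  events <- lapply(events, function(e) sort(unique(as.character(e))))
  keep <- lengths(events) > 0L
  structure(list(tick = tick[keep], events = events[keep]),
            tick_width = as.numeric(tick_width),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, max = 10L, ...) {
  n <- length(x$tick)
  cat(sprintf("Complex event sequence: %d occupied tick%s (tick width %gs)\n",
              n, if (n == 1L) "" else "s", attr(x, "tick_width")))
  show <- seq_len(min(n, max))
  for (i in show)
    cat(sprintf("  t=%d  {%s}\n", x$tick[i], paste(x$events[[i]], collapse = " ")))
  if (n > max) cat(sprintf("  ... %d more\n", n - max))
  invisible(x)
}

#' @export
as.data.frame.event_sequence <- function(x, ...) {
  data.frame(tick = rep(x$tick, lengths(x$events)),
             event = unlist(x$events, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' @export
length.event_sequence <- function(x) length(x$tick)

#' Restrict an event sequence to a tick interval
#'
#' @param x an `event_sequence`.
#' @param from,to inclusive tick bounds.
#' @return The restricted `event_sequence`.
#' @export
window_sequence <- function(x, from, to) {
  stopifnot(inherits(x, "event_sequence"))
  keep <- x$tick >= from & x$tick <= to
  event_sequence(x$tick[keep], x$events[keep],
                 tick_width = attr(x, "tick_width"))
}

.normalize_signal <- function(signal) {
  s <- toupper(trimws(as.character(signal)))
  s[s %in% c("SYS", "SBP", "SYSTOLIC")] <- "SYS_BP"
  s[s %in% c("DIA", "DBP", "DIASTOLIC")] <- "DIA_BP"
  s[s %in% c("SPO2", "SAO2", "OX")] <- "SPO2"
  s[s %in% c("HR", "PULSE", "HEART_RATE")] <- "HR"
  if (!all(s %in% VITAL_SIGNALS))
    stop("unknown signal code(s): ",
         paste(unique(s[!s %in% VITAL_SIGNALS]), collapse = ", "))
  s
}

.parse_timestamp <- function(ts) {
  if (is.numeric(ts)) return(as.numeric(ts))
  num <- suppressWarnings(as.numeric(ts))
  if (!anyNA(num)) return(num)
  parsed <- as.POSIXct(as.character(ts), tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
  as.numeric(parsed)
}

#' Discretize a vital-sign sample stream into a complex event sequence
#'
#' Bins timestamped measurements of one subject onto a discrete time axis
#' (tick = `floor(timestamp / tick_width) + 1`), classifies each signal in
#' each tick into a state label, and assembles the per-tick simultaneous
#' event sets. When several samples of the same signal fall into one tick the
#' latest one wins (monitoring semantics). Systolic and diastolic pressure
#' landing in the same tick are classified jointly.
#'
#' With `include_normal = FALSE` (the default) normal states are dropped and
#' ticks left with no abnormal event are omitted, so the sequence contains
#' only clinically notable states; set it to `TRUE` to keep `"N"` events.
#'
#' @param samples a data frame with columns `subject`, `timestamp` (numeric
#'   epoch seconds or ISO-8601 strings), `signal` (one of `SYS_BP`, `DIA_BP`,
#'   `SPO2`, `HR`, common aliases accepted) and `value`. All rows must belong
#'   to a single subject.
#' @param tick_width tick width in seconds (default 60).
#' @param include_normal keep `"N"` events? Default `FALSE`.
#' @return An [event_sequence()].
#' @examples
#' s <- data.frame(subject = "p1", timestamp = c(0, 0, 0),
#'                 signal = c("HR", "SYS_BP", "DIA_BP"),
#'                 value = c(120, 130, 85))
#' discretize_stream(s)  # tick 1: {BP_HB, Pulse_H}
#' @export
discretize_stream <- function(samples, tick_width = 60, include_normal = FALSE) {
  stopifnot(is.data.frame(samples), tick_width > 0)
  need <- c("subject", "timestamp", "signal", "value")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (nrow(samples) == 0L)
    return(event_sequence(integer(0), list(), tick_width = tick_width))
  if (length(unique(samples$subject)) > 1L)
    stop("discretize_stream expects samples from a single subject")
  ts <- .parse_timestamp(samples$timestamp)
  if (anyNA(ts) || any(!is.finite(ts)) || any(ts < 0))
    stop("timestamps must be finite, non-negative seconds (or parseable ISO-8601)")
  sig <- .normalize_signal(samples$signal)
  val <- as.numeric(samples$value)
  if (anyNA(val) || any(!is.finite(val))) stop("values must be finite numbers")

  ord <- order(ts)  # stable: later file rows win among equal timestamps
  tick <- floor(ts[ord] / tick_width) + 1
  sig <- sig[ord]; val <- val[ord]
  # last sample of each (tick, signal) wins
  key <- paste(tick, sig)
  keep <- !duplicated(key, fromLast = TRUE)
  tick <- as.integer(tick[keep]); sig <- sig[keep]; val <- val[keep]

  out_ticks <- sort(unique(tick))
  events <- lapply(out_ticks, function(tk) {
    in_tick <- tick == tk
    s <- sig[in_tick]; v <- val[in_tick]
    labs <- character(0)
    sysv <- if ("SYS_BP" %in% s) v[s == "SYS_BP"] else NA_real_
    diav <- if ("DIA_BP" %in% s) v[s == "DIA_BP"] else NA_real_
    if (!is.na(sysv) || !is.na(diav))
      labs <- c(labs, classify_blood_pressure(sysv, diav))
    if ("SPO2" %in% s) labs <- c(labs, classify_oxygen(v[s == "SPO2"]))
    if ("HR" %in% s) labs <- c(labs, classify_heart_rate(v[s == "HR"]))
    if (!include_normal) labs <- labs[labs != "N"]
    sort(unique(labs))
  })
  keep <- lengths(events) > 0L
  event_sequence(out_ticks[keep], events[keep], tick_width = tick_width)
}

#' Read a vital-sign sample table from delimited text
#'
#' Expects a header `subject,timestamp,signal,value` (comma- or
#' tab-separated; the delimiter is sniffed from the first line unless given).
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs `\t` vs `,`.
#' @return A data frame of samples suitable for [discretize_stream()].
#' @export
read_vital_samples <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject", "timestamp", "signal", "value")
  if (!all(need %in% names(df)))
    stop("sample file must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Write / read an event sequence as JSON
#'
#' The on-disk form is an array of `{"tick": <int>, "events": [<label>...]}`
#' objects; `read_event_sequence()` round-trips what
#' `write_event_sequence()` produces.
#'
#' @param x an `event_sequence`.
#' @param path file path.
#' @return `write_event_sequence()` returns `path` invisibly;
#'   `read_event_sequence()` returns an [event_sequence()].
#' @export
write_event_sequence <- function(x, path) {
  stopifnot(inherits(x, "event_sequence"))
  recs <- lapply(seq_along(x$tick), function(i)
    list(tick = x$tick[i], events = as.list(x$events[[i]])))
  jsonlite::write_json(list(tick_width = attr(x, "tick_width"), sequence = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_sequence
#' @export
read_event_sequence <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- obj$sequence
  event_sequence(vapply(recs, function(r) as.integer(r$tick), integer(1)),
                 lapply(recs, function(r) unlist(r$events, use.names = FALSE)),
                 tick_width = as.numeric(obj$tick_width))
}
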