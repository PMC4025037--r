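# Synthetic vital-sign streams with planted temporal structure.
#
# Baselines keep a healthy subject: HR ~ N(80, 8) bpm, systolic ~ N(115, 8)
# and diastolic ~ N(72, 6) mmHg, SpO2 ~ N(97, 1.2) % clipped to [0, 100] —
# at zero noise every sample classifies to N. Background noise pushes a
# signal family into a uniformly chosen abnormal band; a planted rule, when
# its trigger state set is realised at tick t, fires with the given
# probability and deterministically places its consequent states at t + lag
# by writing representative in-band values (overriding noise at that tick).

# representative in-band values used when a planted consequent fires
.state_values <- list(
  BP_HB = list(SYS_BP = 130, DIA_BP = 85),
  BP_H1 = list(SYS_BP = 150, DIA_BP = 95),
  BP_H2 = list(SYS_BP = 170, DIA_BP = 105),
  SpO2_Lmicro = list(SPO2 = 91.5),
  SpO2_Lmid = list(SPO2 = 82),
  SpO2_Lhard = list(SPO2 = 65),
  Pulse_H = list(HR = 110),
  Pulse_L = list(HR = 50)
)

# abnormal bands for background noise: family -> list of label -> c(lo, hi)
.noise_bands <- list(
  HR = list(Pulse_H = c(101, 130), Pulse_L = c(40, 59)),
  BP = list(BP_HB = c(120, 139), BP_H1 = c(140, 159), BP_H2 = c(160, 190)),
  SPO2 = list(SpO2_Lmicro = c(89, 93.9), SpO2_Lmid = c(75, 88.9),
              SpO2_Lhard = c(50, 74.9))
)
# matching diastolic bands for the BP stages
.dia_bands <- list(BP_HB = c(80, 89), BP_H1 = c(90, 99), BP_H2 = c(100, 120))

#' Simulate a vital-sign sample stream with planted temporal dependencies
#'
#' Draws per-tick heart rate, systolic/diastolic pressure and SpO2 from
#' healthy baseline distributions (clipped into the normal bands, so an
#' undisturbed stream discretizes entirely to `N`), perturbs each signal
#' family into a random
#' abnormal band with probability `background_rate` per tick, and overlays
#' planted temporal rules: whenever a rule's trigger state set is realised at
#' tick `t`, with probability `prob` its consequent states are written at
#' `t + lag` as fixed in-band values. The default planted rule is
#' tachycardia preceding prehypertension one tick later with probability 0.9
#' under 5% background noise over 500 ticks — the regime used throughout the
#' package's recovery tests.
#'
#' The output is byte-identical for a given `seed` and varies across seeds.
#'
#' @param n_ticks number of ticks to simulate (default 500).
#' @param tick_width seconds per tick (default 60).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param subject subject identifier for the output table.
#' @param baseline named list of `c(mean, sd)` for `HR`, `SYS`, `DIA`,
#'   `SPO2`.
#' @param background_rate probability, per signal family and tick, of an
#'   abnormal excursion (default 0.05).
#' @param planted_rules list of `list(trigger=, consequent=, lag=, prob=)`
#'   entries; triggers/consequents are state-label sets.
#' @param force_trigger_at optional integer ticks at which every planted
#'   rule's trigger states are written unconditionally (useful for
#'   deterministic tests).
#' @return A data frame of samples (`subject`, `timestamp`, `signal`,
#'   `value`) with 4 rows per tick, ready for [discretize_stream()].
#' @examples
#' s <- simulate_vitals(n_ticks = 50, seed = 1)
#' discretize_stream(s)
#' @export
simulate_vitals <- function(n_ticks = 500L, tick_width = 60, seed = NULL,
                            subject = "sim-1",
                            baseline = list(HR = c(80, 8), SYS = c(115, 8),
                                            DIA = c(72, 6), SPO2 = c(97, 1.2)),
                            background_rate = 0.05,
                            planted_rules = list(list(
                              trigger = "Pulse_H", consequent = "BP_HB",
                              lag = 1L, prob = 0.9)),
                            force_trigger_at = integer(0)) {
  stopifnot(n_ticks >= 1, tick_width > 0,
            background_rate >= 0, background_rate <= 1)
  for (r in planted_rules)
    stopifnot(r$prob >= 0, r$prob <= 1, r$lag >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n_ticks)
  # baseline draws are clipped into the normal bands: the healthy subject is
  # normal by construction, and every abnormal state is attributable to
  # background noise or a planted rule
  hr <- pmin(100, pmax(60, stats::rnorm(n, baseline$HR[1], baseline$HR[2])))
  sys <- pmin(119.5, pmax(90, stats::rnorm(n, baseline$SYS[1], baseline$SYS[2])))
  dia <- pmin(79.5, pmax(55, stats::rnorm(n, baseline$DIA[1], baseline$DIA[2])))
  spo2 <- pmin(100, pmax(94, stats::rnorm(n, baseline$SPO2[1], baseline$SPO2[2])))

  # background excursions, drawn up-front for determinism
  for (fam in names(.noise_bands)) {
    hit <- stats::runif(n) < background_rate
    if (!any(hit)) next
    bands <- .noise_bands[[fam]]
    pick <- sample(names(bands), sum(hit), replace = TRUE)
    lo <- vapply(bands[pick], `[`, numeric(1), 1)
    hi <- vapply(bands[pick], `[`, numeric(1), 2)
    val <- stats::runif(sum(hit), lo, hi)
    if (fam == "HR") hr[hit] <- val
    if (fam == "SPO2") spo2[hit] <- val
    if (fam == "BP") {
      sys[hit] <- val
      dlo <- vapply(.dia_bands[pick], `[`, numeric(1), 1)
      dhi <- vapply(.dia_bands[pick], `[`, numeric(1), 2)
      dia[hit] <- stats::runif(sum(hit), dlo, dhi)
    }
  }

  write_states <- function(t, labels) {
    for (lab in labels) {
      vals <- .state_values[[lab]]
      if (is.null(vals)) next  # "N" or unknown: leave baseline
      if (!is.null(vals$HR)) hr[t] <<- vals$HR
      if (!is.null(vals$SYS_BP)) sys[t] <<- vals$SYS_BP
      if (!is.null(vals$DIA_BP)) dia[t] <<- vals$DIA_BP
      if (!is.null(vals$SPO2)) spo2[t] <<- vals$SPO2
    }
  }
  for (t in force_trigger_at)
    for (r in planted_rules) write_states(t, r$trigger)

  # sequential pass: realised states at t (after any overrides landing at t)
  # decide whether each rule schedules its consequent at t + lag
  for (t in seq_len(n)) {
    states <- c(classify_blood_pressure(sys[t], dia[t]),
                classify_oxygen(spo2[t]), classify_heart_rate(hr[t]))
    for (r in planted_rules) {
      if (all(r$trigger %in% states) && t + r$lag <= n &&
          stats::runif(1) < r$prob)
        write_states(t + r$lag, r$consequent)
    }
  }

  data.frame(
    subject = subject,
    timestamp = rep((seq_len(n) - 1L) * tick_width, each = 4L),
    signal = rep(c("SYS_BP", "DIA_BP", "SPO2", "HR"), times = n),
    value = as.numeric(rbind(sys, dia, spo2, hr)),
    stringsAsFactors = FALSE)
}

#' The worked-example event sequence over abstract labels
#'
#' A five-tick complex event sequence over the abstract alphabet \{A, B, C\}
#' — simultaneous sets \{A,B,C\}, \{A,B,C\}, \{B,C\}, \{B\}, \{A\} at ticks
#' 1..5 — used throughout the documentation and tests to exercise batch
#' mining and the sliding-window update on paper-checkable numbers: mining
#' ticks 1-4 at minimum support 2 (window 4) gives A:2, B:4, C:3, AB:2,
#' BB:3, BC:2, CB:3, CC:2, BBB:2 among the frequent episodes, and the slide
#' to tick 5 yields the final frequent table A:2, B:3, C:2, BB:2, CB:2.
#'
#' @return An [event_sequence()] with tick width 1.
#' @export
vsp_example_sequence <- function() {
  event_sequence(1:5,
                 list(c("A", "B", "C"), c("A", "B", "C"), c("B", "C"),
                      "B", "A"),
                 tick_width = 1)
}
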