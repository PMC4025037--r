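# Episode representation: a serial episode is a list of "steps", each step a
# set (character vector) of events required to co-occur at one tick. Steps
# must appear at strictly increasing ticks in any occurrence. The canonical
# key serialises steps with "|" and within-step events (lexicographically
# sorted) with ",".

#' Canonical episode key
#'
#' Serialises a serial episode (list of simultaneous event sets) into a
#' canonical string: events within a step are sorted and joined with `","`,
#' steps are joined with `"|"`. A plain character vector is taken as a
#' sequence of single-event steps, so `c("B","B")` and `list("B","B")` both
#' key to `"B|B"`.
#'
#' @param episode a list of character vectors (steps), or a character vector
#'   of single-event steps.
#' @return A length-1 character key.
#' @examples
#' episode_key(c("C", "B"))                     # "C|B"
#' episode_key(list(c("Pulse_H", "BP_HB"), "BP_HB"))
#' @export
episode_key <- function(episode) {
  steps <- as_episode(episode)
  paste(vapply(steps, paste, character(1), collapse = ","), collapse = "|")
}

#' @rdname episode_key
#' @param key a canonical key produced by `episode_key()`.
#' @return `parse_episode()` returns the list-of-steps form.
#' @export
parse_episode <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  lapply(strsplit(key, "|", fixed = TRUE)[[1]],
         function(s) strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Normalise an episode to list-of-steps form
#' @keywords internal
as_episode <- function(episode) {
  if (is.character(episode)) episode <- as.list(episode)
  if (!is.list(episode) || length(episode) == 0L)
    stop("an episode is a non-empty list of event sets")
  steps <- lapply(episode, function(s) sort(unique(as.character(s))))
  if (any(lengths(steps) == 0L)) stop("episode steps must be non-empty")
  steps
}

#' Human-readable episode string
#'
#' Single-event steps print bare, multi-event steps parenthesised:
#' `"Pulse_H -> (BP_HB Pulse_H)"`.
#'
#' @inheritParams episode_key
#' @return A length-1 character string.
#' @export
format_episode <- function(episode) {
  steps <- as_episode(episode)
  paste(vapply(steps, function(s) {
    if (length(s) == 1L) s else paste0("(", paste(s, collapse = " "), ")")
  }, character(1)), collapse = " -> ")
}

# ticks of `seq` whose event set contains all of `step`
.step_ticks <- function(step, seq) {
  hit <- vapply(seq$events, function(ev) all(step %in% ev), logical(1))
  seq$tick[hit]
}

#' Minimal occurrences of an episode (direct computation)
#'
#' An interval `[s, e]` is an occurrence of a serial episode if its steps
#' match at strictly increasing ticks within the interval; it is a *minimal*
#' occurrence if no proper sub-interval also contains an occurrence. Support
#' is counted as the number of minimal occurrences whose span satisfies
#' `e - s < window`.
#'
#' This function computes the list straight from the definition — for every
#' tick where the first step matches, the earliest completion of the
#' remaining steps is found greedily, and dominated (nested) intervals are
#' discarded — independent of the pattern-growth miner, for which it serves
#' as the reference count (see [mine_episodes()]).
#'
#' @param episode an episode (list of steps, or character vector of
#'   single-event steps).
#' @param seq an [event_sequence()].
#' @param window maximum allowed span in ticks: occurrences must satisfy
#'   `end - start < window`. Default `Inf` (no bound).
#' @return An integer matrix with columns `start`, `end`, one row per
#'   minimal occurrence, ordered by start.
#' @examples
#' s <- vsp_example_sequence()
#' minimal_occurrences(c("B", "B"), window_sequence(s, 1, 4), window = 4)
#' @export
minimal_occurrences <- function(episode, seq, window = Inf) {
  stopifnot(inherits(seq, "event_sequence"), window >= 1)
  steps <- as_episode(episode)
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (length(seq$tick) == 0L) return(empty)
  tick_lists <- lapply(steps, .step_ticks, seq = seq)
  if (any(lengths(tick_lists) == 0L)) return(empty)
  starts <- tick_lists[[1]]
  ends <- vapply(starts, function(s) {
    cur <- s
    for (k in seq_along(steps)[-1]) {
      nxt <- tick_lists[[k]]
      nxt <- nxt[nxt > cur]
      if (length(nxt) == 0L) return(NA_integer_)
      cur <- nxt[1]
    }
    cur
  }, integer(1))
  ok <- !is.na(ends)
  starts <- starts[ok]; ends <- ends[ok]
  if (length(starts) == 0L) return(empty)
  # starts strictly increasing, greedy ends non-decreasing: an interval is
  # non-minimal iff a later one shares its end
  keep <- c(ends[-length(ends)] != ends[-1], TRUE)
  starts <- starts[keep]; ends <- ends[keep]
  span_ok <- (ends - starts) < window
  cbind(start = starts[span_ok], end = ends[span_ok])
}
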