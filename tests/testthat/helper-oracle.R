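# Independent brute-force oracles, kept deliberately dumb.

# Does the episode occur at strictly increasing ticks within [s, e]?
bf_occurs_within <- function(step_ticks, s, e) {
  cur <- s - 1L
  for (tk in step_ticks) {
    nxt <- tk[tk > cur & tk <= e]
    if (length(nxt) == 0L) return(FALSE)
    cur <- nxt[1]
  }
  TRUE
}

bf_step_ticks <- function(steps, seq) {
  lapply(steps, function(st)
    seq$tick[vapply(seq$events, function(ev) all(st %in% ev), logical(1))])
}

# Minimal occurrences straight from the interval definition: an interval is
# minimal iff it contains an occurrence and neither one-tick shrinkage does.
bf_minimal_occurrences <- function(episode, seq, window = Inf) {
  steps <- if (is.character(episode)) as.list(episode) else episode
  tl <- bf_step_ticks(steps, seq)
  ticks <- seq$tick
  res <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(ticks)) {
    for (j in seq(i, length(ticks))) {
      s <- ticks[i]; e <- ticks[j]
      if (e - s >= window) break
      if (!bf_occurs_within(tl, s, e)) next
      shrink_l <- i < j && bf_occurs_within(tl, ticks[i + 1L], e)
      shrink_r <- i < j && bf_occurs_within(tl, s, ticks[j - 1L])
      if (!shrink_l && !shrink_r) res <- rbind(res, c(s, e))
    }
  }
  res
}

# Enumerate every frequent serial episode (single-event steps) by breadth-
# first extension, counting with the package's definitional
# minimal_occurrences(); episodes without any windowed occurrence cannot
# have occurring extensions, which is the only pruning applied.
bf_frequent_episodes <- function(seq, min_support, window, max_len) {
  alphabet <- sort(unique(unlist(seq$events)))
  out <- integer(0)
  frontier <- lapply(alphabet, function(e) list(e))
  len <- 1L
  while (length(frontier) > 0L) {
    grow <- list()
    for (st in frontier) {
      n <- nrow(minimal_occurrences(st, seq, window = window))
      if (n == 0L) next
      if (n >= min_support) out[[episode_key(st)]] <- n
      if (len < max_len)
        for (e in alphabet) grow[[length(grow) + 1L]] <- c(st, list(e))
    }
    frontier <- grow
    len <- len + 1L
  }
  out[sort(names(out), method = "radix")]
}

# Random complex event sequence over an abstract alphabet.
random_sequence <- function(n_ticks, alphabet_size = 3L, max_events = 3L,
                            p_occupied = 0.8) {
  alphabet <- LETTERS[seq_len(alphabet_size)]
  ticks <- which(stats::runif(n_ticks) < p_occupied)
  if (length(ticks) == 0L) ticks <- 1L
  k <- min(max_events, length(alphabet))
  events <- lapply(ticks, function(i) sample(alphabet, sample.int(k, 1L)))
  event_sequence(ticks, events, tick_width = 1)
}

# Named support vector of an episode_set, sorted by key.
episode_support_table <- function(ep) {
  sup <- vapply(ep, `[[`, integer(1), "support")
  names(sup) <- vapply(ep, `[[`, character(1), "key")
  sup[sort(names(sup), method = "radix")]
}

# Fresh window filled from a sequence by sliding tick by tick.
filled_window <- function(seq, width, min_support = 2L, max_len = 5L) {
  w <- sliding_window(width = width, min_support = min_support,
                      max_len = max_len)
  for (i in seq_along(seq$tick)) slide(w, seq$tick[i], seq$events[[i]])
  w
}
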