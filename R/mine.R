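# Pattern-growth miner over minimal-occurrence lists.
#
# Growth appends one event at a time to the right end of an episode. The
# minimal occurrences of the extension alpha.e are obtained from those of
# alpha by a join: each minimal occurrence [b,u] of alpha contributes the
# candidate [b,t] with t the first tick > u carrying e; candidates sharing an
# end are dominated by the one with the latest start. This recurrence is
# exact, and support (the number of minimal occurrences, span-bounded by the
# window) is anti-monotone under prefix extension — each minimal occurrence
# of alpha.e contains a minimal occurrence of alpha with the same start — so
# growing only frequent episodes loses nothing. Support is NOT anti-monotone
# under deletion of interior steps, so no other pruning is applied.

# join the minimized occurrence list `occ` of a prefix with the sorted tick
# list `t_e` of the appended event; returns a minimized, span-filtered matrix
.mo_join <- function(occ, t_e, window) {
  if (nrow(occ) == 0L || length(t_e) == 0L)
    return(occ[0L, , drop = FALSE])
  idx <- findInterval(occ[, 2L], t_e) + 1L  # first tick strictly after end
  valid <- idx <= length(t_e)
  starts <- occ[valid, 1L]
  ends <- t_e[idx[valid]]
  if (length(starts) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  keep <- c(ends[-length(ends)] != ends[-1], TRUE)  # keep latest start per end
  starts <- starts[keep]; ends <- ends[keep]
  ok <- (ends - starts) < window
  cbind(start = starts[ok], end = ends[ok])
}

#' Mine frequent serial episodes by minimal occurrences
#'
#' Discovers every serial episode (sequence of single events at strictly
#' increasing ticks) whose number of minimal occurrences within the span
#' bound reaches `min_support`, by candidate-free pattern growth: the
#' prefix tree of the sequence ([episode_tree()]) indexes which events occur
#' at which ticks, single events seed the search, and each frequent episode
#' is extended by the events the tree reports after its occurrences. Support
#' counts are maintained exactly through a minimal-occurrence join, so every
#' reported count equals the direct computation of
#' [minimal_occurrences()].
#'
#' @param seq an [event_sequence()].
#' @param min_support minimum number of minimal occurrences (default 2).
#' @param window span bound in ticks: an occurrence `[s, e]` is counted only
#'   if `e - s < window`. This is the same "time interval" that drives the
#'   sliding window (default 4).
#' @param max_len cap on episode length, a guard against pathological growth
#'   (default 5).
#' @param tree optionally a pre-built [episode_tree()] of `seq`.
#' @return An object of class `episode_set`: a list with one entry per
#'   frequent episode (`steps`, `key`, `support`, `occurrences`), ordered by
#'   episode length then canonical key, with the mining parameters attached
#'   as attributes.
#' @examples
#' w1 <- window_sequence(vsp_example_sequence(), 1, 4)
#' ep <- mine_episodes(w1, min_support = 2, window = 4)
#' episode_support(ep, c("B", "B"))  # 3
#' @export
mine_episodes <- function(seq, min_support = 2L, window = 4L, max_len = 5L,
                          tree = NULL) {
  stopifnot(inherits(seq, "event_sequence"),
            min_support >= 1L, window >= 1L, max_len >= 1L)
  min_support <- as.integer(min_support)
  out <- list()
  if (length(seq$tick) > 0L) {
    if (is.null(tree)) tree <- episode_tree(seq)
    # event -> sorted ticks, recovered through the tree's header links
    ev_ticks <- list()
    for (tk in seq$tick) {
      for (e in tree_events_at(tree, tk)) ev_ticks[[e]] <- c(ev_ticks[[e]], tk)
    }
    ev_ticks <- ev_ticks[order(names(ev_ticks), method = "radix")]

    frontier <- list()
    for (e in names(ev_ticks)) {
      occ <- cbind(start = ev_ticks[[e]], end = ev_ticks[[e]])
      if (nrow(occ) >= min_support)
        frontier[[e]] <- list(steps = list(e), key = e,
                              support = nrow(occ), occurrences = occ)
    }
    out <- frontier
    len <- 1L
    while (length(frontier) > 0L && len < max_len) {
      nxt <- list()
      for (ent in frontier) {
        occ <- ent$occurrences
        # events observable after an occurrence end, within the span bound:
        # ticks t with end_i < t < start_i + window for some occurrence i
        cand_ticks <- seq$tick[vapply(seq$tick, function(t)
          any(occ[, 2L] < t & t < occ[, 1L] + window), logical(1))]
        cand <- unique(as.character(
          unlist(lapply(cand_ticks, tree_events_at, tree = tree))))
        for (e in sort(cand, method = "radix")) {
          joined <- .mo_join(occ, ev_ticks[[e]], window)
          if (nrow(joined) >= min_support) {
            key <- paste0(ent$key, "|", e)
            nxt[[key]] <- list(steps = c(ent$steps, list(e)), key = key,
                               support = nrow(joined), occurrences = joined)
          }
        }
      }
      out <- c(out, nxt)
      frontier <- nxt
      len <- len + 1L
    }
    if (length(out) > 1L) {
      lens <- vapply(out, function(x) length(x$steps), integer(1))
      keys <- vapply(out, `[[`, character(1), "key")
      out <- out[order(lens, keys, method = "radix")]
    }
  }
  structure(out, class = "episode_set",
            min_support = min_support, window = as.integer(window),
            max_len = as.integer(max_len))
}

#' Look up the support of one episode in a mined set
#'
#' @param x an `episode_set` from [mine_episodes()].
#' @param episode an episode (steps list / character vector) or canonical key.
#' @return Integer support, or `NA` if the episode is not in the set.
#' @export
episode_support <- function(x, episode) {
  stopifnot(inherits(x, c("episode_set", "vsp_update")))
  key <- if (is.character(episode) && length(episode) == 1L &&
             grepl("|", episode, fixed = TRUE)) episode else episode_key(episode)
  if (inherits(x, "vsp_update")) {
    all <- c(x$frequent, x$tracked_infrequent)
    return(if (key %in% names(all)) unname(all[[key]]) else NA_integer_)
  }
  ent <- x[[key]]
  if (is.null(ent)) NA_integer_ else ent$support
}

#' @export
as.data.frame.episode_set <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(episode = character(0), key = character(0),
                      length = integer(0), support = integer(0)))
  data.frame(
    episode = vapply(x, function(e) format_episode(e$steps), character(1)),
    key = vapply(x, `[[`, character(1), "key"),
    length = vapply(x, function(e) length(e$steps), integer(1)),
    support = vapply(x, `[[`, integer(1), "support"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.episode_set <- function(x, max = 20L, ...) {
  cat(sprintf("Frequent episodes: %d (min support %d, window %d ticks)\n",
              length(x), attr(x, "min_support"), attr(x, "window")))
  df <- as.data.frame(x)
  print(utils::head(df[c("episode", "support")], max), row.names = FALSE)
  if (nrow(df) > max) cat(sprintf("  ... %d more\n", nrow(df) - max))
  invisible(x)
}

#' Write / read mined episodes as JSON
#'
#' Serialises each episode as
#' `{"episode": [["B"],["B"]], "support": 3, "occurrences": [[1,2],...]}`.
#'
#' @param x an `episode_set`.
#' @param path file path.
#' @export
write_episodes <- function(x, path) {
  stopifnot(inherits(x, "episode_set"))
  recs <- lapply(x, function(e)
    list(episode = lapply(e$steps, as.list),
         support = e$support,
         occurrences = lapply(seq_len(nrow(e$occurrences)), function(i)
           as.list(unname(e$occurrences[i, ])))))
  jsonlite::write_json(
    list(min_support = attr(x, "min_support"), window = attr(x, "window"),
         max_len = attr(x, "max_len"), episodes = unname(recs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (r in obj$episodes) {
    steps <- lapply(r$episode, function(s) unlist(s, use.names = FALSE))
    occ <- if (length(r$occurrences) == 0L)
      matrix(integer(0), ncol = 2L) else
      do.call(rbind, lapply(r$occurrences, function(p) as.integer(unlist(p))))
    colnames(occ) <- c("start", "end")
    key <- episode_key(steps)
    out[[key]] <- list(steps = steps, key = key,
                       support = as.integer(r$support), occurrences = occ)
  }
  structure(out, class = "episode_set",
            min_support = as.integer(obj$min_support),
            window = as.integer(obj$window),
            max_len = as.integer(obj$max_len))
}
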