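# Sliding-window maintenance of the episode table.
#
# The window is an environment (reference semantics: updates mutate it in
# place). It tracks EVERY episode with at least one windowed minimal
# occurrence in the current contents, up to max_len, not just the frequent
# ones: minimal-occurrence support is anti-monotone only under prefix
# extension, and an episode frequent tomorrow may be sub-threshold today, so
# keeping all occurrence lists is what makes the incremental state provably
# equal to batch re-mining after every slide. Memory stays bounded by the
# window width and the length cap.
#
# Exactness of the two update steps:
#  * deletion: the expired tick is the oldest, so it can only be the START
#    of a minimal occurrence; dropping occurrences that start there leaves
#    exactly the minimal-occurrence lists of the shortened contents.
#  * addition: a new tick t can only create occurrences ENDING at t; for an
#    episode alpha.e with e at t, the unique candidate is [b, t] with b the
#    latest start among alpha's occurrences ending before t, kept iff its
#    span is inside the window and no existing occurrence is nested in it.

#' Create an empty sliding window
#'
#' @param width window width in ticks (the "time interval"): tick `t` is live
#'   while `newest - t < width`.
#' @param min_support minimum minimal-occurrence count for an episode to be
#'   reported frequent.
#' @param max_len cap on tracked episode length (default 5).
#' @return An object of class `sliding_window` (an environment; the update
#'   functions modify it in place and return an update summary).
#' @examples
#' w <- sliding_window(width = 4, min_support = 2)
#' slide(w, 1, c("A", "B", "C"))
#' @export
sliding_window <- function(width, min_support = 2L, max_len = 5L) {
  stopifnot(width >= 1L, min_support >= 1L, max_len >= 1L)
  win <- new.env(parent = emptyenv())
  win$width <- as.integer(width)
  win$min_support <- as.integer(min_support)
  win$max_len <- as.integer(max_len)
  win$tick <- integer(0)
  win$events <- list()
  win$stats <- new.env(parent = emptyenv())
  class(win) <- "sliding_window"
  win
}

#' @export
print.sliding_window <- function(x, ...) {
  keys <- ls(x$stats, sorted = FALSE)
  sup <- vapply(keys, function(k) nrow(x$stats[[k]]$occurrences), integer(1))
  cat(sprintf(
    "Sliding window: width %d, min support %d; ticks [%s]; %d tracked episode(s), %d frequent\n",
    x$width, x$min_support,
    if (length(x$tick)) paste(range(x$tick), collapse = "..") else "",
    length(keys), sum(sup >= x$min_support)))
  invisible(x)
}

#' Current window contents as an event sequence
#' @param win a [sliding_window()].
#' @return An [event_sequence()] of the live ticks.
#' @export
window_contents <- function(win) {
  stopifnot(inherits(win, "sliding_window"))
  event_sequence(win$tick, win$events)
}

.win_result <- function(win, newly = character(0)) {
  keys <- sort(ls(win$stats, sorted = FALSE), method = "radix")
  sup <- vapply(keys, function(k) win$stats[[k]]$support, integer(1))
  if (length(keys) == 0L) sup <- integer(0)
  freq <- sup[sup >= win$min_support]
  infreq <- sup[sup < win$min_support]
  newly <- newly[newly %in% keys]
  gen <- sup[match(sort(newly, method = "radix"), keys)]
  names(gen) <- sort(newly, method = "radix")
  structure(list(frequent = freq, tracked_infrequent = infreq,
                 newly_generated = gen),
            class = "vsp_update")
}

#' @export
print.vsp_update <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0L) "(none)" else
    paste(sprintf("%s:%d", vapply(names(v), function(k)
      format_episode(parse_episode(k)), character(1)), v), collapse = ", ")
  cat("frequent:          ", fmt(x$frequent), "\n")
  cat("tracked infrequent:", fmt(x$tracked_infrequent), "\n")
  cat("newly generated:   ", fmt(x$newly_generated), "\n")
  invisible(x)
}

#' Expire the oldest tick of the window
#'
#' Removes the window's oldest tick and every minimal occurrence anchored at
#' it (the oldest tick can only be an occurrence's start), recomputes
#' supports, and reclassifies episodes; episodes left with no occurrence are
#' dropped from tracking.
#'
#' @param win a [sliding_window()], modified in place.
#' @param expired_tick the tick to expire; must equal the window's oldest
#'   tick.
#' @return A `vsp_update` summary: named support vectors `frequent`,
#'   `tracked_infrequent`, `newly_generated` (always empty here).
#' @export
delete_oldest_events <- function(win, expired_tick) {
  stopifnot(inherits(win, "sliding_window"))
  if (length(win$tick) == 0L) stop("window is empty")
  if (expired_tick != win$tick[1])
    stop("expired_tick (", expired_tick, ") is not the oldest window tick (",
         win$tick[1], ")")
  win$tick <- win$tick[-1]
  win$events <- win$events[-1]
  for (k in ls(win$stats, sorted = FALSE)) {
    ent <- win$stats[[k]]
    occ <- ent$occurrences
    if (nrow(occ) > 0L && occ[1L, 1L] == expired_tick)
      occ <- occ[-1L, , drop = FALSE]
    if (nrow(occ) == 0L) {
      rm(list = k, envir = win$stats)
    } else {
      ent$occurrences <- occ
      ent$support <- nrow(occ)
      win$stats[[k]] <- ent
    }
  }
  .win_result(win)
}

#' Temporal join of tracked episodes with an event at the newest tick
#'
#' For every tracked episode `alpha` (shorter than the length cap) with a
#' minimal occurrence ending before `tick` and starting inside the window
#' span, forms the extension `alpha -> event` and computes its updated
#' minimal-occurrence list: the single join candidate `[b, tick]` (with `b`
#' the latest such start) is appended to any occurrences the extension
#' already has, unless an existing occurrence is nested inside it. The
#' single-step episode `event` itself is included with its occurrence at
#' `tick`. The window is not modified; [add_new_events()] merges the result.
#'
#' @param win a [sliding_window()].
#' @param event a single event label present at the new tick.
#' @param tick the newest tick.
#' @return A named list keyed by episode, each entry holding `steps`, `key`,
#'   `support` and the merged `occurrences` matrix.
#' @export
temporal_join <- function(win, event, tick) {
  stopifnot(inherits(win, "sliding_window"), is.character(event),
            length(event) == 1L)
  if (length(win$tick) && tick < win$tick[length(win$tick)])
    stop("tick must not precede the window head")
  out <- list()
  add_occ <- function(prev_key, prev_steps, b) {
    key <- if (is.null(prev_key)) event else paste0(prev_key, "|", event)
    steps <- c(prev_steps, list(event))
    ent <- win$stats[[key]]
    occ <- if (is.null(ent))
      matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    else ent$occurrences
    if (nrow(occ) == 0L || occ[nrow(occ), 1L] < b) {
      occ <- rbind(occ, c(b, tick))
      out[[key]] <<- list(steps = steps, key = key,
                          support = nrow(occ), occurrences = occ)
    }
    invisible(NULL)
  }
  add_occ(NULL, list(), tick)  # the event's own occurrence [tick, tick]
  for (k in sort(ls(win$stats, sorted = FALSE), method = "radix")) {
    ent <- win$stats[[k]]
    if (length(ent$steps) >= win$max_len) next
    occ <- ent$occurrences
    prior <- occ[occ[, 2L] < tick, , drop = FALSE]
    if (nrow(prior) == 0L) next
    b <- prior[nrow(prior), 1L]       # latest start among prior occurrences
    if (tick - b >= win$width) next   # span bound
    add_occ(k, ent$steps, b)
  }
  out
}

#' Ingest a new simultaneous event set at the window head
#'
#' Appends the new tick to the window contents and updates the episode
#' table: each event's own occurrence list gains `[tick, tick]`, and the
#' temporal join extends every tracked episode that can reach the new tick,
#' updating episodes already tracked and creating the rest. Supports after
#' the call equal batch mining of the updated contents. No expiry is
#' performed here — compose with [delete_oldest_events()] or use [slide()].
#'
#' @param win a [sliding_window()], modified in place.
#' @param tick the new tick; must exceed every tick in the window.
#' @param events character vector of simultaneous events at `tick`.
#' @return A `vsp_update` summary; `newly_generated` holds the episodes
#'   created by this call.
#' @export
add_new_events <- function(win, tick, events) {
  stopifnot(inherits(win, "sliding_window"))
  tick <- as.integer(tick)
  if (length(win$tick) && tick <= win$tick[length(win$tick)])
    stop("new tick must exceed all window ticks")
  events <- sort(unique(as.character(events)))
  if (length(events) == 0L) return(.win_result(win))
  win$tick <- c(win$tick, tick)
  win$events <- c(win$events, list(events))
  newly <- character(0)
  existing <- ls(win$stats, sorted = FALSE)
  for (e in events) {
    joined <- temporal_join(win, e, tick)
    for (key in names(joined)) {
      if (!key %in% existing) newly <- c(newly, key)
      win$stats[[key]] <- joined[[key]]
    }
  }
  .win_result(win, newly = newly)
}

#' Slide the window to a new tick
#'
#' Composite update: expires every tick that falls out of
#' `(tick - width, tick]`, then ingests the new simultaneous event set. After
#' the call the tracked episode table equals batch mining of the window
#' contents.
#'
#' @inheritParams add_new_events
#' @return A `vsp_update` summary for the final state.
#' @examples
#' w <- sliding_window(width = 4, min_support = 2)
#' s <- vsp_example_sequence()
#' for (i in seq_along(s$tick)) print(slide(w, s$tick[i], s$events[[i]]))
#' @export
slide <- function(win, tick, events) {
  stopifnot(inherits(win, "sliding_window"))
  tick <- as.integer(tick)
  while (length(win$tick) > 0L && tick - win$tick[1] >= win$width)
    delete_oldest_events(win, win$tick[1])
  add_new_events(win, tick, events)
}

#' Audit a window against batch re-mining
#'
#' Re-mines the current window contents from scratch and compares episode
#' for episode and support for support with the incrementally maintained
#' table — the frequent table always, and with `all = TRUE` (default) every
#' tracked episode.
#'
#' @param win a [sliding_window()].
#' @param all audit sub-threshold tracked episodes too?
#' @return `TRUE` if the tables agree; otherwise `FALSE` with a `"diff"`
#'   attribute describing the discrepancies.
#' @export
check_batch <- function(win, all = TRUE) {
  stopifnot(inherits(win, "sliding_window"))
  batch <- mine_episodes(window_contents(win),
                         min_support = if (all) 1L else win$min_support,
                         window = win$width, max_len = win$max_len)
  bsup <- vapply(batch, `[[`, integer(1), "support")
  bkey <- vapply(batch, `[[`, character(1), "key")
  names(bsup) <- bkey
  keys <- sort(ls(win$stats, sorted = FALSE), method = "radix")
  wsup <- vapply(keys, function(k) win$stats[[k]]$support, integer(1))
  if (length(keys) == 0L) wsup <- integer(0) else names(wsup) <- keys
  if (!all) wsup <- wsup[wsup >= win$min_support]
  bsup <- bsup[sort(names(bsup), method = "radix")]
  wsup <- wsup[sort(names(wsup), method = "radix")]
  if (identical(unname(bsup), unname(wsup)) &&
      identical(names(bsup), names(wsup))) return(TRUE)
  only_b <- setdiff(names(bsup), names(wsup))
  only_w <- setdiff(names(wsup), names(bsup))
  both <- intersect(names(bsup), names(wsup))
  mism <- both[bsup[both] != wsup[both]]
  structure(FALSE, diff = list(missing = only_b, extra = only_w,
                               support_mismatch = mism))
}
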