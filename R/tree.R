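# Prefix tree over simultaneous event sets. Each tick's event set is sorted
# lexicographically and spelled as a root-to-node path; only the terminal
# node of the path records the tick (its "leaf"), so ticks with identical
# event sets share one path. A header table maps every tick to its leaf.

#' Build the simultaneous-event prefix tree of a sequence
#'
#' One pass over the complex event sequence inserts each tick's
#' lexicographically sorted event set as a root-to-node path; shared prefixes
#' are merged and the tick is recorded only at the terminal node of its path
#' (the leaf's tick set). A header table keyed by tick links every time point
#' to its leaf so the events present at any tick can be recovered from the
#' tree without rescanning the sequence — this is what guides episode growth
#' in [mine_episodes()].
#'
#' @param seq an [event_sequence()].
#' @return An object of class `episode_tree` with a mutable node structure
#'   (`$root`), and a header table (`$header`) mapping tick to leaf path.
#' @examples
#' tr <- episode_tree(vsp_example_sequence())
#' tree_events_at(tr, 1)  # "A" "B" "C"
#' @export
episode_tree <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  new_node <- function(label) {
    nd <- new.env(parent = emptyenv())
    nd$label <- label
    nd$children <- list()
    nd$ticks <- integer(0)
    nd
  }
  root <- new_node(NA_character_)
  header <- vector("list", length(seq$tick))
  names(header) <- as.character(seq$tick)
  for (i in seq_along(seq$tick)) {
    path <- sort(seq$events[[i]])  # fixed (lexicographic) insertion order
    node <- root
    for (e in path) {
      if (is.null(node$children[[e]])) {
        node$children[[e]] <- new_node(e)
        node$children <- node$children[order(names(node$children), method = "radix")]
      }
      node <- node$children[[e]]
    }
    node$ticks <- c(node$ticks, seq$tick[i])  # leaf records the occurrence
    header[[i]] <- path                       # link resolves to that leaf
  }
  structure(list(root = root, header = header, n_ticks = length(seq$tick)),
            class = "episode_tree")
}

#' @rdname episode_tree
#' @param tree an `episode_tree`.
#' @param tick a time point present in the sequence.
#' @return `tree_events_at()` returns the sorted event set of `tick`,
#'   recovered by following the header link and reading the leaf's path.
#' @export
tree_events_at <- function(tree, tick) {
  stopifnot(inherits(tree, "episode_tree"))
  path <- tree$header[[as.character(tick)]]
  if (is.null(path)) return(character(0))
  # verify the link resolves: walk the path and check the leaf holds the tick
  node <- tree$root
  for (e in path) node <- node$children[[e]]
  if (!tick %in% node$ticks)
    stop("corrupt header link for tick ", tick)
  path
}

#' Enumerate the leaves of a prefix tree
#'
#' @param tree an `episode_tree`.
#' @return A list of `list(path = <character>, ticks = <integer>)`, one per
#'   node holding at least one tick, in lexicographic path order.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (length(node$ticks) > 0L)
      out[[length(out) + 1L]] <<- list(path = path, ticks = sort(node$ticks))
    for (nm in names(node$children)) walk(node$children[[nm]], c(path, nm))
  }
  walk(tree$root, character(0))
  out
}

#' @export
print.episode_tree <- function(x, ...) {
  cat(sprintf("Simultaneous-event prefix tree: %d tick(s)\n", x$n_ticks))
  walk <- function(node, depth) {
    for (nm in names(node$children)) {
      ch <- node$children[[nm]]
      leaf <- if (length(ch$ticks)) sprintf("  {%s}", paste(ch$ticks, collapse = ",")) else ""
      cat(strrep("  ", depth), nm, leaf, "\n", sep = "")
      walk(ch, depth + 1L)
    }
  }
  walk(x$root, 1L)
  invisible(x)
}
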