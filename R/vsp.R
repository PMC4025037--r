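#' Fit a vital-signs state predictor
#'
#' The offline phase of the predictor: raw samples are discretized into a
#' complex event sequence ([discretize_stream()]), frequent serial episodes
#' are mined by minimal occurrences ([mine_episodes()]), and confidence-
#' ranked episode rules are derived ([generate_rules()]). The fitted object
#' can then score incoming buffers with [predict.vsp()], optionally mapping
#' predictions to care guidelines.
#'
#' @param x a sample data frame (`subject`, `timestamp`, `signal`, `value`)
#'   or an [event_sequence()].
#' @param min_support minimum minimal-occurrence count (default 2).
#' @param min_confidence minimum rule confidence (default 0.7).
#' @param window episode span bound and sliding-window width, in ticks
#'   (default 4).
#' @param tick_width seconds per tick for discretization (default 60).
#' @param include_normal keep `"N"` events when discretizing?
#' @param max_len cap on episode length (default 5).
#' @return An object of class `vsp` with components `sequence`, `episodes`,
#'   `rules` and `params`.
#' @examples
#' fit <- vsp(simulate_vitals(n_ticks = 200, seed = 42), min_confidence = 0.5)
#' print(fit)
#' predict(fit, event_sequence(1, list("Pulse_H")))
#' @seealso [sliding_window()] for the online, incrementally updated phase.
#' @export
vsp <- function(x, min_support = 2L, min_confidence = 0.7, window = 4L,
                tick_width = 60, include_normal = FALSE, max_len = 5L) {
  seq <- if (inherits(x, "event_sequence")) x
  else discretize_stream(x, tick_width = tick_width,
                         include_normal = include_normal)
  episodes <- mine_episodes(seq, min_support = min_support, window = window,
                            max_len = max_len)
  rules <- generate_rules(episodes, min_support = min_support,
                          min_confidence = min_confidence)
  structure(list(sequence = seq, episodes = episodes, rules = rules,
                 params = list(min_support = as.integer(min_support),
                               min_confidence = min_confidence,
                               window = as.integer(window),
                               tick_width = tick_width,
                               include_normal = include_normal,
                               max_len = as.integer(max_len)),
                 call = match.call()),
            class = "vsp")
}

#' @export
print.vsp <- function(x, ...) {
  cat("Vital-signs state predictor\n")
  cat(sprintf("  events: %d tick(s); frequent episodes: %d; rules: %d\n",
              length(x$sequence$tick), length(x$episodes), nrow(x$rules)))
  cat(sprintf("  min support %d, min confidence %g, window %d tick(s)\n",
              x$params$min_support, x$params$min_confidence, x$params$window))
  invisible(x)
}

#' @export
summary.vsp <- function(object, ...) {
  structure(list(fit = object,
                 episodes = as.data.frame(object$episodes),
                 top_rules = utils::head(object$rules, 10L)),
            class = "summary.vsp")
}

#' @export
print.summary.vsp <- function(x, ...) {
  print(x$fit)
  if (nrow(x$episodes) > 0L) {
    cat("\nFrequent episodes by length:\n")
    print(table(length = x$episodes$length))
    cat("\nTop rules:\n")
    print(structure(x$top_rules, class = c("vsp_rules", "data.frame")))
  }
  invisible(x)
}

#' @export
coef.vsp <- function(object, ...) {
  r <- object$rules
  if (nrow(r) == 0L)
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("support", "confidence"))))
  m <- cbind(support = r$support, confidence = r$confidence)
  rownames(m) <- paste(vapply(r$antecedent, function(k)
    format_episode(parse_episode(k)), character(1)), "=>",
    vapply(r$consequent, function(k)
      format_episode(parse_episode(k)), character(1)))
  m
}

#' Predict the upcoming vital-sign state from a live buffer
#'
#' @param object a fitted [vsp()] model.
#' @param newdata the recent buffer: an [event_sequence()] or a sample data
#'   frame (discretized with the fit's settings).
#' @param guidelines optional `guideline_map` (see [read_guidelines()]); when
#'   given, the return value is a recommendation instead of a bare
#'   prediction.
#' @param ... unused.
#' @return A `vsp_prediction`, or a `vsp_recommendation` when `guidelines`
#'   is supplied (`NULL` if nothing matched).
#' @export
predict.vsp <- function(object, newdata, guidelines = NULL, ...) {
  buf <- if (inherits(newdata, "event_sequence")) newdata
  else discretize_stream(newdata, tick_width = object$params$tick_width,
                         include_normal = object$params$include_normal)
  pred <- match_predict(object$rules, buf, window = object$params$window)
  if (is.null(guidelines)) pred else recommend(pred, guidelines)
}

#' @export
plot.vsp <- function(x, max = 15L, ...) {
  df <- as.data.frame(x$episodes)
  if (nrow(df) == 0L) {
    graphics::plot.new()
    graphics::title("No frequent episodes")
    return(invisible(x))
  }
  df <- df[order(-df$support), ][seq_len(min(nrow(df), max)), ]
  op <- graphics::par(mar = c(5, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(df$support), names.arg = rev(df$episode),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "support (minimal occurrences)",
                    main = "Frequent episodes", ...)
  invisible(x)
}
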