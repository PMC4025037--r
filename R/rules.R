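# Episode rules: X -> Y where X.Y is a frequent episode and confidence is
# sup(X.Y) / sup(X) on minimal-occurrence counts. All prefix/suffix splits
# are emitted, so multi-step antecedents such as
# "(Tachycardia), (Prehypertension) -> (Prehypertension)" arise naturally.

#' Generate episode rules from mined episodes
#'
#' Every frequent episode of length >= 2 is split at every position into a
#' non-empty antecedent prefix and consequent suffix; the split becomes a
#' rule when the full episode meets `min_support` and the confidence
#' `support(full) / support(antecedent)` reaches `min_confidence`. Rules are
#' ranked by confidence (descending), then support (descending), then
#' canonical key — the matching order used for prediction.
#'
#' @param episodes an `episode_set` from [mine_episodes()] (its occurrence
#'   counts provide both numerator and denominator).
#' @param min_support minimum support of the concatenated episode; defaults
#'   to the mining threshold attached to `episodes`.
#' @param min_confidence minimum confidence in \[0, 1\] (default 0.7).
#' @return A `vsp_rules` data frame with columns `antecedent`, `consequent`
#'   (canonical episode keys), `support` and `confidence`.
#' @examples
#' w1 <- window_sequence(vsp_example_sequence(), 1, 4)
#' ep <- mine_episodes(w1, min_support = 2, window = 4)
#' generate_rules(ep, min_confidence = 0.5)
#' @export
generate_rules <- function(episodes, min_support = NULL, min_confidence = 0.7) {
  stopifnot(inherits(episodes, "episode_set"))
  if (is.null(min_support)) min_support <- attr(episodes, "min_support")
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must lie in [0, 1]")
  sup <- vapply(episodes, `[[`, integer(1), "support")
  names(sup) <- vapply(episodes, `[[`, character(1), "key")
  ant <- con <- full <- character(0)
  rsup <- integer(0); rconf <- numeric(0)
  for (ent in episodes) {
    k <- length(ent$steps)
    if (k < 2L || ent$support < min_support) next
    for (cut in seq_len(k - 1L)) {
      a_key <- episode_key(ent$steps[seq_len(cut)])
      s_a <- sup[[a_key]]
      if (is.null(s_a) || is.na(s_a)) next  # antecedent not in the set
      conf <- ent$support / s_a
      if (conf >= min_confidence) {
        ant <- c(ant, a_key)
        con <- c(con, episode_key(ent$steps[seq(cut + 1L, k)]))
        full <- c(full, ent$key)
        rsup <- c(rsup, ent$support)
        rconf <- c(rconf, conf)
      }
    }
  }
  ord <- order(-rconf, -rsup, full, method = "radix")
  structure(data.frame(antecedent = ant[ord], consequent = con[ord],
                       support = rsup[ord], confidence = rconf[ord],
                       stringsAsFactors = FALSE),
            min_support = as.integer(min_support),
            min_confidence = min_confidence,
            class = c("vsp_rules", "data.frame"))
}

#' @export
print.vsp_rules <- function(x, max = 15L, ...) {
  cat(sprintf("Episode rules: %d (min support %s, min confidence %s)\n",
              nrow(x), attr(x, "min_support"), attr(x, "min_confidence")))
  if (nrow(x) > 0L) {
    shown <- utils::head(x, max)
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %s => %s   (sup %d, conf %.3f)\n",
                  format_episode(parse_episode(shown$antecedent[i])),
                  format_episode(parse_episode(shown$consequent[i])),
                  shown$support[i], shown$confidence[i]))
    if (nrow(x) > max) cat(sprintf("  ... %d more\n", nrow(x) - max))
  }
  invisible(x)
}

#' Write / read an episode rule base as JSON
#'
#' @param x a `vsp_rules` object.
#' @param path file path.
#' @export
write_rules <- function(x, path) {
  stopifnot(inherits(x, "vsp_rules"))
  recs <- lapply(seq_len(nrow(x)), function(i)
    list(antecedent = lapply(parse_episode(x$antecedent[i]), as.list),
         consequent = lapply(parse_episode(x$consequent[i]), as.list),
         support = x$support[i], confidence = x$confidence[i]))
  jsonlite::write_json(list(min_support = attr(x, "min_support"),
                            min_confidence = attr(x, "min_confidence"),
                            rules = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(obj$rules)
  df <- data.frame(
    antecedent = vapply(obj$rules, function(r)
      episode_key(lapply(r$antecedent, function(s) unlist(s, use.names = FALSE))),
      character(1)),
    consequent = vapply(obj$rules, function(r)
      episode_key(lapply(r$consequent, function(s) unlist(s, use.names = FALSE))),
      character(1)),
    support = vapply(obj$rules, function(r) as.integer(r$support), integer(1)),
    confidence = vapply(obj$rules, function(r) as.numeric(r$confidence), numeric(1)),
    stringsAsFactors = FALSE)
  if (n == 0L)
    df <- data.frame(antecedent = character(0), consequent = character(0),
                     support = integer(0), confidence = numeric(0))
  structure(df, min_support = as.integer(obj$min_support),
            min_confidence = as.numeric(obj$min_confidence),
            class = c("vsp_rules", "data.frame"))
}

#' Match a rule base against the live event buffer and predict
#'
#' Scans the rules in priority order (confidence, then support, then key): a
#' rule matches when its antecedent has an occurrence inside the buffer whose
#' final step lies exactly at the most recent tick (anchored-suffix match);
#' earlier steps are located backwards through the buffer. The first matching
#' rule fires and its consequent steps become the predicted states for the
#' next tick(s).
#'
#' @param rules a `vsp_rules` object.
#' @param buffer an [event_sequence()] holding the most recent ticks.
#' @param window optional span bound in ticks for the matched occurrence
#'   (antecedent plus predicted steps would fall inside one window).
#' @return A `vsp_prediction`: `states` (event set predicted one tick ahead;
#'   empty if nothing matched), `steps` (full consequent), `horizon`, and the
#'   matched `rule` (or `NULL`).
#' @examples
#' buf <- event_sequence(1, list("Pulse_H"))
#' rules <- structure(data.frame(antecedent = "Pulse_H", consequent = "BP_HB",
#'                               support = 9L, confidence = 0.9),
#'                    class = c("vsp_rules", "data.frame"))
#' match_predict(rules, buf)$states  # "BP_HB"
#' @export
match_predict <- function(rules, buffer, window = NULL) {
  stopifnot(inherits(rules, "vsp_rules"), inherits(buffer, "event_sequence"))
  none <- structure(list(states = character(0), steps = list(),
                         horizon = integer(0), rule = NULL),
                    class = "vsp_prediction")
  n <- length(buffer$tick)
  if (n == 0L || nrow(rules) == 0L) return(none)
  latest <- buffer$tick[n]
  lower <- if (is.null(window)) -Inf else latest - window + 1
  for (i in seq_len(nrow(rules))) {
    ant <- parse_episode(rules$antecedent[i])
    k <- length(ant)
    if (!all(ant[[k]] %in% buffer$events[[n]])) next
    cur <- latest
    ok <- TRUE
    if (k > 1L) {
      for (j in seq(k - 1L, 1L)) {
        idx <- which(buffer$tick < cur &
                       vapply(buffer$events, function(ev)
                         all(ant[[j]] %in% ev), logical(1)))
        if (length(idx) == 0L) { ok <- FALSE; break }
        cur <- buffer$tick[max(idx)]  # latest feasible: maximises the start
      }
      if (ok && cur < lower) ok <- FALSE
    }
    if (ok) {
      con <- parse_episode(rules$consequent[i])
      return(structure(list(states = con[[1]], steps = con,
                            horizon = seq_along(con),
                            rule = list(antecedent = rules$antecedent[i],
                                        consequent = rules$consequent[i],
                                        support = rules$support[i],
                                        confidence = rules$confidence[i])),
                       class = "vsp_prediction"))
    }
  }
  none
}

#' @export
print.vsp_prediction <- function(x, ...) {
  if (length(x$states) == 0L) {
    cat("No rule matched; no prediction.\n")
  } else {
    cat(sprintf("Predicted next state: {%s}\n", paste(x$states, collapse = " ")))
    if (length(x$steps) > 1L)
      cat(sprintf("  further horizon: %s\n",
                  format_episode(x$steps[-1])))
    cat(sprintf("  via rule %s => %s (sup %d, conf %.3f)\n",
                format_episode(parse_episode(x$rule$antecedent)),
                format_episode(parse_episode(x$rule$consequent)),
                x$rule$support, x$rule$confidence))
  }
  invisible(x)
}

.pattern_key <- function(states) paste(sort(unique(as.character(states))),
                                       collapse = ",")

#' Read a care-guideline map
#'
#' Accepts a two/three-column TSV (`pattern<TAB>text[<TAB>id]`, where
#' `pattern` lists state labels separated by spaces or commas) or a JSON
#' array of `{"pattern": [...], "text": "...", "id": "..."}` objects.
#'
#' @param path file path.
#' @return A `guideline_map` data frame with columns `pattern` (canonical
#'   state-set key), `text` and `id`.
#' @export
read_guidelines <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    pat <- vapply(obj, function(r)
      .pattern_key(unlist(r$pattern, use.names = FALSE)), character(1))
    txt <- vapply(obj, function(r) as.character(r$text), character(1))
    id <- vapply(obj, function(r)
      if (is.null(r$id)) NA_character_ else as.character(r$id), character(1))
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 2L) stop("guideline file needs at least pattern and text columns")
    pat <- vapply(strsplit(df[[1]], "[ ,]+"), .pattern_key, character(1))
    txt <- df[[2]]
    id <- if (ncol(df) >= 3L) as.character(df[[3]]) else rep(NA_character_, nrow(df))
  }
  if (anyDuplicated(pat)) stop("guideline patterns must be unique")
  structure(data.frame(pattern = pat, text = txt, id = id,
                       stringsAsFactors = FALSE),
            class = c("guideline_map", "data.frame"))
}

#' Attach a care guideline to a prediction
#'
#' Looks the predicted state set up in the guideline map: first as an exact
#' set match, then label by label as a fallback. When no guideline is on
#' file the predicted states are returned alone, flagged `"state-only"`; an
#' empty prediction yields no recommendation (`NULL`).
#'
#' @param prediction a `vsp_prediction` from [match_predict()].
#' @param guidelines a `guideline_map` from [read_guidelines()] (or any data
#'   frame with columns `pattern`, `text`, `id`), or `NULL`.
#' @return `NULL` for an empty prediction; otherwise a `vsp_recommendation`
#'   with fields `states`, `type` (`"guideline"` or `"state-only"`),
#'   `guidelines` (data frame of matched entries, possibly empty).
#' @export
recommend <- function(prediction, guidelines = NULL) {
  stopifnot(inherits(prediction, "vsp_prediction"))
  if (length(prediction$states) == 0L) return(NULL)
  key <- .pattern_key(prediction$states)
  hits <- NULL
  if (!is.null(guidelines) && nrow(guidelines) > 0L) {
    exact <- guidelines[guidelines$pattern == key, , drop = FALSE]
    hits <- if (nrow(exact) > 0L) exact else
      guidelines[guidelines$pattern %in% prediction$states, , drop = FALSE]
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(pattern = character(0), text = character(0),
                       id = character(0), stringsAsFactors = FALSE)
    type <- "state-only"
  } else type <- "guideline"
  structure(list(states = prediction$states, type = type, guidelines = hits,
                 rule = prediction$rule),
            class = "vsp_recommendation")
}

#' @export
print.vsp_recommendation <- function(x, ...) {
  cat(sprintf("Predicted state {%s}", paste(x$states, collapse = " ")))
  if (x$type == "guideline") {
    cat(":\n")
    for (i in seq_len(nrow(x$guidelines)))
      cat("  - ", x$guidelines$text[i], "\n", sep = "")
  } else cat("  [no guideline on file]\n")
  invisible(x)
}

#' Precision, recall and F-measure of state predictions
#'
#' Positions are scored one-vs-rest per category, a category being one
#' distinct state set (so a combined state such as
#' `(Pulse_H, BP_HB)` is its own class, distinct from `BP_HB` alone). With
#' `average = "macro"` (default) precision and recall are averaged over the
#' M observed categories and F = 2PR/(P+R) is taken on the averages;
#' `average = "micro"` pools the counts first. A class never predicted
#' contributes precision 0, a class never true contributes recall 0.
#'
#' @param predicted,truth equal-length lists of state sets (character
#'   vectors), or character vectors of state-set keys.
#' @param average `"macro"` (default) or `"micro"`.
#' @return A `vsp_eval` object: `per_class` counts, `precision`, `recall`,
#'   `f_measure`, and `M`.
#' @examples
#' evaluate_predictions(list("X", "Y", "Y"), list("X", "X", "Y"))
#' @export
evaluate_predictions <- function(predicted, truth,
                                 average = c("macro", "micro")) {
  average <- match.arg(average)
  as_keys <- function(x) {
    if (is.character(x)) return(vapply(strsplit(x, "[ ,]+"), .pattern_key,
                                       character(1)))
    vapply(x, .pattern_key, character(1))
  }
  p <- as_keys(predicted); t <- as_keys(truth)
  if (length(p) != length(t))
    stop("predicted and truth must have equal length")
  cats <- sort(unique(c(p, t)), method = "radix")
  tp <- vapply(cats, function(k) sum(p == k & t == k), integer(1))
  fp <- vapply(cats, function(k) sum(p == k & t != k), integer(1))
  fn <- vapply(cats, function(k) sum(p != k & t == k), integer(1))
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  if (average == "macro") {
    prec <- mean(safe_div(tp, tp + fp))
    rec <- mean(safe_div(tp, tp + fn))
  } else {
    prec <- safe_div(sum(tp), sum(tp) + sum(fp))
    rec <- safe_div(sum(tp), sum(tp) + sum(fn))
  }
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(per_class = data.frame(category = cats, TP = tp, FP = fp,
                                        FN = fn, row.names = NULL,
                                        stringsAsFactors = FALSE),
                 precision = prec, recall = rec, f_measure = f,
                 M = length(cats), average = average),
            class = "vsp_eval")
}

#' @export
print.vsp_eval <- function(x, ...) {
  cat(sprintf("%s-averaged over %d categories:\n", x$average, x$M))
  cat(sprintf("  precision %.4f  recall %.4f  F-measure %.4f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}
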