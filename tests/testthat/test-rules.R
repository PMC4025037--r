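test_that("rule confidence is the support ratio of the printed counts", {
  w1 <- window_sequence(vsp_example_sequence(), 1, 4)
  ep <- mine_episodes(w1, min_support = 2, window = 4)
  rules <- generate_rules(ep, min_confidence = 0)
  bb <- rules[rules$antecedent == "B" & rules$consequent == "B", ]
  expect_equal(bb$confidence, 3 / 4)   # sup(BB)=3 over sup(B)=4
  expect_equal(bb$support, 3L)
  expect_true(all(rules$confidence > 0 & rules$confidence <= 1))
  expect_error(generate_rules(ep, min_confidence = 1.5), "\\[0, 1\\]")
})

test_that("length-1 episodes yield no rules and thresholds filter", {
  one <- event_sequence(1, list("A"))
  ep <- mine_episodes(one, min_support = 1)
  expect_identical(nrow(generate_rules(ep, min_confidence = 0)), 0L)
  w1 <- window_sequence(vsp_example_sequence(), 1, 4)
  ep2 <- mine_episodes(w1, min_support = 2, window = 4)
  strict <- generate_rules(ep2, min_confidence = 0.9)
  expect_true(all(strict$confidence >= 0.9))
})

test_that("multi-step splits are emitted: both cut points of a length-3 episode", {
  w1 <- window_sequence(vsp_example_sequence(), 1, 4)
  ep <- mine_episodes(w1, min_support = 2, window = 4)
  rules <- generate_rules(ep, min_confidence = 0)
  bbb <- rules[vapply(seq_len(nrow(rules)), function(i)
    paste(rules$antecedent[i], rules$consequent[i], sep = "|"),
    character(1)) == "B|B|B", ]
  expect_identical(sort(bbb$antecedent), c("B", "B|B"))
})

test_that("rule order is a deterministic total order", {
  w1 <- window_sequence(vsp_example_sequence(), 1, 4)
  ep <- mine_episodes(w1, min_support = 2, window = 4)
  r1 <- generate_rules(ep, min_confidence = 0)
  r2 <- generate_rules(mine_episodes(w1, min_support = 2, window = 4),
                       min_confidence = 0)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$confidence) <= 0))
  ties <- which(diff(r1$confidence) == 0)
  expect_true(all(r1$support[ties] >= r1$support[ties + 1L]))
})

test_that("matching is anchored at the newest tick and first match wins", {
  rules <- structure(
    data.frame(antecedent = c("Pulse_H", "BP_HB"),
               consequent = c("BP_HB", "BP_H1"),
               support = c(9L, 5L), confidence = c(0.9, 0.8),
               stringsAsFactors = FALSE),
    min_support = 2L, min_confidence = 0.5,
    class = c("vsp_rules", "data.frame"))
  buf <- event_sequence(1:2, list("BP_HB", "Pulse_H"))
  pred <- match_predict(rules, buf)
  expect_identical(pred$states, "BP_HB")   # anchored at the latest tick
  expect_identical(pred$rule$antecedent, "Pulse_H")
  # BP_HB is present at tick 1 but not at the buffer head: no match
  none <- match_predict(rules[2, ], buf)
  expect_length(none$states, 0L)
  expect_null(none$rule)
  empty_rules <- structure(rules[0, ], class = c("vsp_rules", "data.frame"))
  expect_length(match_predict(empty_rules, buf)$states, 0L)
})

test_that("equal-confidence ties fire the higher-support rule", {
  # U->Y: support 8 of 10 (conf 0.8); T->X: support 4 of 5 (conf 0.8)
  u_ticks <- seq(1, 19, by = 2); y_ticks <- seq(2, 16, by = 2)
  t_ticks <- seq(30, 38, by = 2); x_ticks <- seq(31, 37, by = 2)
  ticks <- sort(c(u_ticks, y_ticks, t_ticks, x_ticks))
  events <- lapply(ticks, function(tk)
    if (tk %in% u_ticks) "U" else if (tk %in% y_ticks) "Y"
    else if (tk %in% t_ticks) "T" else "X")
  seq <- event_sequence(ticks, events)
  rules <- generate_rules(mine_episodes(seq, min_support = 2, window = 2),
                          min_confidence = 0)
  uy <- rules[rules$antecedent == "U" & rules$consequent == "Y", ]
  tx <- rules[rules$antecedent == "T" & rules$consequent == "X", ]
  expect_equal(uy$confidence, 0.8)
  expect_equal(tx$confidence, 0.8)
  expect_gt(uy$support, tx$support)
  # both antecedents match a buffer ending in {T, U}; higher support wins
  pred <- match_predict(rules, event_sequence(50, list(c("T", "U"))))
  expect_identical(pred$states, "Y")
  # exhaustive-scan oracle over all matching rules
  matching <- rules[rules$antecedent %in% c("T", "U"), ]
  best <- matching[order(-matching$confidence, -matching$support), ][1, ]
  expect_identical(pred$rule$consequent, best$consequent)
})

test_that("multi-step antecedents must occur in order within the buffer", {
  rules <- structure(
    data.frame(antecedent = "Pulse_H|BP_HB", consequent = "BP_HB",
               support = 4L, confidence = 0.8, stringsAsFactors = FALSE),
    class = c("vsp_rules", "data.frame"))
  hit <- event_sequence(1:2, list("Pulse_H", "BP_HB"))
  expect_identical(match_predict(rules, hit)$states, "BP_HB")
  wrong_order <- event_sequence(1:2, list("BP_HB", "Pulse_H"))
  expect_length(match_predict(rules, wrong_order)$states, 0L)
  too_old <- event_sequence(c(1, 9), list("Pulse_H", "BP_HB"))
  expect_length(match_predict(rules, too_old, window = 4)$states, 0L)
})

test_that("recommendations fall back from exact set to per-label to state-only", {
  gl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("BP_HB\trecheck blood pressure in 15 minutes\tG1",
               "Pulse_H BP_HB\tassess perfusion and notify physician\tG2"),
             gl)
  gm <- read_guidelines(gl)
  pred <- structure(list(states = c("Pulse_H", "BP_HB"),
                         steps = list(c("Pulse_H", "BP_HB")),
                         horizon = 1L, rule = NULL), class = "vsp_prediction")
  rec <- recommend(pred, gm)
  expect_identical(rec$type, "guideline")
  expect_identical(rec$guidelines$id, "G2")  # exact set match preferred
  solo <- structure(list(states = "BP_HB", steps = list("BP_HB"),
                         horizon = 1L, rule = NULL), class = "vsp_prediction")
  expect_match(recommend(solo, gm)$guidelines$text, "recheck")
  unknown <- structure(list(states = "BP_H2", steps = list("BP_H2"),
                            horizon = 1L, rule = NULL), class = "vsp_prediction")
  expect_identical(recommend(unknown, gm)$type, "state-only")
  expect_identical(recommend(unknown, NULL)$type, "state-only")
  none <- structure(list(states = character(0), steps = list(),
                         horizon = integer(0), rule = NULL),
                    class = "vsp_prediction")
  expect_null(recommend(none, gm))
})

test_that("guideline JSON and TSV readers agree", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("BP_HB\trecheck\tG1", tsv)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"pattern": ["BP_HB"], "text": "recheck", "id": "G1"}]', js)
  expect_identical(read_guidelines(tsv), read_guidelines(js))
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("BP_HB\ta", "BP_HB\tb"), dup)
  expect_error(read_guidelines(dup), "unique")
})

test_that("evaluation reproduces the hand confusion matrix", {
  perfect <- evaluate_predictions(list("X", "Y"), list("X", "Y"))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_measure, 1)

  ev <- evaluate_predictions(list("X", "Y", "Y"), list("X", "X", "Y"))
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f_measure, 0.75)
  expect_identical(ev$M, 2L)
  pc <- ev$per_class
  expect_identical(pc$TP[pc$category == "X"], 1L)
  expect_identical(pc$FN[pc$category == "X"], 1L)
  expect_identical(pc$FP[pc$category == "Y"], 1L)

  single <- evaluate_predictions(list("X", "X"), list("X", "X"))
  expect_equal(single$precision, 1)
  expect_identical(single$M, 1L)
  expect_error(evaluate_predictions(list("X"), list("X", "Y")), "equal length")
})

test_that("evaluation treats combined state sets as their own categories", {
  ev <- evaluate_predictions(list(c("Pulse_H", "BP_HB")), list("BP_HB"))
  expect_identical(ev$M, 2L)
  expect_equal(ev$precision, 0)
  micro <- evaluate_predictions(list("X", "Y", "Y"), list("X", "X", "Y"),
                                average = "micro")
  expect_equal(micro$precision, 2 / 3)
  expect_equal(micro$recall, 2 / 3)
})

test_that("evaluation is equivariant under joint permutation", {
  set.seed(9)
  p <- sample(c("X", "Y", "Z"), 30, replace = TRUE)
  t <- sample(c("X", "Y", "Z"), 30, replace = TRUE)
  a <- evaluate_predictions(p, t)
  perm <- sample(30)
  b <- evaluate_predictions(p[perm], t[perm])
  expect_equal(a[c("precision", "recall", "f_measure")],
               b[c("precision", "recall", "f_measure")])
})

test_that("rule bases round-trip through JSON", {
  w1 <- window_sequence(vsp_example_sequence(), 1, 4)
  rules <- generate_rules(mine_episodes(w1, min_support = 2, window = 4),
                          min_confidence = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(as.data.frame(back), as.data.frame(rules))
  expect_identical(attr(back, "min_support"), attr(rules, "min_support"))
})
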