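# vspredictor

Early-warning prediction of vital-sign states from monitoring streams, for
health-informatics researchers and engineers building caregiver-support
tools. The package turns timestamped measurements of blood pressure, pulse
oximetry and heart rate into discrete clinical states, mines the resulting
event sequence for frequent **serial episodes**, keeps the episode table up
to date under a **sliding window** as the stream advances, derives
confidence-ranked **episode rules**, and uses them to predict the state a
patient is heading into — optionally mapped to a care guideline.

## The model

A discretized stream is a *complex event sequence*: ticks `t = 1, 2, ...`,
each with a set of simultaneous states (e.g. `{Pulse_H, BP_HB}` —
tachycardia with prehypertension). A serial episode `s1 -> s2 -> ... -> sk`
occurs in an interval when its steps appear at strictly increasing ticks; a
**minimal occurrence** is an interval containing an occurrence such that no
proper sub-interval does. Support is the number of minimal occurrences with
span inside the window:

    sup(α) = #{ [s, e] minimal occurrence of α : e − s < window }

Mining is candidate-free pattern growth over a simultaneous-event prefix
tree, with minimal-occurrence lists maintained by an exact join (support is
provably anti-monotone under prefix extension, so growing frequent episodes
only is complete). Online, the window update deletes occurrences anchored at
the expired tick and temporally joins each tracked episode with the arriving
events; after every slide the table equals batch re-mining of the window
contents. Rules are all prefix/suffix splits of frequent episodes,

    conf(X -> Y) = sup(X·Y) / sup(X),

ordered by confidence, support, then canonical key; prediction matches
antecedents anchored at the newest buffer tick and the first match fires.
Prediction quality is scored by macro-averaged precision, recall and
F-measure over the observed state-set categories.

## Worked example

The bundled abstract sequence (`vsp_example_sequence()`) is small enough to
check every number by hand. Mining its first four ticks at minimum support
count 2 with a 4-tick window:

```r
library(vspredictor)
s <- vsp_example_sequence()
fit <- vsp(window_sequence(s, 1, 4), min_support = 2, window = 4,
           min_confidence = 0.5)
fit
#> Vital-signs state predictor
#>   events: 4 tick(s); frequent episodes: 15; rules: 18
#>   min support 2, min confidence 0.5, window 4 tick(s)
```

The frequent table contains `A:2, B:4, C:3, AB:2, BB:3, BC:2, CB:3, CC:2,
BBB:2` (and the rest of the frequent closure, e.g. `CBB:2`). Note `B -> C`
(support 2) and `C -> B` (support 3) differ — episodes are directional. The
top rules:

```r
fit$rules
#> Episode rules: 18 (min support 2, min confidence 0.5)
#>   C => B   (sup 3, conf 1.000)
#>   A => B   (sup 2, conf 1.000)
#>   ...
#>   B => B   (sup 3, conf 0.750)
```

`C => B` at confidence 1.000 means every windowed minimal occurrence of `C`
extends to one of `C -> B`; `B => B` has confidence `sup(BB)/sup(B) = 3/4`.

Sliding the window — deleting tick 1, adding `{A}` at tick 5 — updates the
frequent table to `A:2, B:3, C:2, BB:2, CB:2` incrementally, and
`check_batch()` verifies the result equals re-mining from scratch:

```r
w <- sliding_window(width = 4, min_support = 2)
for (i in 1:4) slide(w, s$tick[i], s$events[[i]])
delete_oldest_events(w, 1)
add_new_events(w, 5, "A")
#> frequent:           A:2, B:3, B -> B:2, C:2, C -> B:2
#> ...
check_batch(w)
#> [1] TRUE
```

On a synthetic clinical stream with a planted dependency (tachycardia →
prehypertension at probability 0.9 under 5 % background noise), the fitted
predictor recovers the planted rule and predicts from a live buffer:

```r
fit2 <- vsp(simulate_vitals(n_ticks = 500, seed = 1), min_confidence = 0.7)
coef(fit2)
#>                               support confidence
#> Pulse_L -> Pulse_H => BP_HB         2  1.0000000
#> SpO2_Lmid -> Pulse_H => BP_HB       2  1.0000000
#> Pulse_H => BP_HB                   13  0.9285714
predict(fit2, event_sequence(1, list("Pulse_H")))
#> Predicted next state: {BP_HB}
#>   via rule Pulse_H => BP_HB (sup 13, conf 0.929)
```

The recovered confidence (0.93 here) estimates the planted firing
probability; a guideline map passed to `predict()` turns the prediction into
a care recommendation.

A command-line interface wrapping the same functions is installed at
`inst/cli/vsp.R` (subcommands `simulate`, `discretize`, `mine`, `rules`,
`stream`, `predict`, `evaluate`).

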