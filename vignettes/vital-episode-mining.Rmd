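---
title: "Mining vital-sign episodes and predicting the next state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining vital-sign episodes and predicting the next state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vspredictor)
```

## The problem

Continuous monitoring of a patient's blood pressure, oxygen saturation and
heart rate produces a stream of numbers; what a caregiver needs is advance
notice of the *state* the patient is heading into — "tachycardia now tends to
be followed by prehypertension a minute later". `vspredictor` implements that
pipeline as four cooperating stages:

1. **Discretization** — measurements become labelled clinical states on a
   discrete time axis, forming a *complex event sequence*: a series of ticks,
   each carrying a set of simultaneous states.
2. **Episode mining** — frequent *serial episodes* (ordered patterns of
   states) are counted by their minimal occurrences.
3. **Sliding-window maintenance** — the episode table follows the stream in
   real time: expired events are deleted, new events are joined in, without
   re-mining from scratch.
4. **Rules and prediction** — episode rules `X -> Y` ranked by confidence
   match the live buffer and predict the next state, optionally mapped to a
   care guideline.

## Discretization

The classifiers use standard clinical staging bands:

| signal | state | band |
|---|---|---|
| blood pressure | `BP_HB` (prehypertension) | 120–139 / 80–89 mmHg |
| | `BP_H1` (stage 1) | 140–159 / 90–99 mmHg |
| | `BP_H2` (stage 2) | ≥ 160 / ≥ 100 mmHg |
| SpO2 | `SpO2_Lmicro` (mild hypoxemia) | < 94 % |
| | `SpO2_Lmid` (moderate) | < 89 % |
| | `SpO2_Lhard` (severe) | < 75 % |
| heart rate | `Pulse_H` (tachycardia) | > 100 bpm |
| | `Pulse_L` (bradycardia) | < 60 bpm |
| any | `N` | otherwise |

Three conventions make classification total and unambiguous:

* A blood-pressure reading is staged by the **most severe** component:
  125/92 mmHg is stage 1 because the diastolic criterion dominates. Range
  bounds of the form 120–139 are inclusive; the heart-rate thresholds are
  strict as written (100 bpm is normal, 101 is tachycardia).
* The hypoxemia bands overlap as printed ("< 94", "< 89", "< 75"); they are
  resolved most-severe-first, yielding half-open bands.
* Ticks are 1-based (`floor(timestamp / tick_width) + 1`), with a
  configurable `tick_width` defaulting to 60 s. When several samples of one
  signal land in a tick, the **last one wins** — monitoring semantics: the
  freshest reading describes the tick.

Normal (`N`) events are dropped by default (`include_normal = FALSE`) and
ticks holding nothing else are omitted: downstream mining is about patterns
among *abnormal* states, and keeping `N` would let near-constant normal
events dominate every support count. The flag exists because the opposite
convention is defensible when normality itself is the signal of interest.

```{r}
discretize_stream(data.frame(
  subject = "p1", timestamp = c(0, 0, 0),
  signal = c("HR", "SYS_BP", "DIA_BP"), value = c(120, 130, 85)))
```

## Episodes and minimal occurrences

A *serial episode* is an ordered sequence of steps occurring at strictly
increasing ticks (each step in general a set of simultaneous states; the
miner grows single-state steps). An interval `[s, e]` is a **minimal
occurrence** when it contains an occurrence of the episode but no proper
sub-interval does; *support* is the number of minimal occurrences whose span
stays inside the window (`e - s < window`). Serial direction matters:
on the bundled example sequence `B -> C` has support 2 while `C -> B` has
support 3.

```{r}
s <- vsp_example_sequence()
w1 <- window_sequence(s, 1, 4)
minimal_occurrences(c("C", "B"), w1, window = 4)
```

`minimal_occurrences()` computes straight from this definition (greedy
earliest completion per start, then removal of dominated intervals) and acts
as the reference count in the test suite; the miner never calls it.

## The prefix tree and pattern growth

One scan of the sequence builds a prefix tree: each tick's event set, sorted
lexicographically, is a root-to-node path, identical sets share a path, and
only the terminal node records the tick. A header table links every tick to
its leaf, so "which events are present at tick t" is answered from the tree.

`mine_episodes()` grows episodes candidate-free: single events seed the
search and each frequent episode is extended by the events the tree reports
within reach of its occurrences. Minimal-occurrence lists are maintained by
a join: a minimal occurrence `[b, u]` of a prefix extends to the candidate
`[b, t]` with `t` the first later tick carrying the appended event, and
among candidates sharing an end only the latest start survives.

Two facts justify the search strategy; both are exercised by randomized
property tests against brute force:

* **The join recurrence is exact.** Every minimal occurrence of the
  extension arises from a minimal occurrence of the prefix with the same
  start, so the maintained lists equal the definitional ones.
* **Support is anti-monotone under prefix (and, by time reversal, suffix)
  extension**, so growing only frequent episodes is complete. It is *not*
  anti-monotone under deletion of interior steps — on the sequence
  `{A}, {A,B}, {C}, {B}, {C}` the episode `A -> B -> C` has two minimal
  occurrences while its sub-episode `A -> C` has one — so the miner prunes
  on prefixes only.

The mined set is therefore the *complete* frequent closure. On the bundled
example this includes, besides the familiar nine episodes `A:2, B:4, C:3,
AB:2, BB:3, BC:2, CB:3, CC:2, BBB:2`, the equally frequent length-3
episodes (`CBB`, `ACB`, …) that a quick manual enumeration easily misses —
completeness is asserted against brute force rather than against a curated
list. `max_len` (default 5) caps growth as a guard; observed clinical
patterns are short.

## Sliding-window maintenance

Online, only the most recent `width` ticks matter (tick `t` is live while
`newest - t < width`). Two incremental operations keep the episode table
equal to batch re-mining of the window contents after every slide — the
central correctness property, asserted on hundreds of randomized streams:

* **Events deletion.** The expired tick is the oldest, so it can only be
  the *start* of a minimal occurrence; occurrences anchored there are
  dropped, supports recount, episodes left with no occurrence leave the
  table.
* **Events addition.** A new tick can only *end* occurrences. For each
  tracked episode with an occurrence finishing before the new tick, the
  temporal join forms the extension ending in the new event with the single
  candidate occurrence `[b, t]`, `b` the latest feasible start; the
  candidate is kept unless an existing occurrence nests inside it or the
  span leaves the window.

A design choice follows from the correctness requirement: the window tracks
**every** episode with at least one windowed occurrence (up to `max_len`),
not only the frequent ones, and the join fires for every tracked episode
rather than only when the new event crosses the frequency threshold.
Restricting either — e.g. joining only newly frequent events — breaks batch
equivalence, because sub-threshold episodes can become frequent later.
Sub-threshold episodes are retained until their occurrences expire; memory
stays bounded by the window width and the length cap.

```{r}
w <- sliding_window(width = 4, min_support = 2)
for (i in 1:4) slide(w, s$tick[i], s$events[[i]])
delete_oldest_events(w, 1)
add_new_events(w, 5, "A")
check_batch(w)
```

## Rules, matching, recommendation

Rule generation splits every frequent episode of length ≥ 2 at every
position; `X -> Y` is kept when the concatenation meets the support
threshold and `confidence = sup(X·Y) / sup(X)` (on minimal-occurrence
counts — the natural definition given the statistics kept) reaches
`min_confidence`, default 0.7. Rules are ordered by confidence, then
support, then canonical key: a deterministic total order, so matching is
reproducible run to run.

Matching is **anchored at the buffer head**: a rule fires when its
antecedent occurs inside the recent buffer with its final step at the most
recent tick, scanning rules in priority order and stopping at the first
match. The consequent is asserted for the next tick (horizon 1; multi-step
consequents map to consecutive future ticks). Predictions are looked up in
the guideline map by exact state-set match, then label by label; with no
entry the state alone is reported ("state-only"), never silently dropped.

Evaluation scores positions one-vs-rest per category, a category being one
distinct state *set* (the combined state `(Pulse_H BP_HB)` is a class of
its own, distinct from `BP_HB`). Precision and recall are macro-averaged
over the M observed categories and F = 2PR/(P+R) is taken on the averages;
micro-averaging is available behind a flag for sensitivity analysis. The
macro default reflects the "average over M categories" reading of the
standard formulas; with heavy class imbalance — ubiquitous in clinical
states — the two can differ substantially, which is why both are offered. A
class never predicted contributes precision 0, a class never true
contributes recall 0.

## The synthetic generator

`simulate_vitals()` exists so every stage is testable end to end without
patient data. It emulates: healthy per-signal baselines (HR ~ N(80, 8) bpm,
systolic ~ N(115, 8), diastolic ~ N(72, 6) mmHg, SpO2 ~ N(97, 1.2) %, each
clipped into its normal band so an undisturbed stream discretizes entirely
to `N`); background abnormal excursions at 5 % per signal family per tick
into a uniformly chosen abnormal band; and planted temporal dependencies —
by default tachycardia at `t` placing prehypertension at `t + 1` with
probability 0.9, written as fixed representative in-band values (130/85
mmHg) that override noise at the target tick. Output is deterministic given
the seed.

What it does **not** emulate: autocorrelated physiology, drift, treatment
effects, missing channels, artefacts, or inter-patient variability. Passing
the recovery tests therefore shows the pipeline finds the dependencies it
is pointed at under honest noise — not that it handles real monitor data;
the discretization thresholds, not the generator, are the part carried over
from clinical practice unchanged.

## Problem sizes and numerical choices

The test suite validates at these scales, chosen to exercise the
combinatorics while keeping a full run around a minute: oracle equivalence
of the miner on 200 random sequences (alphabet ≤ 5, ≤ 25 ticks, ≤ 3 events
per tick, window ≤ 6, episode length ≤ 4); batch-equivalence of the sliding
window on 200 random streams of 10 slides each plus 30 longer streams;
planted-rule recovery on 50 seeded 500-tick streams, requiring the
tachycardia rule at confidence ≥ 0.7 in at least 90 % of runs.

Remaining conventions, for completeness: ties everywhere break
lexicographically (C-locale radix order) for determinism; empty ticks are
absent rather than empty sets; a blood-pressure tick carrying only one
component is classified on that component alone; `run_online()` refreshes
its rule base from the window every slide by default but keeps the last
non-empty base when a sparse window momentarily supports no rules; the
sliding window object has reference semantics (updates mutate in place), an
explicit departure from copy-on-modify R, chosen because the episode table
is a live index, not a value.

## Limitations

* Steps grown by the miner are single states; simultaneous-set *patterns*
  enter through matching (a step matches any tick whose set contains it)
  and through composite categories in evaluation, not through subset
  enumeration during growth, which would square the search space for little
  clinical gain.
* Minimal-occurrence support has known quirks: it is not anti-monotone
  under interior-step deletion, and a window bound is required for it to be
  meaningful on long streams.
* One window serves one subject; there is no cross-patient pooling online.
* Guideline content is the user's: the package ships the mapping mechanism,
  not clinical advice.
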