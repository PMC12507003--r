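---
title: "From RFID detections to social networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RFID detections to social networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burrowtrack)
```

`burrowtrack` reconstructs what every member of a group-housed colony of
burrowing rodents (the motivating system is the naked mole-rat) is doing,
around the clock, from nothing but RFID reader pings — and then asks two
questions of the reconstructed record: *do individuals have stable
behavioral phenotypes?* and *which pairs of individuals are socially
connected?* This vignette explains each stage of the pipeline, the
assumptions behind it, the tunable parameters and their defaults, and what
the synthetic-colony validation does and does not establish.

## The burrow as a 5×5 grid

The housing system is nine boxes in a 3×3 arrangement joined by twelve
pipes, with a ring-antenna RFID reader at each pipe end (24 readers). On
the grid model, boxes sit at the nine positions with both 0-based
coordinates even, pipes between adjacent boxes, and the four remaining
diagonal positions are void. `build_layout()` validates this description
and precomputes adjacency and box-to-box shortest paths.

## Location reconstruction

A reader ping places an animal in that reader's pipe. Between two pings
the animal is assigned the unique cell "between" the readers:

* both readers on one pipe → that pipe;
* readers on two pipes that meet at a box → that box;
* the same reader twice within 0.3 s → the pipe (it lingered inside the
  antenna ring); after more than 0.3 s → the box at that reader's end;
* non-adjacent readers → the interval is unknown (`NA`).

Choices the rules do not pin down, made here once: intervals are half-open
`[t_i, t_{i+1})` with 0.1-s ticks; the 0.3-s boundary is inclusive
(exactly 0.3 s → pipe); ticks before the first ping are unknown; the
interval after the final ping is resolved by applying the same-reader rule
against the recording end; simultaneous duplicate pings of one tag keep
the earlier record with a warning. The *tracking error rate* is the pooled
fraction of unknown ticks.

## Stay events and their categories

A stay event is a maximal run of ticks in one cell. The communal nest is
annotated automatically as the box with the highest mean occupant count in
a 6-hour window centered on each 10-s sample (ties to the lowest
(row, col); all-unknown windows carry the previous nest forward). Toilet
and garbage chambers are supplied as manual annotations.

Nest stays longer than 600 s are `Rest`; at most 600 s, `Nest`. Other
stays take the chamber's function at the event midpoint (`Toilet`,
`Garbage`) or `Other`. The 600-s threshold is a fixed practical value
sitting in the antimode between the two modes of the nest-stay duration
distribution (short visits of seconds versus multi-hour rests);
`find_duration_modes()` (kernel density on log-durations, Silverman
bandwidth) is provided to check that an antimode indeed lies there in any
given dataset, not to re-derive the threshold.

Three cleaning rules follow: stays over 600 s in pipes adjacent to the
current nest become `Rest` (animals rest in nest-adjacent tunnels);
non-nest boxes where five or more individuals co-reside continuously
(every 10-s sample) for over 600 s are sub-nests, whose long stays become
`Rest`; unknown gaps over 30 minutes are attributed to resting in the nest
(an animal parked in the nest generates no pings). Colony-wide
*disturbance phases* — maximal intervals with under 25% of the colony
resting including a dip under 10% — are detected on the 10-s rest-fraction
series and excluded from all downstream analyses.

## Daily behavior vectors and phenotype clustering

Each individual-day yields 23 parameters: Sum, N and Mean duration for
each of the five categories, plus Sum and N relative to the day's total
active (non-Rest) duration for the four non-Rest categories. Per colony,
each parameter is shifted by +1 (durations and counts can be 0) and
Box-Cox transformed at its maximum-likelihood λ, then z-scored within each
colony-day.

The normalized vectors are embedded to two dimensions with UMAP
(`n_neighbors = 5`, `min_dist = 0.1`, pinned seed, single-threaded so the
embedding is reproducible), binned onto a 512-px raster padded 5%,
smoothed with an isotropic Gaussian blur, and partitioned by watershed
segmentation with minima suppression at 5% of the density maximum. Each
sample takes the label of its watershed compartment; clusters are numbered
by descending size (cluster identities are data-specific). The default
blur bandwidth is adaptive, `raster / sqrt(n_samples)`, which tracks the
typical inter-point spacing — about 9 px for ~3000 samples and about 30 px
for 300 — because a fixed pixel bandwidth appropriate at one sample size
badly over- or under-segments at another. Both `blur_sigma` and `hmin`
remain exposed. Samples far outside the embedding (beyond 5 IQRs of the
centroid distance) are flagged; if ≥80% of one individual's samples are
flagged, the individual is excluded and the embedding recomputed.

## Consistency, co-assignment, leadership

With $P_i(k)$ the fraction of days individual $i$ is assigned to cluster
$k$ and $K$ clusters, the consistency index is
$1 - H_i/\ln K$ with $H_i = -\sum_k P_i(k)\ln P_i(k)$: 1 when a single
cluster is used, 0 when uniform. Its null draws 30 i.i.d. labels per
simulated individual from the pooled mean probabilities (10,000 draws at
full scale); the p-value is the add-one proportion of simulated indices at
least as large, which avoids exact zeros. The null takes the probability
vector as an argument, so the pooling can be global (the default reading
of "overall mean probability") or per colony at the caller's choice.

Colony-level day-to-day stability is the cosine similarity of consecutive
daily binary membership vectors per cluster, compared against within-day
element shuffles. The co-assignment index for clusters $(k,l)$ is
$\frac{1}{N}\sum_i P_i(k)P_i(l)$ over $\bar P(k)\bar P(l)$; values above 1
mark cluster pairs that recur within the same individuals. One analytic
caveat documented here because it matters for interpretation: with a
finite number of days the *diagonal* index does not converge to 1 under
independence but to $1 + (1-p)/(n_{\text{days}}\,p)$ (1.2 for uniform
$K = 7$ over 30 days) — only off-diagonal indices approach 1.

Leadership at a nest transition ranks individuals by their first `Rest`
onset in the new nest within a window from 2 h before to 12 h after the
transition (tied onsets share averaged ranks); transitions where at most
80% of the colony participates are discarded. Ranks are exported for
external modeling; ordinal model fitting is out of scope.

## Dyadic indices under cyclic-permutation nulls

Three relationship measures share one engine. For each (directed) dyad a
count is compared against surrogates built by circularly shifting one
member's vector — a null that preserves each individual's autocorrelation
while destroying cross-correlation:

* **Synchrony**: binary Rest/Active states at 10-s samples; count of
  samples in the same state; 9999 surrogates at full scale.
* **Proximity**: restricted to samples where both individuals are active
  and outside the nest; count of equal non-nest cells; the vectors are
  rebuilt over the restricted index set before shifting. 10-s samples
  (exposed as `interval_s`); 9999 surrogates at full scale.
* **Follow**: movement events (adjacent-cell transitions with their
  paths); a followee movement counts once if the follower repeats the
  identical path within a (0, 3]-second window. Surrogates keep the
  follower's movement *timing* fixed and circularly shift its *path*
  labels; 999 surrogates at full scale.

Shift offsets are drawn uniformly with replacement from 1..L−1. Missing
samples (disturbances, unknown gaps) are removed pairwise before shifting.
The index is the z-score of the actual count within its surrogate
distribution; the p-value ranks the actual value among actual-plus-
surrogates (add-one, own tail); dyads in the top or bottom 2.5% are
significantly high or low. A zero surrogate standard deviation (e.g. a
constant activity vector) leaves the index undefined and the dyad flagged
non-significant. Follow indices are Yeo-Johnson transformed and z-scored
across all directed dyads before comparison across groups.

Significantly high dyads form weighted networks (edge weight = index;
follow edges point follower → followee). Strength centrality is the sum of
incident edge weights, split into in-/out-strength for follow. Temporal
robustness re-runs the full dyadic pipeline in consecutive day blocks
(six 5-day blocks at full scale), re-deriving significance per block from
that block's own surrogates.

## The synthetic colony

No recording of the original system is deposited, so validation rests on
an agent-based generator whose planted structure the pipeline must
recover. Individuals alternate exponential rest bouts (in the nest) and
active bouts composed of *trips*: shortest-path walks to a destination box
with exponential pipe/box transit dwells and a longer destination dwell.
Defaults (per individual, overridable as vectors to plant phenotypes):
rest bout mean 5000 s, active bout mean 3600 s, destination dwell 30 s,
nest visit 6 s, transits 2 s — chosen to reproduce the field-typical
regime: a strongly bimodal nest-stay distribution (seconds versus hours),
roughly half the colony resting at any time, and thousands of reader
crossings per individual-day. The colony starts at its stationary
rest/active mix.

Planted structure:

* **Coupling** — every spontaneous rest onset is a colony-wide "rest
  call"; an active individual joins the caller with probability equal to
  the coupling entry and adopts the caller's bout end (jittered ≤30 s).
  Sharing whole bouts, not just onsets, is what makes pairwise synchrony
  tunable: with independent bout lengths the state correlation washes out.
* **Co-location** — each planted pair has a shared preferred destination
  box, redrawn hourly; a trip goes there with the planted probability.
* **Follow** — the follower shadows the followee's trajectory at a fixed
  delay drawn below the follow lag, bridging into and out of shadow
  episodes by shortest-path walks; strength 1 shadows the entire
  recording, so every followee movement is re-traced within the lag.
* **Disturbances** — Poisson episodes (default 2/day) of 10–30 min force
  everyone out of rest; interrupted resters re-settle with a 300-s mean
  delay after the episode ends.

Two numerical guards make the generator exactly consistent with the
tracker's inference rules: box dwells are floored at 0.4 s (just above the
0.3-s re-detection threshold, so a box visit is never mistaken for
lingering inside the antenna) and pipe transits at 1.6 ticks (so every
crossing is resolvable at tick resolution). Without the floors a small,
rule-inherent mismatch fraction is unavoidable — real data would contain
it, but oracle-equivalence tests should not.

What the generator does **not** emulate: within-chamber posture and
fine-scale movement, signal-strength noise or ghost reads (misses are
clean Bernoulli drops at crossings), task-related movement structure,
thermoregulatory huddling, breeding dynamics and circadian drift. Passing
the recovery tests therefore shows the *statistical machinery* is sound —
the rules are implemented faithfully and the nulls are calibrated — not
that the biological conclusions of any particular colony are correct.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run desk-scale versions of every
stage (sizes chosen to keep a full run in minutes): tracking
oracle-equivalence on 10 individuals × 2 h (noise-free reconstruction
matches truth at every defined tick; with 10% missed detections the error
rate equals the brute-force NA tally); stay-event time conservation and
strict Rest boundary; consistency-index anchors (1, 0, and a frozen
29-of-30-days value) plus null calibration over 2000 simulated individuals
× 999 draws, averaged over 10 replicate experiments because a single
999-draw null carries ±0.8 pp of threshold noise; co-assignment
independence on 200 individuals; permutation-null calibration on 210
unrelated dyads of a 21-individual, 2-day colony with 199 surrogates
(significant fraction, index mean and sd); recovery of 10 planted-coupled
versus 10 independent dyads over 20 seeds of a 20-individual, 2-day
colony; follow-direction recovery over 20 seeds; and recovery of three
planted phenotypes (30 individuals × 10 days, bout parameters
3000/5000/9000 s rest, 5000/3600/2000 s active, 15/30/60 s dwell) by the
full normalize–embed–watershed path, scored as mean adjusted Rand index
against the planted labels over 5 seeds — averaging because single-seed
ARI is dominated by whether the embedding fragments one phenotype into
two islands.

## Known limitations

* UMAP is only reproducible for a pinned seed, single thread and fixed
  package version; cluster *identities* are data-specific throughout.
* The watershed cluster count is sensitive to the blur bandwidth; the
  adaptive default is a rule of thumb, and both knobs are exposed.
* The trailing-interval rule can misplace an animal that ends the
  recording inside a pipe; with crossing-complete recordings this affects
  at most the final transit.
* Follow counting matches paths exactly; a follower taking a parallel
  route is not counted, mirroring the strict definition.
* The generator's movement model is an assumption-bearing stand-in, not a
  kinematic model of any real species.
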