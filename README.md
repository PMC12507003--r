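# burrowtrack

Continuous, colony-wide behavioral profiling of group-housed burrowing
rodents — the motivating system is the naked mole-rat, a eusocial mammal
living in colonies of ~20 animals — from raw RFID detection logs.
Laboratory burrows instrumented with ring-antenna readers produce a stream
of `(time, tag, reader)` pings; `burrowtrack` turns that stream into
tick-level grid locations, categorized stay events, daily behavioral
phenotypes, and dyad-level social networks, with every stage testable
against a ground-truthed synthetic colony. It is written for behavioral
ecologists and computational ethologists who run RFID-tracked group
housing and want the full inference chain — not just the tracking — in one
auditable package.

## What it computes

**Tracking.** The burrow is a 5×5 grid (9 boxes, 12 pipes, 24 readers).
Detections place an animal in a reader's pipe; intervals between
detections are resolved to the shared pipe, the shared box, the reader's
end box (same-reader gap > 0.3 s), or `NA` (non-adjacent readers). The
error rate is the pooled fraction of unlocatable ticks.

**Stay events.** Maximal single-cell stays are categorized Rest / Nest /
Toilet / Garbage / Other, with the nest annotated by 6-hour windowed
majority occupancy and Rest defined as a nest stay exceeding 600 s.
Cleaning rules reclassify nest-adjacent tunnel rests and sub-nests, fill
long unlocatable gaps, and excise colony-wide disturbance phases (resting
fraction < 25% with a dip < 10%).

**Phenotypes.** Each individual-day becomes a 23-parameter vector (Sum, N,
Mean per category, plus activity-relative terms), Box-Cox transformed per
colony and z-scored per colony-day, embedded with UMAP and segmented into
behavioral clusters by watershed on a blurred density map. Phenotype
stability is quantified by an entropy-based consistency index,

    H_i = -Σ_k P_i(k) ln P_i(k),   consistency(i) = 1 - H_i / ln K,

with a Monte-Carlo null, by day-to-day cosine stability per cluster, and
by a co-assignment index C_emp(k,l) / C_ref(k,l) comparing within-
individual cluster pairing against independence.

**Social structure.** For every dyad, counts of activity-state synchrony,
out-of-nest spatial proximity, and directional path-following (same
adjacent-cell move within 3 s) are compared against cyclic-shift
surrogates that preserve autocorrelation while destroying
cross-correlation. Each dyad gets

    index = (N_actual - mean(N_surrogate)) / sd(N_surrogate),

a rank p-value, and a significance class (top/bottom 2.5%). Significant
dyads form weighted (directed, for follow) networks whose strength
centralities are tracked across consecutive time subsets.

**Synthetic colonies.** `simulate_colony()` generates ground-truthed
trajectories and detection logs with planted rest-rhythm coupling,
co-location preference, follower–followee relations, disturbance episodes
and detection misses, so parameter recovery can be verified end to end.

## Worked example

Simulate a 2-day, 8-animal colony in which one pair (ind01, ind02) has a
planted rest-rhythm coupling of 0.9, then run the pipeline and test every
dyad's synchrony against 199 cyclic surrogates:

```r
library(burrowtrack)

layout <- build_layout()
cpl <- matrix(0, 8, 8); cpl[1, 2] <- cpl[2, 1] <- 0.9
config <- colony_config(8, 2 * 86400, coupling = cpl, seed = 42)
sim <- simulate_colony(config, layout)

locations <- reconstruct_locations(sim$detections, layout,
                                   duration_s = config$duration_s,
                                   tags = config$ids)
locations
#> <location_series> 8 individuals x 1728000 ticks @ 0.1 s; 1.12% unknown

nest <- annotate_nest(locations, layout = layout)
ann <- chamber_annotation(nest, config$toilet_cell, config$garbage_cell)
events <- apply_corrections(classify_stays(segment_stays(locations), ann),
                            ann, config$duration_s, layout)
table(events$category)
#> Garbage    Nest   Other    Rest  Toilet
#>    5677    3839   56158     161    3994

disturb <- detect_disturbances(
  rest_fraction_series(events, 8, config$duration_s))
act <- vapply(config$ids, function(id)
  binarize_activity(events, id, config$duration_s, exclusions = disturb),
  integer(config$duration_s / 10))

dyad_synchrony(act[, 1], act[, 2], n_surrogates = 199, seed = 1)[
  c("index", "p_value", "class")]
#> index 6.42, p = 0.005, significant_high     (the planted pair)
dyad_synchrony(act[, 3], act[, 4], n_surrogates = 199, seed = 2)[
  c("index", "p_value", "class")]
#> index 1.15, p = 0.170, ns                   (an unrelated pair)

tbl <- dyad_index_table(act, "synchrony", n_surrogates = 199, seed = 3)
net <- build_network(tbl, ids = config$ids)
sort(strength_centrality(net), decreasing = TRUE)
#> ind01 ind02 ind03 ... : 6.85  6.85  0  0  0  0  0  0
```

The pipeline localizes the colony with a 1.1% error rate, finds the
planted pair (synchrony index 6.4, significant at the 2.5% tail) while the
control pair stays at chance, and the resulting network contains exactly
the planted edge — both members carry its weight as their strength
centrality. `run_pipeline(config, out_dir)` performs all of the above plus
phenotype clustering and writes CSV/GraphML artifacts and a JSON manifest.

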