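# phenotrack

Ontology-driven data management for plant phenotyping experiments, in R.

High-throughput phenotyping campaigns — conveyor glasshouses, instrumented
fields — attach millions of measurements to thousands of distinct objects:
plants, pots, carts, plots, leaves, sensors, images. Reanalysing such data
(or combining glasshouse and field campaigns) fails not on the numbers but on
the bookkeeping: *which* plant was this, *where* was it on 21 May, *what*
happened to it, and *how exactly* was "leaf area" measured? phenotrack is a
self-contained store for that bookkeeping, plus the computations that depend
on it.

## What it does

* **Identification** — structured URIs
  (`http://.../m3p/arch/2017/c17000118` = plant 118, campaign 2017,
  installation `arch`): counter-based minting that never reissues a serial,
  and a parser that rejects identifiers whose year digits disagree with
  their year directory. `mint_uri()`, `parse_uri()`.
* **Knowledge graph** — subject–predicate–object triples over built-in,
  extensible class hierarchies for experimental objects and events, with
  subsumption (`is_a()`, `instances_of()`) and transitive-closure inference
  (`kg_closure()` for `isPartOf` chains), path retrieval (`kg_related()`),
  and N-Triples / Turtle-subset serialization.
* **Events & annotations** — moves, sowing, harvest, troubles
  (breakdown / dysfunction / incident), recorded against objects and
  inherited down part-of chains ("all leaves from plots that lodged");
  web-style annotations on objects or single data points.
* **Object tracking & series stitching** — `residence_intervals()` replays
  move events into a half-open partition of time; `stitch()` assembles the
  environmental series an object actually sensed across installations, with
  per-point provenance and explicit gaps (never interpolated);
  `thermal_time()` accumulates degree-days from sowing on the stitched
  series, with the accumulation method recorded in the result.
* **Variables** — trait–method–unit triplets with SKOS-style mappings
  (`exactMatch`/`closeMatch`/`broader`/`narrower`) to reference-ontology
  identifiers such as `CO_322:0000880` or `UO_0000242`;
  `find_by_external()` resolves external accessions to local terms.
* **Hybrid queries** — `select_objects()` combines class membership, event
  and relation constraints, and aggregated value thresholds with AND/OR
  combinators: "plants with leaf area > 0.6 m² and/or height > 1500 mm",
  "images of plots having suffered lodging", "sensors displaying > 40 °C"
  (`sensors_exceeding()`).
* **Replicate screening** — `flag_outliers()` scores replicate summaries
  (final value or AUC) with the modified z-score
  `0.6745 |x − median| / MAD` (threshold 3.5), auto-annotates flagged plants
  and traces their origin through the graph to, e.g., a seed lot
  (`trace_origin()`).
* **Synthetic experiments** — `simulate_experiment()` deterministically
  generates a complete glasshouse + field campaign (object web, events,
  diurnal temperatures, logistic growth, planted moves / lodging /
  contaminated replicates) so everything above is testable offline.

The store has reference semantics (an environment of tibbles), functions take
it first and pipe cleanly, results are tibbles with `autoplot()` methods, and
outlier reports support broom-style `tidy()`/`glance()`.

## Worked example

```r
library(phenotrack)

st <- simulate_experiment(fixture_config(seed = 1))

# where was this (moved) plant over the campaign?
plant <- st$truth$moved$plant[1]
iv <- residence_intervals(st, plant, "2017-04-13", "2017-06-02")
iv$days <- interval_days(iv)
iv[, c("location", "start", "end", "days")]
#> # A tibble: 3 × 4
#>   location                         start               end                  days
#>   <chr>                            <dttm>              <dttm>              <dbl>
#> 1 http://www.phenome-fppn.fr/m3p/… 2017-04-13 00:00:00 2017-05-15 00:00:00    32
#> 2 http://www.phenome-fppn.fr/m3p/… 2017-05-15 00:00:00 2017-05-25 00:00:00    10
#> 3 http://www.phenome-fppn.fr/m3p/… 2017-05-25 00:00:00 2017-06-02 00:00:00     8
```

The plant spent 10 days in the second installation; its thermal time is
computed on the temperatures it actually sensed there (base 8 °C for maize):

```r
tt <- thermal_time(st, plant, sim_variable("air_temperature"), base_temp = 8)
tail(tibble::as_tibble(tt)[, c("date", "mean_temp", "increment", "thermal_time")], 3)
#> # A tibble: 3 × 4
#>   date       mean_temp increment thermal_time
#>   <date>         <dbl>     <dbl>        <dbl>
#> 1 2017-05-30      21.9      13.9         733.
#> 2 2017-05-31      21.9      13.9         747.
#> 3 2017-06-01      22.0      14.0         761.
```

761 °C·d accumulated since sowing — each day contributes the day's mean
stitched temperature minus the base. Hybrid query and replicate screen:

```r
select_objects(st, query_spec("Plant",
  data = list(
    where_value(sim_variable("leaf_area"),    ">", 0.6,  aggregator = "max"),
    where_value(sim_variable("plant_height"), ">", 1500, aggregator = "max")
  ),
  data_combinator = "OR"
))
#> 199 plants (of 236) pass either threshold

reports <- qc_outliers(st, sim_variable("leaf_area"))
flagged <- dplyr::bind_rows(lapply(reports, function(r) r$scores[r$scores$flagged, ]))
trace_origin(st, flagged$member[1])
#> $derivesFrom
#> [1] "http://www.phenome-fppn.fr/seedlot/lot_contaminated"
#> $hasVariety
#> [1] "http://www.phenome-fppn.fr/germplasm/variety10"
```

The flagged replicate traces straight back to the contaminated seed lot the
generator planted. `autoplot()` on a stitched series, a thermal-time result
or an outlier report draws the corresponding figure.

A thin command-line interface over these functions ships in
`inst/cli/phenotrack` (subcommands `mint`, `parse`, `simulate`, `track`,
`stitch`, `thermal-time`, `closure`, `query`, `outliers`), operating on a
store saved as plain-text files (`save_store()` / `load_store()`).

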