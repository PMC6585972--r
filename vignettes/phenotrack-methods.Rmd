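---
title: "Tracking, stitching and screening phenotyping experiments with phenotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, stitching and screening phenotyping experiments with phenotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotrack)
library(dplyr)
```

## The problem

A high-throughput phenotyping campaign produces measurements attached to
thousands of distinct physical things: plants, the pots and carts that carry
them, field plots and individual tagged leaves, the sensors that record the
climate they experience, and the images they are derived from. Reusing such a
dataset — or merging glasshouse and field campaigns — requires answering, for
any object and any instant: *what is this object, where was it, what happened
to it, and how exactly was each reported number measured?* phenotrack keeps
those answers in a single store and derives the quantities that depend on them
(per-plant environmental series, thermal time, replicate anomaly screens).

## Identification

Every physical object carries a structured URI:

```
<base>/<installation path>/<year>/<type code><yy><serial>
```

`base` names the national + local infrastructure, the optional path names an
installation, and the local identifier packs a type code (`c` plant, `o` plot,
`l` leaf, `pc` pot, `ct` cart, `ac` device, `ic` image), the year modulo 100,
and a zero-padded serial. The redundancy between the year directory and the
`yy` digits is deliberate: the parser rejects identifiers whose two year
encodings disagree, which catches a whole class of transcription errors.

```{r}
parse_uri("http://www.phenome-fppn.fr/m3p/arch/2017/c17000118")
```

Minting is counter-based per (base, year, type code), so serials are never
reissued; the padding width (default 6) is a registry setting and the parser
accepts any width. Non-physical entities — events, annotations, seed lots —
use label-style names (`event:moveTo328`) stored verbatim and excluded from
the code grammar.

## The knowledge graph

Relations are subject–predicate–object triples over two built-in class
forests: experimental objects (scientific objects, devices, infrastructures,
germplasm, images, experiments, agents) and experimental events (moves,
sowing, harvest, treatment, measurement, sampling, and troubles subdivided
into breakdown / dysfunction / incident). Both forests are user-extensible;
each class has at most one parent, which is the simplest model that supports
subsumption queries (`Trouble` matches an `Incident`).

Two inferences are supported, because they are the two that cross-object
retrieval actually needs:

* **subsumption** — `is_a()` and every class-filtered operation;
* **transitivity** — `kg_closure()` materialises, on demand and cached,
  the pairs connected by two or more edges of a predicate flagged transitive
  (`isPartOf` by default). Inferred triples are kept apart from asserted
  ones; mutations invalidate the cache.

Property-chain effects (a sample participating in its plant's experiment) are
deliberately *not* materialised; they are expressed at query time with
`kg_related()` paths, e.g. `c("isPartOf", "participatesIn")`, where a
transitive step traverses its closure and a `^` prefix inverts a step.
Unknown predicates auto-register as non-transitive with a warning, keeping
the vocabulary open.

Serialization is N-Triples or a deliberately small Turtle subset (`@prefix`,
`a`, one statement per line). Write-then-read is the identity on triples and
class assertions; one caveat: `rdf:type` objects are mapped back to class
assertions only when the receiving store's hierarchy knows the class, so
user-defined classes should be re-registered before reloading a dump.

## Events, annotations and object tracking

Events are timestamped instances of the event hierarchy linked to objects via
`concerns`; annotations are agent-authored notes (motivations: commenting,
describing, flagging — a closed set, so queries over them stay closed) on
objects or individual data points. Event visibility follows containment
*downwards*: a lodging incident on a plot is visible from each of its leaves
(`events_for(..., inherit = TRUE)`), never the reverse.

`residence_intervals()` replays an object's placement and its move events
into a partition of the observation window. The conventions, stated once and
used everywhere:

* intervals are half-open `[start, end)` — a measurement taken at the move
  instant belongs to the *new* location, so no point can be double-counted;
* durations are `(end - start) / 86 400 s`, not calendar-inclusive counts
  (a 19 May to 29 May stay is 10 days);
* two moves of one object at the same instant are an error, as is a move
  whose `from_location` contradicts the replayed current location — the
  system's job is to surface such data bugs, not to order them silently;
* a harvest event truncates the partition.

## Environmental series and thermal time

Sensor points carry no location; where a sensor was is a separate, time-bound
statement (`assign_sensor()`), with non-overlapping half-open spans per
(location, variable) — sensor replacement is two abutting spans, and the value
at the boundary instant comes from the successor. `stitch()` assembles the
series an object actually sensed: per residence interval, the points of the
sensor assigned to that location, each point carrying its provenance (sensor,
location, interval). Sub-intervals with no assigned sensor or no data are
reported as gaps; nothing is ever interpolated — surfacing gaps for
annotation, not imputing them, is the design position. Points of a location's
sensors that fall outside their assignment span are counted as
`lost_points`, which makes the bookkeeping conservative and checkable:
served + lost = all in-interval points of that location's sensors.

`thermal_time()` accumulates degree-days on the stitched series from the
object's sowing event (or an explicit origin): per civil day,
`max(0, mean(T) - base)`. Choices worth knowing:

* civil days are computed in a configured time zone, default UTC —
  deterministic, and configurable for local-time installations;
* `base_temp` has **no default**: it is a biological, per-species parameter
  (about 8–10 °C for maize), not a system constant;
* days without data contribute zero and are flagged `no_data`;
* the accumulation method is registered by name
  (`daily_mean_above_base` by default) and recorded with every result,
  because the method is part of the variable's definition;
* the output is non-decreasing by construction.

## Variables and ontology mappings

A variable is a trait–method–unit triplet of terms; two variables may share a
trait and differ in method (glasshouse leaf area from 3-D reconstruction vs
field leaf area inverted from the gap fraction are different variables, and
no algorithm here pretends otherwise). Terms map to external ontology
identifiers (Crop Ontology, Unit Ontology, ...) through exactly four
SKOS-style relations — `exactMatch`, `closeMatch`, `broader`, `narrower` —
stored as ordinary triples, so mappings survive serialization.
`broader`/`narrower` are not traversed transitively: mappings are direct
links, and hierarchical expansion is a query-side decision. Identifiers are
opaque strings, never resolved against live services; methods may stay
local-only with no mapping at all. For a well-standardised trait an
`exactMatch` is assumed appropriate; genuinely local traits use `closeMatch`
to their nearest standard relatives.

## Hybrid queries

`select_objects()` combines a target class (subsumption-aware) with semantic
constraints (has an event of a class, possibly inherited; reaches a resource
along a predicate path) and data constraints (aggregated observation value
passes a comparator). Each constraint list has its own AND/OR combinator and
the two lists are intersected — one level of grouping, enough for
"leaf area > 0.6 m² and/or height > 1500 mm" without growing a query planner.
The default aggregator is `any` (existential, the natural reading of "sensors
that display temperatures higher than 40 °C"); trait queries typically want
`latest` or `max`, stated per query because both readings are legitimate.
Results are URI-sorted, hence deterministic.

## Replicate screening

`flag_outliers()` scores each replicate's summary statistic (final value or
trapezoid area under the curve, time in days) with the modified z-score
`0.6745 |x - median| / MAD`, flagging scores above 3.5 — the standard
convention for that statistic, chosen over clustering because the target
failure mode is a single deviant replicate (e.g. seed contamination) among
near-clones, and a robust deterministic score is auditable. When the MAD is
zero the score falls back to `|x - median| / (1.253314 meanAD)`; when that is
also zero, nothing is flagged. Groups under three members warn and flag
nothing. The detector is scale-invariant, never flags a member at the median,
and its name travels in the report so alternative detectors can be registered
and compared. Flagged members can be auto-annotated (motivation `flagging`,
body naming method/score/threshold) and traced through the graph
(`trace_origin()`, default paths `derivesFrom` and `hasVariety`) back to seed
lots — the "go backwards to the origin of the incident" workflow. Flagging is
per plant, not per data point; curve-shape anomalies are left to expert eyes.

## The synthetic experiment generator

`simulate_experiment()` builds the full object web of a two-installation
campaign: a glasshouse whose plants (each with pot and cart, minted URIs,
genotype and seed-lot provenance) can spend ten days in a second compartment
with a warmer climate, and a field with one plot per genotype, tagged leaves
and plot images. Defaults are the emulated study conditions: 59 genotypes,
4 glasshouse replicates each (the replicate count of the expert-annotation
scenario), 13 April – 2 June 2017, hourly diurnal temperatures
(sinusoid with 24 h period plus Gaussian noise; 22 ± 6 °C vs 28 ± 4 °C in
the two glasshouse compartments, 20 ± 8 °C in the field), daily logistic
growth observations, a mid-campaign sensor replacement in the home
compartment, a lodging incident on a fraction of plots, and a fraction of
replicates whose asymptotic size is scaled to 0.4 — a contaminated seed lot.

Growth parameters are drawn per genotype, with a small within-genotype
replicate jitter (4 % multiplicative, 0.5 d on the logistic midpoint):
genotypes differ strongly, replicates are near-clones, which is what
controlled-condition replicate curves look like and what makes a contaminated
replicate visible. One global seed fixes everything; per-resource streams are
derived by hashing the resource URI with the seed, so adding a plant never
perturbs another plant's data, and equal seeds give byte-identical triple
dumps.

What the generator does *not* emulate — and therefore what green tests do not
certify about real data: sensor drift and calibration error, spatial climate
gradients within an installation, missing-at-random observation dropout,
plant death, and the genuinely hard trait-mapping problem between glasshouse
and field leaf area (documented above as a variables-module concern, not
solved algorithmically).

## Numerical and testing choices

Problem sizes in the test-suite and acceptance script were chosen to exercise
the semantics at desk scale: 200 random part-of DAGs of up to 30 nodes against
an independent BFS oracle, 200 random move schedules for the interval
partition invariant, 60 randomized stitching fixtures for count conservation
and provenance, 200 replicate groups of four for the screen's recall (planted
10 σ outliers) and clean false-flag rate (counted per member), and small
simulated campaigns (5 genotypes × 4 replicates) for round-trip and query
checks. Timestamps are stored as UTC instants; exact equality of interval
endpoints is meaningful because all arithmetic is in whole seconds. Ties and
degenerate inputs are errors, not guesses: simultaneous moves, overlapping
sensor assignments, empty kinetic series, fewer than three replicates.

## Known limitations

* No full OWL reasoning (functional properties, cardinality, disjointness),
  no SPARQL, no named graphs; the inference surface is subsumption plus
  transitive closure, by design.
* The class hierarchy is a forest — no multiple inheritance.
* Calibration records can be stored as triples but are never applied to
  served values; values are raw, with provenance.
* Per-data-point outlier flagging and mixed-model spatial corrections are out
  of scope; the screen operates on per-plant summaries.
* The observation JSON dialect mirrors breeding-API observation units but is
  versioned locally; no web service is included.
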