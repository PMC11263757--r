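---
title: "Cluster methodology, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster methodology, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixclust)
```

## The model

`fixclust` identifies *activity clusters* in GPS collar data: sets of fixes
close enough in space to indicate concentrated activity worth a field
visit. The rule has two parameters with direct biological meaning:

* `buffer_m` (*x*) — a disc of radius *x* meters is drawn around every fix.
  Two fixes are *connected* when their buffers overlap, which happens
  exactly when their centers are at most *2x* apart. The comparison is
  inclusive: tangent buffers count as overlapping.
* `min_locations` (*y*) — connected components of the overlap graph with at
  least *y* members become clusters; smaller components are single points.

Connectivity is transitive, so a chain of pairwise-overlapping buffers
forms one cluster even when its endpoints are far apart. This matches how
the cluster polygon is drawn (the union of the member buffers is one
connected region) and gives the method its characteristic sensitivity to
`buffer_m`: enlarging the buffer can only merge components, never split
them, which the test suite verifies as a monotonicity property.

The *consecutive-only* mode replaces the full overlap graph with edges
between time-adjacent fixes only: clusters are maximal runs of consecutive
fixes in which every adjacent pair is within *2x*. Spatial revisits
separated by an excursion then remain separate clusters — appropriate when
the research question distinguishes repeated visits from continuous
occupancy. Every consecutive-mode cluster is contained in some default-mode
cluster on the same data (the edge set is a subset), a refinement property
the tests check on random instances.

Clustering is strictly per animal. Cluster IDs are `<animal>_<seq>` with
`seq` counting from 1 in order of first visit, so IDs are deterministic and
stable under data that arrives in time order.

### Summary attributes

For each cluster: `first_time`/`last_time` are the first and last member
timestamps; `n_inside` is the member count; `n_outside` counts the same
animal's non-member fixes falling inside the `[first_time, last_time]`
window; `percent_time = 100 * n_inside / (n_inside + n_outside)`. The
percentage is fix-count based, not duration based: under a regular fix
schedule counts and durations are proportional, counts remain well defined
when the schedule is irregular, and the quantity then stays consistent with
the two counts it is displayed beside. The mean center (the navigation
waypoint) is the arithmetic mean of member coordinates.

### Point IDs

Every fix receives a point ID `<animal>_<C{seq}|SP>_<MMDDHH>` (cluster
number or `SP` for single points, then zero-padded month, day, hour).
Same-hour collisions within an animal get the minute appended, remaining
ties a running letter, so IDs are always unique. The exact grammar —
delimiters, zero padding, collision handling — is this package's
convention, documented here because downstream field databases key on it.

## Incremental analyses and ID constancy

Cluster studies run the analysis repeatedly as data accumulate during a
season, and previously issued IDs must keep meaning the same site. Rather
than appending new fixes to frozen previous polygons, `reconcile()`
recomputes clusters on the **full** fix set and then relabels:

* identical member set as one previous cluster → same ID, state preserved;
* superset of one previous cluster → same ID, state `Grown`;
* superset of two or more previous clusters (a new fix bridged them) → the
  lowest previous seq number survives; the absorbed IDs are retired and
  their field-entered columns are folded into the survivor's notes;
* no previous members → a fresh ID.

Recomputing on the full set guarantees *batch equivalence*: the member
partition of any sequence of incremental runs is identical to a single
batch run on the same total data, because with unchanged parameters and a
growing fix set, overlap components can only grow or merge. Reconciliation
is pure relabelling. This is the single strongest correctness property of
the incremental path and is tested over random splits of synthetic
datasets.

Two bookkeeping rules make ID constancy durable:

* **High-water marks.** Fresh seq numbers start above the highest number
  ever issued for the animal — including numbers retired by merges, which
  would otherwise be invisible in the latest layer. The per-animal
  high-water mark is stored in the cluster layer (`issued_seq`) so the rule
  survives the file round trip.
* **Which merge survivor.** Keeping the lowest (oldest) seq number is a
  convention; any fixed choice preserves constancy, but oldest-wins means
  the surviving ID is the one most likely to already appear in field notes.

Parameters must stay constant within a study; `reconcile()` compares the
run's configuration against the stored sidecar on every clustering-relevant
field and refuses on any difference, naming the offending fields. Changing
parameters mid-season is an error by design, not a supported workflow.

Matching between previous and current clusters uses the stable member key
(animal, timestamp). Point-ID strings embed the cluster seq number and can
legitimately change when clusters are relabelled, so they identify members
for display and export but not for reconciliation.

## Parameters and defaults

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| `buffer_m` | m | — (required) | Half the maximum connection distance. 30 m suits predation studies on large carnivores; den/nest studies may use less. |
| `min_locations` | fixes | — (required) | 2 detects brief stops; larger values demand longer occupancy. |
| `consecutive_only` | flag | `FALSE` | See above. |
| `subsample_minutes` | min | 0 (off) | Set to the nominal fix interval when collars emit proximity bursts. |
| `period_start`, `period_end` | instant | — | Closed interval on both ends, so a fix at midnight on the last day is inside. Field conventions like "May 1 to May 31" imply an inclusive last day. |
| `crs_epsg` | — | — | A projected meter-unit CRS. WGS84 UTM codes (326xx/327xx) additionally enable lon/lat derivation for GPX. |

Subsampling is greedy and anchored at each animal's first in-period fix:
keep the first fix, then each next fix at least *z* minutes after the last
kept one. Anchoring at the first fix (rather than a nominal grid) is
deterministic, needs no schedule metadata, and collapses bursts without
shifting an already-regular schedule. The operation is idempotent and the
pipeline order is fixed: validate → period filter → subsample.

All timestamps are treated as UTC; collar data conventionally are, and UTC
avoids daylight-saving ambiguity in the consecutive-fix logic.

## Numerical and format choices

* **Distances** are planar Euclidean in the projected CRS — the same
  geometry GIS buffering uses. Geodesic distances were rejected: at the
  scale of a buffer (tens of meters) projection distortion is orders of
  magnitude below GPS error.
* **Polygons.** The cluster polygon is the exact union of the member
  buffer discs, computed analytically (boundary arcs of each circle not
  interior to any other, stitched at circle intersection points) and
  discretised at 64 segments per full circle; the area error of the
  discretisation is below 0.2%. Two discs tangent at exactly *2x* yield a
  single pinched ring, consistent with the inclusive overlap rule. A ring
  of buffers around uncovered ground yields an explicit hole ring.
* **Projections.** WGS84 UTM forward/inverse transforms are implemented
  in-package (Krueger series to n^6, sub-millimeter accuracy within a
  zone) and verified in tests against independent geodesic distances and
  round-trip identities.
* **Layer format.** The cluster layer is GeoJSON with coordinates in the
  study CRS at full double precision (a `crs` member declares the EPSG
  code), so a write/read round trip reproduces vertices to machine
  precision; the settings sidecar is a plain `key = value` text file,
  diff-friendly and human-readable for retracing methods across seasons.
  Tables export as CSV; xlsx is recognised but not bundled. The "latest"
  previous layer is chosen by the analysis time recorded in its sidecar,
  not by filesystem timestamps, so layers copied between field laptops
  keep their history.
* **Degenerate inputs.** Coincident fixes collapse in the polygon union;
  duplicate (animal, timestamp) rows collapse at validation keeping the
  first; non-finite coordinates are dropped and counted; zero or one fix
  yields no clusters; an empty period yields an empty—but still
  writable and restorable—result.

## The synthetic generator, and what passing tests mean

`generate_tracks()` plants *stationary bouts* (fixes scattered
isotropically, Gaussian with `scatter_sd_m`, around a planted center for a
known interval) inside *directed travel*. Travel between bouts is a
straight-line transit at constant per-fix displacement with 5 m cross-track
jitter; before the first and after the last bout the animal walks with a
persistent heading (turning noise capped at ±45°) that follows the bout
transect, so approach, transits and departure all progress the same way and
the track is globally self-avoiding at the buffer scale: progress along the
travel axis exceeds half a step every fix, so two travel fixes can never
lie within the connection distance. Burst episodes insert extra fixes
between schedule ticks at a faster interval, interpolated along the path.
Truth counts are defined by schedule ticks inside each bout interval,
because clustering consumes fixes, not durations.

The packaged scenario (`scenario_case_study()`) is shaped like a spring
predation study on three bears: May 1–31, 60-minute fixes, 3–4 bouts per
animal along each animal's seasonal travel axis, one 10-minute proximity
burst during a transit, analysed with a 30 m buffer, minimum two locations
and a 60-minute subsample. Bout centers are spaced 120 m per schedule tick
of travel time so transit fixes stay well beyond the 60 m connection
distance. Validation sizes: 200 seeded replicates for recovery and for the
bout-free null, 100 random instances for oracle equivalence, 50 for each
monotonicity property, 10 datasets × 20 splits for incremental
equivalence.

What this does and does not show: the generator's travel is deliberately
non-revisiting, so the bout-free null measuring *zero* spurious clusters is
a property of the movement model, not a claim about real animals — real
tortuous foraging paths do self-approach and will produce clusters at
those places, which is precisely the method's intended sensitivity, and
which parameter choice must manage on real data. What the simulations do
validate is the machinery: exact recovery of true stationary bouts against
a moving background, the clustering rule against an independent brute-force
oracle, and ID bookkeeping under accumulation, merging and re-analysis.

## Known limitations

* No fix-quality filtering (DOP, 2D/3D) and no gap interpolation — fixes
  are taken as given.
* `percent_time` is fix-count based (see above); under severely irregular
  schedules without subsampling it is a biased estimate of elapsed time
  share.
* Shapefile I/O is not built in; the GeoJSON layer and CSV tables are the
  interchange formats, and shapefile users should convert externally.
* Geographic coordinates (for GPX) can only be derived when the study CRS
  is WGS84 UTM; other projected CRS work for clustering but export
  waypoints only if lon/lat are supplied in the input.
* One clustering algorithm. Stay-point methods with moving centroids
  behave differently around slow travel; this package implements the
  buffer-overlap family only.
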