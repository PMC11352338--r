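---
title: "Methods: social interaction networks and behavioral phenotyping with flysin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social interaction networks and behavioral phenotyping with flysin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysin)
```

# Overview

`flysin` quantifies the social structure of small groups of *Drosophila*
walking in a circular open-field arena. The pipeline runs in four stages:

1. **Trajectories** — per-frame position and body heading of each fly, in
   arena-local millimetres (`FlyTrackSet`).
2. **Interaction events** — directed bouts detected by distance, facing
   angle and minimum duration (`detectEvents()`).
3. **Social interaction networks (SINs)** — directed graphs whose edge
   weights are the number (`count`) and total duration (`duration`) of
   events (`buildNetwork()`).
4. **Metrics and normalization** — global efficiency, clustering
   coefficient, betweenness and closeness centrality, expressed as
   z-scores against a chimeric-group random-network null
   (`sinZScores()`).

Companion modules compute day/night locomotor activity, sleep bouts and
free-running circadian period from beam-break monitors; negative-geotaxis
climbing scores; glutathione and relative H~2~O~2~ from plate-reader
assays; and group-comparison statistics. A synthetic-data generator with
exact ground truth backs every stage's tests.

# Interaction model

Two flies interact — directed, actor toward target — at a frame when

* their centroid distance is at most 2.5 body lengths (body length 2 mm,
  so 5 mm), and
* the actor faces the target: the absolute offset between the actor's
  heading and the actor-to-target bearing is at most 80°, half of the
  160° field-of-view cone.

A directed event is a maximal run of consecutive qualifying frames lasting
at least 0.6 s; the comparison is inclusive, so at 30 Hz an 18-frame run
(0.6 s exactly) is an event and a 17-frame run is not. Event duration is
run length divided by frame rate.

Design choices worth making explicit, all switchable in
`InteractionCriteria`:

* **Cone convention.** "Facing each other within a 160 degree angle" is
  ambiguous between a full- and a half-angle reading. Because edges are
  explicitly directional (per actor), we adopt the per-actor cone with
  half-angle comparison (offset ≤ 80°); `angleConvention = "full"` selects
  the other reading.
* **Distance anchoring.** Distance is centroid-to-centroid, and "2.5 body
  lengths" resolves to a fixed 5 mm threshold rather than a per-fly
  measured length, since the equivalence is stated globally.
* **Gaps.** A missing (untracked) frame breaks a run. Short tracking gaps
  can first be interpolated with `fillGaps()` (linear in position,
  shorter-arc circular in heading, ties exactly π apart resolved toward
  positive rotation); the default maximum interpolated gap is a tenth of
  a second of frames. This keeps the detector a pure function of the
  filled tracks.

# Network metrics

SINs are directed and weighted; all metrics treat edge weight (count or
duration) as tie *strength*, converting to path distance as
`distance = 1/weight` — the standard convention for interaction-strength
weights (stronger tie = closer).

* **Global efficiency**: mean over ordered node pairs of the inverse
  shortest-path distance; unreachable pairs contribute 0.
* **Clustering coefficient**: the geometric-mean-of-weights directed
  triangle formulation with total-degree normalization; with `W` rescaled
  by its maximum and `S = W^(1/3) + (W')^(1/3)`, node *i* scores
  `diag(S^3)_i / 2 / (dtot_i(dtot_i − 1) − 2·dbi_i)`. Values lie in [0, 1];
  nodes with fewer than two distinct neighbours score 0.
* **Betweenness centrality**: fraction of shortest paths between ordered
  pairs passing through the node, normalized by `(n−1)(n−2)`.
* **Closeness centrality**: incoming-distance closeness with the
  Wasserman–Faust reachability correction,
  `C_i = (R_i/(n−1)) · (R_i / Σ incoming distances)`, which remains
  meaningful on disconnected graphs. For closeness, edge weights are
  first rescaled by the maximum weight so all edge distances are ≥ 1 and
  the score is guaranteed to lie in [0, 1] (without this, a graph whose
  weights exceed 1 could score above 1). Harmonic closeness is available
  via `variant = "harmonic"`.

**Numerical tie handling.** Shortest-path computations (Floyd–Warshall
distances plus ordered path counting) are implemented in the package with
an explicit tie tolerance of 1e-9 (relative): path lengths within the
tolerance are treated as equal. This matters because with
`distance = 1/weight` and small integer weights, mathematically tied
paths differ in floating point (three hops of weight 3 sum to
`0.9999999999999999`, not `1.0`); exact-double comparisons would make
betweenness path counts depend on rounding order. The test suite verifies
every metric against an independent exhaustive simple-path enumeration
oracle on all 3-node digraphs and random 4–5-node digraphs with weights
in {1, 2, 3}.

**Summarization.** Global efficiency is a network-level quantity. The
three local metrics are summarized per recording by their unweighted mean
over nodes before z-scoring — the least-structured choice — and per-node
z-scores can also be emitted (`emitNodes = TRUE`), where a node's observed
value is compared against the pooled distribution of node values across
null networks.

# The chimeric-group null model

Observed metric values are normalized as
`z = (observed − mean(null)) / sd(null)` (sample SD, n−1 denominator)
against random networks built by re-assembling groups: `groupSize` flies
are sampled without replacement from the pooled (recording, fly) index of
one experimental condition, their trajectories overlaid in the common
arena frame, and interaction detection re-run as if they were co-housed.
Edges in such a chimeric group can only reflect spatial coincidence, not
real social interaction. The default is 10,000 random networks of 12
flies.

Decisions:

* "From different measurements" is enforced as *not all flies from a
  single recording*; `strict = TRUE` requires every fly to come from a
  distinct recording.
* Sampling is without replacement within one random network and with
  replacement across networks; the RNG seed is mandatory
  (`NullModelSpec`).
* A degenerate null (zero SD) yields z = 0 if the observation equals the
  null mean, and a flagged undefined z otherwise.

Because a chimeric group of non-social flies is statistically the same
object as an observed group of non-social flies, the null model is
*exchangeable* under the no-sociality ground truth: the test suite checks
that observed and null metric distributions agree (two-sample KS) and
that z-scores over many replicate synthetic experiments are centered near
zero with |z| < 4 essentially always.

# Synthetic data: what it emulates, and what it does not

`simulateTrajectories()` produces a correlated random walk: headings
diffuse (SD `turningNoiseRad` per √s, default 1.5), speed is constant
(default 8 mm/s, a typical walking speed), and arena walls reflect the
velocity about the tangent. Flies start uniformly placed in the arena.
With `attractionStrength > 0`, each fly's heading is pulled toward the
centroid of its planted group-mates with per-frame gain
`1 − exp(−strength·dt)`, producing genuine spatial aggregation; strength
0 gives fully independent motion. The arena defaults are the study
conditions: 61 mm diameter, 12 flies, 25 min at 30 Hz. The frame rate is
a package default (the recording hardware's rate is not fixed by the
assay), chosen so the 0.6 s minimum duration spans an exact whole number
of frames.

The generator makes no claim of behavioral realism beyond the statistical
structure the pipeline assumes: no thigmotaxis, grooming, courtship or
collision avoidance. Passing recovery tests therefore show that the
pipeline correctly measures the planted statistical structure, not that
it captures every property of real fly movement.

`simulateActivity()` draws per-minute Poisson counts from a circadian
waveform with a morning and a (stronger) evening peak (Gaussian bumps,
SD 1.5 h), a midday siesta dip and a deeper night trough — the canonical
LD actogram shape. Under constant darkness the waveform free-runs at
`periodH`. Sleep bouts are injected as forced-zero windows (rate
`sleepBoutRatePerH`, mean length `sleepBoutLenMin`), so the ground truth
is exact rather than emergent; overlapping injected windows are merged in
the recorded truth. Note that at low mean rates, incidental runs of zero
Poisson counts are themselves legitimate sleep by the definition below —
exact bout-recovery tests therefore use a flat high-rate profile
(8 counts/min) where incidental zeros are vanishingly rare.

`simulateGeotaxis()` and `simulateAssayReadings()` are direct draws from
the assumed observation models (binomial climbing counts; linear
absorbance with Gaussian noise, the post-reduction read corresponding to
`GSH + 2·GSSG`).

# Activity, sleep and circadian period

* **Activity** is the beam-break count per minute. Phase summaries
  average counts per minute over the 12 h light ([08:00, 20:00)) and dark
  phases across complete recorded days; incomplete first/last days are
  excluded to avoid partial-phase bias.
* **Sleep** is a maximal run of zero-count minutes *strictly longer* than
  5 min, following the standard arousal-threshold-validated cutoff read
  literally ("longer than 5 min"): a 5-min run is not sleep, a 6-min run
  is. The common ≥ 5 convention is available (`strict = FALSE`).
  Per-phase totals attribute each bout minute to the phase it falls in,
  so bouts spanning a boundary split proportionally.
* **Circadian period** is estimated from constant-darkness recordings
  (≥ 3 days) by a chi-square periodogram on a 0.1 h grid over 16–32 h.
  The statistic folds the series at integer-minute candidate periods
  using *every* recorded minute (columns may contain unequal numbers of
  cycles); `Q_P = Σ K_h (M_h − mean)^2 / var` is χ² with P−1 df under
  noise. Using all minutes avoids the discontinuity of the classical
  complete-cycle truncation, which deflates the statistic by a whole
  cycle just above integer-day periods and biases the peak. Peak picking
  maximizes the df-standardized statistic lightly smoothed across the
  grid (3-point running mean) to suppress discretization jitter;
  significance is judged at the picked period against its χ² line with
  Bonferroni correction over the candidate grid. An autocorrelation-peak
  method is available as an alternative.

# Geotaxis and redox

Climbing trials score `100·n_climbed/n_flies` (flies reaching 5 cm within
5 s). Groups are summarized by their trial mean; the genotype summary is
mean ± SEM over *group* scores — the unit of replication is the group of
ten flies, since trials of one group share flies and are not independent.
Pooled-trial SEM is available (`scheme = "pooled"`) because the study
design descriptions are ambiguous between the two.

Glutathione concentrations invert an ordinary least-squares calibration
line (A415 vs known GSH concentration, ≥ 3 distinct points); each GSSG
reduces to two GSH, so `GSSG = (total − free)/2`. Negative
back-calculated concentrations are clipped to zero with a warning rather
than erroring — plate-reader noise near zero is routine — and
`total < free` is flagged. DHE fluorescence is an indirect readout, so
the H~2~O~2~ module reports only blank-corrected values and fold change
versus the control-group mean, never absolute concentrations.

# Group-comparison statistics

The testing scheme mirrors the assay design: a variance gate (Bartlett,
or Brown–Forsythe as Levene on deviations from group medians) routes to
one-way ANOVA with Tukey HSD, or to Kruskal–Wallis with Dunn's rank post
hoc. Those gates test variance homogeneity, not normality, although they
are often described as normality checks; the gate is implemented as the
variance test it is. Dunn's z statistics use the tie-corrected pooled
variance and Holm adjustment by default (the adjustment is configurable;
Holm is a safe default where the original correction is unstated).
Post hoc tables are reported only when the omnibus p is below α = 0.05
unless `alwaysPosthoc = TRUE`. Constant-valued input is a flagged
degenerate case with no test. The omnibus type-I error of both branches
is calibrated by simulation in the test suite (nominal 5%, accepted
3–7%).

# Problem sizes used by the tests

The package defaults are the study-scale conditions (25 min recordings at
30 Hz, 12 flies, 10,000 random networks, 5-day activity recordings). The
test and acceptance suites run the same code at reduced sizes chosen so
the full suite completes in minutes: 60 s recordings for the replicated
null-calibration and planted-effect experiments (the exchangeability
being tested does not depend on recording length), 500 random networks
per replicate with 50 replicates, and one full 10,000-network null as a
smoke test. The acceptance script reports the same quantities at 20
replicates and 300 random networks.

# Known limitations

* The trajectory generator's null is exchangeable by construction; real
  recordings can violate exchangeability (arena-specific wall effects,
  shared lighting gradients), which the chimeric null only partly
  controls.
* Metrics are computed on the aggregate network of a recording; temporal
  network dynamics, community structure and interaction-type
  classification are out of scope.
* The FlyTracker import shim maps columns via configuration; it does not
  parse proprietary binary exports.
* DHE readouts are relative; no absolute H~2~O~2~ concentration is ever
  reported.
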