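---
title: "Methods: simulating landscapes, foragers and the networks they leave behind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating landscapes, foragers and the networks they leave behind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

patchnet asks a methodological question of movement ecology: when a spatial
network of habitat connectivity is inferred from animal relocations, how much
of the inferred structure is real, and how much is an artifact of the
relocation schedule? The package answers it by simulation: it generates
fragmented resource landscapes, walks mechanistic foragers across them at a
one-relocation-per-step resolution, builds patch-level networks from the full
and from thinned trajectories, and measures what thinning does to network
topology and to agreement with classical connectivity models.

## Landscape model

Landscapes are 50 x 50 cell grids drawn from a stationary Gaussian random
field with mean `trend_t` and exponential covariance
`sill * exp(-h / range_r)` plus an optional nugget. Negative values are
truncated to zero and the field is normalized to sum to one, so positive
cells carry resource of gradual quality and zero cells are inert matrix.
Three canonical parameter sets span the fragmentation gradient:

| level  | range_r | trend_t | character                            |
|--------|---------|---------|--------------------------------------|
| low    | 5       | 0.3     | one dominant patch, few satellites   |
| medium | 2       | -0.5    | many mid-sized patches               |
| high   | 2       | -1.5    | sparse scatter of small patches      |

`range_r` is the range *parameter* of the exponential model; the effective
decorrelation distance is about `3 * range_r`. We state this because
geostatistics tools disagree on which of the two conventions the word
"range" denotes; results compared against a tool using the effective-range
convention must rescale accordingly.

The field is simulated by Cholesky factorization of the exact 2500 x 2500
covariance matrix. The factor depends only on (dims, nugget, sill, range),
so it is cached per session and each additional landscape costs one matrix
product. The tests verify the realized covariance independently, by fitting
an empirical semivariogram over 200 replicate fields and comparing it to
`sill * (1 - exp(-h / range_r))` at lags 1..10.

A landscape whose truncation removes every positive cell is flagged `empty`;
`generate_landscape_nonempty()` redraws with an incremented seed (this is
rare under all three parameter sets, and impossible under `low`).

Patches are connected components of positive cells, 8-connectivity by
default (the common landscape-metrics convention; 4-connectivity is an
option). The four fragmentation indices follow the FRAGSTATS definitions:
aggregation (realized over maximal same-class rook adjacencies, with the
largest-integer-square rule for the maximum), cohesion, division and the
proportion of resource cells. Adjacencies for the aggregation index are
always rook edges, regardless of the patch-labelling connectivity.

## Forager model

Movement is a continuous-space correlated biased random walk, one recorded
relocation per timestep, step length fixed at 1 cell. The heading proposed
at each step is the direction of a weighted sum of three unit-scaled
vectors — persistence (the previous heading), attraction toward remembered
resources, and repulsion from avoided locations — perturbed by von Mises
noise with concentration `kappa`. Boundaries reflect.

Memory is a value per resource cell, initialized to the baseline field
(the forager knows its landscape), refreshed to the *current* (depleted or
recovered) value within the perception radius, and decaying exponentially
elsewhere. The attraction vector is the resultant of unit vectors toward
remembered cells, weighted by memory value times `exp(-d / mem_dist)` and
normalized by the total weight. The normalization matters: the magnitude of
the resultant then measures directional consensus, so a forager surrounded
symmetrically by equally remembered resources feels no net pull, and
negligible residual memory cannot pin the walk in place.

Resources deplete and regenerate: the occupied cell loses a fraction
`consumption` of its current value each step, and every cell relaxes toward
its baseline at rate `regen`. The pair (consumption = 0.9, regen = 2e-4)
makes local grazing unsustainable on the timescale of a run, which produces
the grazing waves that carry the forager across many patches — the behaviour
the network analysis needs. With gentle consumption and fast regrowth the
walk settles into a small sustainable home range and visits almost nothing,
which is a legitimate regime but not the one under study.

Four processes share this core:

* **F** — foraging only.
* **F+Pe** — an elusive predator: with probability `p_encounter` per step an
  encounter appears uniformly within the perception disc; the forager flees
  `flee_dist` cells and avoids the location for `avoid_duration` steps.
* **F+Ps** — a stalking predator: identical, except encounters sit on
  resource cells near the forager, drawn proportionally to current value, so
  avoidance costs the forager its best foraging grounds.
* **F+T** — territoriality: `n_foragers` (default 2) foragers move
  simultaneously on the shared resource field, deposit scent marks every
  `mark_interval` steps (lifetime `mark_lifetime`) and are repelled by
  foreign marks. Runs discard a 10,000-step burn-in so territories are in
  place before recording; networks pool all foragers of a run, as one would
  pool the individuals of a tracked population.

Full trajectories are 10,000 relocations. The parameter defaults in
`movement_params()` are this package's concrete instantiation of the forager
family; they were fixed during model bring-up by inspecting behaviour
(patch turnover under F, territory separation under F+T, flight responses
under predation) and then frozen. Quantities that depend on the exact
instantiation — most visibly the agreement level of distance-threshold
models — should be read as properties of this instantiation, not constants
of nature.

The walk itself is implemented in C++ (Rcpp) with all randomness drawn from
R's generator, so `set.seed()` makes every trajectory bit-reproducible. The
von Mises sampler is the Best–Fisher (1979) rejection algorithm, written
here because no installed package provides one.

## From trajectory to network

`locate()` assigns each relocation to the patch of its containing cell
(cells are half-open; a coordinate exactly on a boundary belongs to the cell
that starts there). `visit_sequence()` drops matrix fixes, collapses runs
within one patch, and merges an A → matrix → A excursion into the original
visit, so no self-link can arise. `build_network()` keeps the unique
unordered pairs of successive visits: networks are unweighted, undirected,
and one fix inside a patch counts as a visit — no residency threshold.

`resample_trajectory()` keeps every k-th relocation. Simulation-mode
resampling is deterministic with phase 0; empirical workflows can draw the
phase at random and can rotate it daily (`daily_shift`), mimicking GPS duty
cycles that shift the sampling hour each day.

## Topology diagnostics

Scale-freeness is assessed exactly as in the classical empirical literature:
ordinary least squares of log frequency on log degree over observed degrees
at least 1, scale parameter = negated slope, scale-free when it exceeds 1.
A maximum-likelihood fit would be statistically preferable but answers a
different question; OLS on the log-log frequency table is the estimator the
results are defined by, so it is the default and the only one used. Degree
distributions of single 50 x 50 networks are short, so study-level fits pool
the degrees of all replicate landscapes in a (fragmentation level, process)
cell; 30 landscapes per level make those pooled fits stable.

The small-world test draws `ensemble_size` (default 100) Erdős–Rényi G(n, m)
graphs matching the network's node and link counts and computes
`sigma = (C / C_R) / (L / L_R)` per replicate, declaring the network
small-world when `min(sigma) > 1`. Numerical choices, all forced by small
sparse graphs:

* `L` (and `L_R`) averages shortest paths over *reachable* pairs only, with
  the unreachable count reported; G(n, m) replicates at realistic m are
  often disconnected, and discarding them would bias the null.
* A replicate with `C_R = 0` while `C > 0` contributes `sigma = Inf` (it
  cannot veto smallness); a network with `C = 0` is not small-world by
  definition and skips the ensemble entirely.
* Ensemble seeds derive from a per-network seed, so metric tables are
  byte-reproducible.

## Theoretical graphs and their scoring

Inter-patch distance is the minimum Euclidean distance between patch
boundary-cell centers (centroid distance is available as an option). The
minimum planar graph is approximated by grid Voronoi under uniform
resistance: every cell joins its nearest patch and patches whose regions
share a rook edge are linked; region adjacency keeps the embedding planar
(link counts never exceed 3P - 6).

DIST50 and DIST95 link all patch pairs up to the median and the 95% quantile
(type-7) of realized link lengths. The threshold comparison is *inclusive*:
on a cell grid the length distribution has large atoms (many pairs at
exactly distance 2), and a strict "closer than the median" cutoff deletes
the entire median atom, usually leaving DIST50 empty — a degenerate reading
that cannot be what a distance-threshold model intends. A `strict` switch
restores the literal semantics.

The random model draws the realized number of links uniformly over all
patch pairs of the landscape. Cohen's kappa scores each model's 0/1 link
predictions against the realized 0/1 links over all patch pairs; under the
random model the expected kappa is exactly zero (the chance-corrected
expectation cancels algebraically), which the study uses as a floor.
Because a single draw's kappa is a coarse hypergeometric quantity, chance-
level summaries average an ensemble of random graphs per landscape.

## Information loss

Against the full-trajectory reference, a resampled network is scored by the
proportion of reference patches detected, the proportion of reference links
detected, and the proportion of its own links that are spurious — pairs
bridged only because an intermediate stepping-stone visit fell between kept
fixes. The scripted-trajectory fixtures make this mechanism exact: an
itinerary with known dwell and transit counts determines, by index
arithmetic alone, which stops a given (k, phase) misses and which shortcut
links appear, and the tests hold the pipeline to that enumeration.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the resampling question
interacts with: gradual resource quality, patch mosaics with controllable
fragmentation, residency runs of variable length inside patches, matrix
transits, revisitation driven by memory, and (per process) displacement by
predators or confinement by territoriality. It does not attempt terrain,
circadian rhythm, seasonal range shifts, measurement error, or fix loss —
real telemetry adds all of these on top of the sampling-frequency effect
studied here. Passing tests therefore certify the pipeline's arithmetic and
the simulated regime, not any particular species' field behaviour.

## Problem sizes

The shipped drivers and tests run a reduced study: 10 landscapes per level
in `analysis/02_simulate_networks.R` (the full grid of
`experiment_config()` defaults — 100 landscapes x 3 levels x 4 processes,
resampling 2..50 — is enumerated but not executed by default), 30 landscapes
per level for the pooled scale-free fits, 30 low-fragmentation landscapes
for the kappa summaries, and 100-graph null ensembles. These sizes keep the
whole suite in the low minutes on one core while leaving every qualitative
contrast (topology erosion with k, fragmentation-dependent information
loss, the DIST50 > MPG > random ordering of model accuracy) clearly
resolved.

## Known limitations

* The forager is one instantiation of the correlated-biased-walk family;
  its update equations are deliberately minimal (single memory field,
  resultant-vector bias, shared resource dynamics). Conclusions that hinge
  on fine behavioural detail should swap in a richer model behind
  `simulate_movement()`.
* The minimum planar graph is the uniform-resistance grid-Voronoi
  approximation; no least-cost paths over heterogeneous resistance.
* Networks are binary. Link weights (movement frequencies) carry real
  information that the unweighted formulation discards by design, to match
  the framework under study.
* Empirical-mode ingestion expects regular time steps; irregular gaps are
  reported (optionally carried forward), not modelled.
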