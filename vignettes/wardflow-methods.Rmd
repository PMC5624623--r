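---
title: "Patient-flow network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-flow network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wardflow treats a hospital as a network of wards connected by patient
transfers. This vignette is the package's own account of the models it
implements: what each statistic measures, the assumptions behind it, the
numerical choices made where a definition left room, and what the
synthetic generator does and does not emulate.

## The flow network

Every movement of an admitted patient from one ward to another is a
directed edge event; discharge is an edge into a virtual exit node named
`EXIT` (a reserved word the readers enforce). Aggregating the events of a
time window gives a weighted directed graph: in *count* mode an edge's
weight is the number of matching transfers; in *proportion* mode it is
that count divided by all transfers in the window, which makes windows
with different admission volumes directly comparable. Proportion weights
sum to one per window by construction, the exit node has no out-edges,
and self-transfers are dropped at read time (they carry no flow
information and are usually data artefacts).

A transfer belongs to a site's network if its source *or* target ward is
assigned to that site, so a cross-site move appears in both sites'
networks; per-site proportions are computed over that site's included
transfers only. The admission event itself creates no edge — a patient's
first edge is their first inter-ward move — and there is no virtual entry
node.

Windows follow the calendar: days, ISO weeks starting Monday, or calendar
months. Windows with no transfers yield empty networks that are kept in
the sequence so positions align with the calendar. When the input is a
weekly aggregate table rather than an event log, a week is assigned to
the calendar month containing its Monday; this is an approximation forced
by the weekly resolution and the pipeline marks event-resolution stages
(paths, daily PCA, differential networks) as skipped rather than
approximating them.

## Node statistics

**Degree difference.** A ward's in-degree counts the distinct wards that
send it patients, its out-degree the distinct wards it sends patients to;
weights are ignored. The difference (in minus out) is a structural role:
large negative values mark distributors (the emergency department sends
patients almost everywhere and receives from nowhere), large positive
values mark collectors (the exit node being the extreme case). Computed
per month, the mean difference classifies wards into `in>>out`,
`balanced` and `out>>in`. The threshold (default 10 distinct neighbours)
is a tuning parameter: no principled value exists, 10 is large enough
that only genuinely asymmetric wards leave the balanced group at hospital
scale, and it is exposed as an argument.

**Edge-weight variability.** For a node with $k \ge 2$ input (or output)
edges with count weights $w_1,\dots,w_k$ and mean $\bar w$, the observed
deviation from perfect balance is

$$\mathrm{dev}_{obs} = \frac{\sum_{i=1}^{k} |w_i - \bar w|}{\bar w},$$

and the maximal deviation for the same total and edge count is attained
when $k-1$ edges carry weight 1 and one edge carries the rest:

$$\mathrm{dev}_{max} = \frac{(k-1)(\bar w - 1) +
  \left(\sum_i w_i - \bar w - k + 1\right)}{\bar w}.$$

The score is $\mathrm{dev}_{obs}/\mathrm{dev}_{max} \in [0,1]$: 0 means
every edge carries the mean weight, 1 the most uneven split possible.
Three numerical choices matter:

* the score is computed on **raw counts**, never proportions: the
  extremal configuration anchors edges at weight 1, which presupposes
  integer weights with minimum 1 (proportion-mode networks are converted
  back to counts before scoring);
* when all weights are equal the observed deviation is 0 and the score is
  defined as 0 — including the degenerate all-ones case where the
  maximal deviation is itself 0. A balanced configuration scoring 0 is
  the only reading consistent with the score's meaning, even though the
  ratio is formally 0/0 there;
* the two deviations are computed by algebraically different routes, so
  an exactly extremal vector can land a rounding error above 1; the
  score is clamped at 1.

The score is permutation invariant but deliberately **not** scale free:
doubling all counts changes it, because the reference configuration keeps
its minimum at 1. The tests assert this documented behaviour rather than
scale invariance.

**Path centrality.** Shortest-path centralities are not meaningful here —
the route a patient takes is dictated by clinical need, not graph
distance — so centrality is the fraction of observed admission-to-exit
ward sequences that pass through the node.

## Core and ephemeral sub-networks

The *core* is the set of edges present (count ≥ 1) in **every** monthly
network of a site. Calendar months with zero transfers are excluded from
the intersection (otherwise a single empty month would empty the core)
and reported. The core is summarised per month by the fraction of edges
it contains and the fraction of count-weighted flow it carries; on
heavy-tailed weight distributions the flow fraction far exceeds the edge
fraction. The complement — edges that appear only in some months — is the
*ephemeral* network; the package reports its complement fractions but
does not model it further.

Adding a month can only shrink the core, so short series inflate it with
borderline edges and series of a few months should be interpreted
cautiously; with only two months the intersection is barely a filter at
all.

## Differential networks against A&E performance

Days are ranked by the percentage of A&E patients meeting the 4-hour
target; the top `floor(0.1 n)` form the High group, the bottom
`floor(0.1 n)` the Low group, the remainder Mid. Ties at a decile
boundary are broken by date, earlier first — an arbitrary but
deterministic rule (and a day claimed by High cannot also be claimed by
Low when all values tie). All transfers on the High days (optionally
shifted back by a lag; lag 1 means "the flow on the previous day") are
pooled into one proportion-mode network, likewise the Low days, and the
differential network is the edge-wise difference best minus worst over
the union of the two edge sets, zero-filling absent edges. Days whose
lagged counterpart falls before the start of the data are dropped with a
message rather than wrapped.

Because both networks are compositions summing to one, the differences
sum to zero over the union; the retention rule keeps edges whose
difference deviates from the *mean* difference by strictly more than
`k_sd` (default 2) standard deviations, which is robust in case the mean
is not exactly zero. The standard deviation is computed over the union of
edges — subtraction over differing edge sets requires zero-filling
regardless, and a shared-edges-only convention would discard exactly the
edges that vanish on one side, which are often the interesting ones.
Sweeping the lag from 0 to 14 days and recording the differential
standard deviation locates the horizon at which flow differences
precede performance extremes.

## PCA of daily flow

Each day becomes a vector of edge proportions (zero when absent); edges
present on fewer than 1% of days (strictly) are removed before
decomposition. Columns are centred and by default also scaled to unit
variance — the scaled variant removes any effect of edge magnitude, the
centred-only variant is available via `scale = FALSE`. Zero-variance
columns are dropped with a message when scaling. Component signs are
fixed by making each component's largest-magnitude loading positive, so
loadings are reproducible across runs and platforms. Components are
summarised by their fraction of total variance and by point-biserial
correlations of the day scores with (a) the High-vs-Low performance
label, Mid days excluded, and (b) the weekend flag; an empty label class
yields `NA` rather than an error.

With hospital-sized edge sets the interesting components carry only a
few percent of total variance each — most variance is day-to-day
sampling noise spread over hundreds of edges — so the default keeps 10
components and association scans across all retained ones.

## The synthetic hospital

`default_params()` defines two site profiles matched in scale to a large
teaching hospital ("dh": 385 A&E arrivals/day, 63 wards) and a district
hospital ("pruh": 177 arrivals/day, 46 wards). The study length defaults
to 152 days (five aligned calendar months from 2024-01-01, a Monday);
the long-series checks use 578 days (19 aligned months). Patients arrive
at the A&E ward by a Poisson process, damped by 0.8 on weekends, and
move by a Markov routing chain until discharge, one hop per hospital
day; admissions still in hospital at the study end are censored, and a
30-hop cap bounds pathological walks.

The routing table is a hub-and-spoke layout: A&E routes to every ward
(heavily to two clinical decision units and a ring of gateway admission
wards), gateways feed downstream specialty wards, and every ward can
discharge. Probabilities are chosen so every support edge expects enough
monthly transfers to appear in every monthly network — the support **is**
the planted core, and it carries roughly 90% of transfers at the default
ephemeral rate, matching the regime where a small stable sub-network
sustains most flow.

Three further structures are planted:

* **Ephemeral flow.** With probability 0.15 per transfer the sampled
  target is replaced by one drawn from the source ward's pool of six
  off-route wards. Pools are redrawn every 30 days at a random per-ward
  phase, so ephemeral edges recur for a few weeks but do not persist
  month after month, and the rotation is deliberately *not* aligned with
  the calendar months the analysis bins on. A uniformly random target
  was rejected: at this scaled-down size (46 wards, five months) a
  high-traffic source would hit the same off-route pairs every month,
  which would make them core by the definition above — persistent flow
  *is* core flow, whatever generated it.
* **Weekend effect.** Besides the arrival dip, A&E-to-CDU routing mass
  is multiplied by 0.8 on weekends and every ward's discharge
  probability by 0.6 (rows renormalised). The strong discharge damping
  reflects the well-documented weekend slowdown in hospital discharges;
  because stays span days, it genuinely thins weekend discharges rather
  than merely lengthening same-day paths.
* **Performance coupling.** A latent daily standard-normal "pressure"
  scales the A&E-to-CDU1 routing mass by $(1 - 0.25 z_d)$ and the
  A&E-to-SUR01 mass by $(1 + 0.5 z_d)$. Daily performance is
  $\mathrm{clip}(\beta_0 + \sum_e \beta_e f_e(d - \ell_e) +
  \mathcal N(0, 4^2),\,0,\,100)$ with $f_e$ the edge's
  proportion-of-day flow, $\beta_{CDU} = +100$ and $\beta_{SUR} = -400$
  at lag $\ell = 1$: more CDU flow yesterday means better A&E performance
  today, more surgical flow means worse. The intercepts (69 for
  "pruh", 82 for "dh") put the mean performance near 74.5% and 87%.
  Days whose lagged flow precedes the data start use the edge's mean
  flow as a neutral fill.

A single seeded RNG stream drives the whole simulation; the same
parameter set (including its seed) reproduces records and performance
byte for byte.

**What passing tests do and do not show.** The generator reproduces the
*statistical* structure the analysis assumes — a stable high-traffic
core, rotating rare routes, weekend modulation, lagged flow-performance
coupling — and nothing else. It has no occupancy or queueing constraints,
no length-of-stay distribution beyond one move per day, no elective
stream, no seasonal trend, and its performance model is linear with
Gaussian noise. Recovery of the planted structure therefore validates the
pipeline's correctness and sensitivity in a known regime; it does not
show that real hospital data satisfy that regime. Scale is also reduced:
with five months and ~2000 possible ward pairs the core contains a much
larger *fraction* of edges (~30–45%) than a real 19-month study would
show, although the flow fraction (~90%) is comparable.

## Problem sizes and defaults

The bundled analyses and tests run at district-hospital scale: 177
arrivals/day over 46 wards for 152 days (~70k transfers), ten
replicate seeds for recovery checks, and one 578-day run for the
weekly-aggregate path. These sizes keep every planted property
measurable while the whole suite completes in minutes on one CPU; all of
them are ordinary function arguments, and nothing in the package depends
on these particular values.

## Known limitations

* Ward-to-site assignment is derived from the site column of the event
  log; a ward that genuinely serves two sites is assigned to both, and
  site-level proportions then count its cross-site transfers in each.
* The core definition is binary presence per month; an edge missing in a
  single month for administrative reasons (ward closure, recoding) drops
  out of the core entirely. Pre-cleaning ward identifiers matters.
* The differential analysis is purely associational; nothing here
  supports causal claims about flow and performance.
* Sequence statistics treat similar-but-unequal ward sequences as
  distinct; no alignment or clustering of near-identical pathways is
  attempted.
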