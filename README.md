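# wardflow

Network analysis of patient flow between hospital wards.

Intra-hospital patient transfers form a temporal weighted directed graph:
wards are nodes, a patient moving from ward *u* to ward *v* is a directed
edge event, and discharge is an edge into a virtual exit node. wardflow is
for hospital analysts and health-services researchers who have a transfer
log (one row per move, with timestamps and site labels) and a daily A&E
performance series (% of patients meeting the 4-hour target), and want to
understand which parts of the flow network are stable, which are
ephemeral, and which carry the traffic that moves with emergency-department
performance.

## What it computes

* **Flow networks per window** — daily / ISO-weekly / monthly snapshots
  with count or proportion edge weights (proportions sum to 1 per window,
  so windows with different admission volumes are comparable).
* **Node statistics** — in/out-degree difference and role classification
  (`in>>out` / `balanced` / `out>>in`); path-based centrality (fraction of
  observed admission-to-exit sequences through a ward); and an
  **edge-weight variability score**: for a node with *k* ≥ 2 input (or
  output) count weights *w₁…w_k* with mean *w̄*,

  ```
  dev_obs = Σ|wᵢ − w̄| / w̄
  dev_max = ((k−1)(w̄−1) + (Σwᵢ − w̄ − k + 1)) / w̄
  score   = dev_obs / dev_max   ∈ [0, 1]
  ```

  0 = perfectly balanced weights, 1 = as uneven as the total allows.
* **Core sub-network** — edges present in *every* monthly network, with
  the fraction of edges and of flow they account for per month.
* **Ward sequences** — per-admission path reconstruction, unique-sequence
  frequencies, and the number of top sequences needed to cover a target
  fraction of visits.
* **Differential networks** — days grouped into best/worst 10% by A&E
  performance; flow pooled per group (optionally lagged); edge-wise
  best-minus-worst differences with >2 SD retention; and a 0–14-day lag
  sweep of the differential spread.
* **PCA clustering** — daily edge-proportion vectors (edges on <1% of
  days removed), centred and scaled, with point-biserial association of
  each component against the High/Low performance labels and the
  weekday/weekend split.
* **Synthetic hospital** — a seeded discrete-event generator with planted
  core, rotating ephemeral routes, weekend modulation and lag-1
  performance coupling, returning the ground truth alongside the data.

## Worked example

Simulate a district-hospital site (177 A&E arrivals/day, 46 wards, five
months) and run the main analyses:

```r
library(wardflow)

sim <- simulate_hospital(default_params("pruh", n_days = 152, seed = 1))
nrow(sim$records)
#> [1] 71168

nets <- windowed_networks(sim$records, "month", site = "PRUH")
core_flow(nets)
#> <core_result> 198 core edges over 5 windows
#>   edge fraction: 35.1% (SD 0.48%)
#>   flow fraction: 90.3% (SD 0.19%)
```

A third of the edges are present in every month, and they carry 90% of
all transfers — the remaining two thirds are ephemeral routes that carry
10%. The most common pathways run through the clinical decision units:

```r
freqs <- sequence_frequencies(reconstruct_paths(sim$records))
head(freqs, 3)
#>    rank path         count fraction cumulative_fraction
#> 1     1 AE>CDU1>EXIT  4676   0.184                0.184
#> 2     2 AE>CDU2>EXIT  1988   0.0783               0.262
#> 3     3 AE>EXIT        661   0.0260               0.288
top_k_coverage(freqs, 0.5)
#> [1] 23
```

Relating flow to performance: the differential spread peaks at a lag of
one day, and the retained edges recover the planted coupling — more CDU
flow the day before the best days, more surgical flow before the worst:

```r
lag_sweep(sim$records, sim$perf, site = "PRUH", max_lag = 3)
#>   lag           sd n_retained
#> 1   0 0.0015980545          8
#> 2   1 0.0023910399          5
#> 3   2 0.0006911427         33
#> 4   3 0.0007726261         28

lagged_differential(sim$records, sim$perf, site = "PRUH", lag = 1)$retained
#>   source target     diff sd_units direction
#> 1 AE     CDU1    0.0624     26.1  better
#> 2 AE     SUR01  -0.0181     -7.58 worse
#> 3 AE     CDU2   -0.00913    -3.82 worse
#> ...
```

Unsupervised clustering of the daily networks finds a weekend component
without being told about weekdays:

```r
dem <- daily_edge_matrix(sim$records, site = "PRUH", perf = sim$perf)
assoc <- component_association(run_flow_pca(dem, 15))
assoc[which.max(abs(assoc$r_weekend)), ]
#>   component variance_fraction r_high_low r_weekend
#> 1       PC6            0.0129      0.343    -0.653
```

`run_flow_analysis()` orchestrates all stages and can write the results
as a CSV bundle with a SHA-256 manifest; a thin command-line front end is
installed at `inst/cli/wardflow` (`wardflow simulate ...`,
`wardflow run ...`).

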