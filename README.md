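# rwinf — superspreader identification in weighted human contact networks

Proximity sensors record who was near whom as timestamped pair records,
one per 20-second sampling window.  `rwinf` turns such streams into static
weighted contact graphs in which each edge carries the **total contact
duration** between a pair, and ranks individuals by their expected role in
an epidemic with the **RWInf** (Real Weighted Influence) score.  It is
aimed at infectious-disease modellers and network epidemiologists working
with face-to-face contact data (schools, hospitals, workplaces,
conferences).

## The method

Records for a pair are merged into sessions (maximal runs with
inter-record gaps ≤ one sampling window Δ); a session over timestamps
t₁ < … < tₙ spans [t₁ − Δ, tₙ], and the edge weight is the summed session
length:

```
W(u,v) = Σ_sessions (et − st)        (seconds of contact)
```

On the resulting graph G(V, E, W):

```
nwI(v)   = Σ_{u ∈ N(v)} W(v,u)              neighbourhood weighted influence
smlI(v)  = Σ_{u ≠ v} nwI(u) / cd(v,u)       cd = hop distance ("level")
ld(v)    = (triangles(v) + 1) · k(v)        local density
RWInf(v) = ld(v) · smlI(v)
```

The highest RWInf is rank 1, the predicted superspreader.  For comparison
the package ships eight weighted baselines (weighted k-shell, Wks, ksdʷ,
ngsc, HIC, weighted degree/betweenness/closeness), a discrete-time SIR
simulator (recovery probability λ = 1) whose mean outbreak size per seed
node is the ground truth, and the evaluation metrics: Kendall's τ-b
against SIR, its average σ(τ) over the grid β = β_th + 0.01·i with
β_th = ⟨k⟩/⟨k²⟩, ranking monotonicity M(I), and improvement percentage η.

## Worked example

```r
library(rwinf)

g <- generate_weighted_graph("erdos_renyi", n = 40, model_param = 0.12, seed = 7)
epidemic_threshold(g)
#> 0.1776

head(rank_nodes(rwinf_scores(g)), 5)
#>   node    score rank
#> 1 n004 494396.3    1
#> 2 n002 470330.0    2
#> 3 n016 334020.3    3
#> 4 n007 319883.5    4
#> 5 n017 244476.3    5

report <- evaluate_all(g, indices = c("rwinf", "wkshell", "wdeg", "hic"),
                       iter = 5, runs = 500, seed = 7)
round(report$sigma_tau, 3)
#>   rwinf wkshell    wdeg     hic
#>   0.672   0.596   0.394   0.764
```

`rank_nodes()` lists nodes by decreasing RWInf (rank 1 = most influential;
node n004's score is ld × smlI in weight units).  `report$sigma_tau` is
each index's Kendall τ-b against the SIR mean outbreak sizes, averaged over
five infection probabilities just above the epidemic threshold 0.178 —
higher means the index orders nodes more like the simulated epidemics do.
`report$monotonicity` and `report$improvement` give M(I) per index and the
per-β improvement of RWInf over each comparator.

For real sensor data, replace the generator with

```r
events <- read_contact_events("contacts.tij.gz", dialect = "tij")
g <- build_weighted_graph(events, interval = 20)
```

A command-line front end with `weigh`, `rank`, `simulate`, `evaluate` and
`synth` subcommands is installed at `system.file("cli", "rwinf.R",
package = "rwinf")`.

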