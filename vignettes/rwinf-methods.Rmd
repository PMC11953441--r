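---
title: "Contact-duration weighting and the RWInf superspreader score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-duration weighting and the RWInf superspreader score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwinf)
```

## The problem

Proximity-sensor deployments (schools, hospitals, workplaces, conferences)
record face-to-face contacts between badge-wearing individuals as
timestamped pair records, one per 20-second sampling window.  For
epidemiological use, who is a likely superspreader depends not only on how
many contacts a person has but on how long each contact lasts: transmission
probability grows with exposure time.  Most influence indices treat the
contact graph as unweighted, or derive edge weights from topology (degree,
k-shell), which throws that temporal information away.

`rwinf` implements the alternative: derive each edge's weight as the total
contact duration between the pair, then rank individuals with the RWInf
score, and judge any index against simulation ground truth.

## From pings to edge weights

A pair's records are merged into *sessions*: maximal runs of records whose
inter-record gap does not exceed `max_gap` (default one sampling interval,
20 s).  Each record asserts contact during the *preceding* window, so a
session over timestamps $t_1 < \dots < t_n$ is taken to start at
$t_1 - \Delta$ and end at $t_n$, giving duration $t_n - t_1 + \Delta$; an
isolated ping contributes one full window, never zero.  The edge weight is

$$W_{uv} = \sum_{\text{sessions } f} (et_f - st_f),$$

the total seconds of contact.  The session-boundary convention is genuinely
open — the alternative ($st = t_1$, isolated pings contribute nothing)
discards all single-ping contacts, which in sparse deployments is most of
them, so the window-inclusive convention is the default; `max_gap` is
exposed because real deployments drop pings.  Timestamps must be integers
(seconds); non-integer stamps are rejected rather than silently rounded,
and node identifiers are kept as opaque strings so badge IDs with leading
zeros survive.  Column order is an explicit flag (`tij` or `ijt`), never
auto-detected.

Some published datasets ship pre-thresholded ordinal weights instead of
durations; `ordinal_weight()` maps seconds onto that four-level scale
(< 5 min, 5–15 min, 15 min–1 h, ≥ 1 h).  The category descriptions overlap
at their boundaries, so the implementation makes the upper category
left-closed (exactly 300 s is level 2) and tests pin that choice.

## The RWInf score

For a weighted contact graph $G(V, E, W)$:

* **Neighbourhood weighted influence** $nwI(v) = \sum_{u \in \phi(v)} W_{vu}$
  — total contact time with direct neighbours.
* **Contact distance** $cd(v, u)$ — the shortest-path *hop count* between
  $v$ and $u$.  The generic shortest-path machinery would admit
  duration-weighted lengths, but the published worked computation divides
  by small integers 1–4, i.e. levels, and duration-weighted lengths would
  perversely penalise strong ties; hop counts are therefore the default,
  with `distance = "weighted-inverse"` (lengths $1/W$) available for
  sensitivity analysis.
* **Single-and-multiple-level influence**
  $smlI(v) = \sum_{u \ne v} nwI(u)/cd(v, u)$.  Unreachable nodes contribute
  0 (the $1/\infty$ limit); connected graphs are the intended domain.
* **Local density** $ld(v) = (\text{triangles}(v) + 1) \cdot k(v)$, with
  degree and triangles taken on the unweighted skeleton.  The $+1$ keeps
  triangle-free nodes in play; isolated nodes score 0 through the degree
  factor.
* **RWInf** $= ld(v) \cdot smlI(v)$; rank 1 is the most influential node.

Because $cd$ and $ld$ are weight-free, multiplying every weight by $c > 0$
scales $nwI$, $smlI$ and RWInf by exactly $c$ — a property the tests assert.
Ranking uses competition ranks (ties share the smaller rank) with ties
ordered by node identifier, so output is deterministic even though ties are
rare in practice.

The package embeds the published 26-node worked computation as a fixture
(`worked_example_fixture()`): feeding its printed $nwI$ values and distances
into `smli_from_tables()` must give 154.333 (3-decimal rounding), and a node
with degree 5 in 5 triangles has $ld = 30$, hence RWInf $= 4629.99$.  The
toy network's full adjacency is not recoverable, so only this fixture is
shipped.

## Comparison indices

Eight baselines are provided behind one dispatcher, `compute_index()`:

| name | definition |
|---|---|
| `wkshell` | shells peeled on $k' = [k^{\alpha_1} (\sum W)^{\beta_1}]^{1/(\alpha_1+\beta_1)}$, $\alpha_1 = \beta_1 = 1$ |
| `wks` | $\alpha_1 k + (1-\alpha_1)\sum_{u}(k_v + k_u)$, $\alpha_1 = 0.5$ |
| `ksdw` | $\sum_u (\alpha_1 k_v + \mu_1 ks_v)(\alpha_1 k_u + \mu_1 ks_u)$ |
| `ngsc` | $\sum_u (t_1 ks_v + t_2 k_v) + (t_1 ks_u + t_2 k_u)$ |
| `hic` | $\sum_u H_v I_v/(1+C_v) + H_u I_u/(1+C_u)$ |
| `wdeg` | $\sum_u W_{vu}$ (= $nwI$, kept as a named baseline) |
| `wbet` | weighted betweenness, edge lengths $1/W$ |
| `wclo` | weighted closeness, same lengths |

Numerical choices that the sources leave open, decided here once:

* The HIC *k-shell iteration factor* $I$ has no published formula; the
  convention from the H-index/coreness literature,
  $I_v = ks_v (1 + n_v/m)$ with $n_v$ the pruning round at which $v$ is
  removed and $m$ the total number of rounds, is adopted and isolated in
  one function so an alternative is a one-line swap.
* `wkshell`'s blended degree $k'$ is real-valued; it is rounded half-up
  (deterministically, avoiding banker's rounding) before peeling, and $k'$
  is recomputed from the residual graph after every removal wave.  With all
  weights 1 it provably reduces to the plain k-shell, which the tests
  assert.
* The `ksdw`/`ngsc` tunables are described in their sources as chosen from
  the giant component without a reproducible rule; the defaults here are
  $\alpha_1 = \mu_1 = t_1 = t_2 = 0.5$, all overridable through `params`.
* For `wbet`/`wclo`, durations are tie *strengths*, not costs, so edge
  lengths default to $1/W$ (stronger ties are shorter); a `raw_weight` mode
  exists because the convention is not stated in the baseline literature.
* Structural indices (`wks`, `ksdw`, `ngsc`, `hic`) depend on topology only;
  rescaling all weights leaves them fixed, another tested invariant.

## SIR ground truth

Spreading capability is measured with a discrete-time synchronous SIR
process: a single seed node is infected; each step, every infected node
independently infects each susceptible neighbour with probability $\beta$,
then recovers with probability $\lambda$ (default 1, i.e. one infectious
step); nodes infected at step $t$ transmit from step $t+1$.  The process
ends when no infected remain and returns the recovered count (seed
included).  A node's ground-truth influence is the mean over `runs`
repetitions (default 1000).

Transmission ignores edge weights by default: the threshold formula
$\beta_{th} = \langle k \rangle / \langle k^2 \rangle$ and the baseline
literature are unweighted-SIR conventions, and using an unweighted ground
truth keeps the evaluation method-agnostic.  A `weighted` mode
(per-contact probability $1 - (1-\beta)^{W/\Delta}$, treating a weight as
$W/\Delta$ independent exposure windows) is available for sensitivity
studies.

Randomness is reproducible by construction: each (β, source) pair gets a
substream seeded deterministically from the root seed, so per-node scores
do not depend on evaluation order, and two runs with the same seed are
bitwise identical.

## Evaluation metrics

* **Kendall's τ** between an index and the SIR scores, in the tie-corrected
  τ-b variant (both sides carry ties); computed on raw scores, which is
  equivalent to computing it on ranks.
* **σ(τ)**: τ averaged over the grid $\beta_i = \beta_{th} + 0.01 i$,
  $i = 1..iter$ (default $iter = 15$); values above 1 are dropped with a
  warning.  An absolute β grid can be supplied instead — the two readings
  of the sweep that circulate (threshold-anchored vs fixed
  $[0.01, 0.15]$) are both supported, with the threshold-anchored rule as
  the default.
* **Monotonicity** $M(I) = [1 - \sum_i V_i(V_i-1) / (V(V-1))]^2$ over
  tie-group sizes $V_i$: 1 for an all-unique ranking, 0 for all-tied.
* **Improvement percentage**
  $\eta = (\tau_{ref} - \tau_{cmp})/|\tau_{cmp}| \cdot 100$, defined 0 when
  $\tau_{cmp} = 0$.

`evaluate_all()` wires these together and `graph_summary()` reports the
usual network descriptors (mean degree, diameter, mean path length, mean
local clustering, $\beta_{th}$), computed on the largest component with a
warning when the graph is disconnected.

## Synthetic data, and what the tests do and do not show

`generate_contact_stream()` emulates the structure of a proximity
deployment: per pair, sessions arrive with geometric inter-session gaps and
geometric lengths in 20-s ticks, every active tick emits a record, and the
generator returns its sessions and per-pair totals as ground truth.
Session starts sit on the tick grid and inter-session gaps are at least two
ticks, so sessionizing with `max_gap = interval` must recover the ground
truth *exactly* — the central generator-versus-pipeline test.  Defaults
(50 individuals, 8-hour horizon, 0.2 sessions/pair/hour, mean session
60 s) are plausible for a one-day workplace deployment and were fixed once;
they are conditions for testing, not estimates of any real dataset.

`generate_weighted_graph()` draws topology from Erdős–Rényi,
Barabási–Albert or ring models with heavy-tailed lognormal(4, 1) weights
(seconds), mimicking the skew of empirical contact durations.

What passing tests show: the operations implement their definitions exactly
(brute-force oracle equivalence on hundreds of small random graphs), the
session algebra is lossless, the SIR simulator matches closed forms, and
the whole pipeline is deterministic.  What they do not show: that RWInf
outperforms the baselines on real contact networks — that claim concerns
the six public SocioPatterns datasets, which this package does not
redistribute.  Users who download them can reproduce that analysis with
`read_contact_events()` → `build_weighted_graph()` → `evaluate_all()`, and
the synthetic generator makes no attempt to replicate those datasets'
empirical degree or duration distributions.

Problem sizes in the shipped test-suite and examples (graphs of 6–50 nodes,
SIR sweeps with tens to ten thousand repetitions) were chosen so the whole
suite runs in well under a minute while keeping Monte-Carlo assertions at
3-standard-error strength.

## A worked run

```{r example, eval = FALSE}
stream <- generate_contact_stream(n_individuals = 30, seed = 1)
events <- parse_contact_events(format_tij(stream$events))
g <- build_weighted_graph(events, interval = 20)

head(rank_nodes(rwinf_scores(g)))

report <- evaluate_all(g, indices = c("rwinf", "wkshell", "wdeg"),
                       iter = 5, runs = 500, seed = 1)
report$sigma_tau
```

## Known limitations

* Directed or signed contacts are out of scope; graphs are simple and
  undirected.
* `smlI` recomputes all-pairs hop distances from scratch; there is no
  incremental update under edge insertions.
* On disconnected graphs, unreachable pairs simply contribute nothing to
  `smlI` and closeness; interpret scores per component.
* The SIR simulator is discrete-time only (no Gillespie dynamics, no
  SEIR/SIS variants, no interventions).
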