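---
title: "Norms and metanorms on interaction networks: model, analysis and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norms and metanorms on interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A population of `n` agents sits on an undirected, unweighted interaction
network. Each agent carries two heritable traits, each encoded as a 3-bit
string taking the eight values `0/7 .. 7/7`:

* **boldness** `b` — the propensity to defect, and
* **vengefulness** `v` — the propensity to punish observed defections and
  to meta-punish observed non-punishments.

One *round* of the game has three stages:

1. **Defection.** Each agent draws an observability value `s ~ U(0,1)` and
   defects iff `b > s`. A defector gains the temptation payoff `T` and
   inflicts the hurt payoff `H` on every other agent in the population:
   the spillover of defection is global, while sanctioning below is
   strictly local to the network.
2. **Punishment.** Each network neighbour of a defector observes the
   defection independently with probability `s` (the defector's own
   draw: sneaky defections are also hard to observe) and, if it observes,
   punishes with probability equal to its vengefulness, paying the
   enforcement cost `E` while the defector receives the punishment
   payoff `P`.
3. **Meta-punishment.** For each observed-but-unpunished defection, every
   common neighbour of the defector and the non-punisher sees the lapse
   with the same probability `s` and meta-punishes with probability equal
   to its vengefulness, paying `ME` while the non-punisher receives `MP`.
   Meta-punishment therefore requires a *triangle* of links: defector,
   non-punisher and meta-punisher must be pairwise connected.

Four rounds form a *generation*. Payoffs are reset at the start of each
generation and accumulated across its rounds. At the end of a generation
all agents update synchronously by local roulette-wheel selection: agent
`i` considers the candidate pool `N(i) + {i}`, gives each candidate a
fitness equal to its accumulated payoff minus the pool minimum, and copies
the joint (boldness, vengefulness) bit-string pair of one candidate drawn
with probability proportional to fitness; when all fitnesses are zero the
draw is uniform. Every bit of each copied string then flips independently
with the mutation rate. The default configuration is

```{r}
library(metanorms)
game_config()
#> payoffs T=3 H=-1 E=-2 P=-9 ME=-2 MP=-9, mutation 0.01/bit,
#> 4 rounds/generation, 50000 generations, 50 agents
```

Including the focal agent in the candidate pool is a deliberate choice
(`include_self`, switchable): excluding self forces even the locally best
agent to churn its strategy and leaves isolated agents without a pool.
Mutation applies on every replication, including self-replication.
Multiple neighbours may punish the same defection; punishments are
cumulative. One global RNG stream drives a run; events are executed in a
fixed order (stage 1 over agents, stages 2-3 nested per defection in
agent-index order), so a run is bit-reproducible from `(network, config,
seed)`.

## Topology statistics

Two numbers dominate the dynamics:

* the **average degree** ⟨k⟩, and
* the **interconnectedness** Λ: the mean number of *triplets* per agent,
  i.e. linked pairs among an agent's neighbours (triangles through the
  agent). Λ = 3 × (#triangles) / n.

`network_stats()` also reports the degree distribution and the mean
clustering per degree class; agents with fewer than two neighbours have
undefined clustering and are counted as 0 in aggregates (they contribute
no triplets either way). `radius2_closure()` links all pairs at
shortest-path distance ≤ 2, the "radius 2" interaction regime in which
agents can also sanction neighbours of neighbours.

## The analytic abstraction

Relaxing both traits to the continuum and exploiting that one defection's
observability draw `s` is shared by all its observers, the relevant
moments for a defector with boldness `b` are `P(defect) = b`,
`E[s·1(s<b)] = b²/2` (observed defection) and `E[s²·1(s<b)] = b³/3`
(observed defection plus observed non-punishment).
`expected_payoff_exact()` sums the six payoff channels over all
defector/observer/meta-observer configurations of an arbitrary network.
For a homogeneous population the population-mean expected one-round
payoff collapses to the closed form

    pi(b, v) = b T + (n-1) b H + <k> (b^2/2) v (E + P)
               + 2 Lambda (b^3/3) v (1-v) (ME + MP)

which depends on the topology only through ⟨k⟩ and Λ. The factor `2Λ`
counts ordered triplets; `v(1-v)` pairs a vigilant meta-punisher with a
lapsing observer. The *binding* correctness contract for these closed
forms is statistical equivalence with the stochastic engine:
the test suite checks simulated mean one-round payoffs against the
formulas within Monte-Carlo error on complete, ring and random topologies
at 10^5 rounds, and the exact and homogeneous forms against each other
(agent-wise on vertex-transitive graphs, population-mean on any graph).

### Mutant gradients and stable states

`mutant_payoff()` embeds a lone deviant `(b_m, v_m)` — with the network's
average statistics — in an incumbent population at `(b, v)`; incumbent
behaviour is held fixed. The drift field of the gradient maps is its
gradient at `mutant = incumbent`:

    d pi_m / d b_m = T + P <k> v b
    d pi_m / d v_m = E <k> b^2/2 + 2 Lambda (b^3/3) (ME (1-v) - MP v)

The mutant payoff is *quadratic* in `b_m` (curvature `P⟨k⟩v ≤ 0`) and
*linear* in `v_m`. Two consequences shape `find_ess()`:

* interior vengefulness can at best be neutrally stable, so strict
  evolutionary stable states lie on the edges `v = 0` or `v = 1`;
* at the box boundaries stability is a sign condition (the gradient must
  point out of the feasible square), not a stationarity condition —
  derivatives need not vanish at corners.

The solver scans each `v` edge for sign changes of the boldness gradient
(refined by `uniroot`), adds boundary candidates under those
Karush-Kuhn-Tucker-style conditions, and then requires the vengefulness
slope to press against the occupied edge. Under the default payoffs this
yields the **norm-collapse state** `(b, v) = (1, 0)`, stable on *every*
topology, and — when Λ is large enough — a **cooperative state**
`(b*, 1)` with `b* = -T/(P⟨k⟩)`, i.e. boldness just small enough that
temptation no longer pays against full vigilance. An ESS is labelled
*cooperative* when `b ≤ 1/2` and `v ≥ 1/2`: the establishment-zone bound
`b ≤ 1/7` would misclassify genuinely vigilant rest points on sparse
networks, where `b* = -T/(P⟨k⟩)` exceeds `1/7` once `⟨k⟩ < 7/3`.

Requiring the cooperative state to be stable in `v` gives a smallest
admissible interconnectedness for each average degree;
`minimal_interconnectedness()` finds it by bisection (absolute tolerance
`1e-4`, existence monotone in Λ). For the default payoff matrix the
threshold works out to `Λ* = ⟨k⟩²/2` — close to the maximum
`C(⟨k⟩, 2)` attainable by a ⟨k⟩-regular topology, so homogeneous sparse
networks essentially never admit the cooperative ESS at radius 1;
degree-heterogeneous, highly clustered networks (e.g. radius-2 closures
of preferential-attachment graphs) can clear it. The simulations below
nevertheless find substantial norm-establishment time on networks *below*
the threshold: finite populations, mutation and the variance of local
selection can seed and hold the norm where the infinite-population
abstraction says it cannot persist — which is why the analytic and
simulated layers are kept as two independent, mutually checking routes.

## Network generators

Three seeded generators supply study networks; their construction
dialects are fixed so that `(parameters, seed)` reproduces an edge set
bit-for-bit:

* `generate_ba(n, m)` — preferential attachment seeded from a complete
  graph on `m` nodes, attachment without replacement; `m = 1` yields
  trees (triangle-free controls).
* `generate_watts(n, k, beta)` — ring lattice with one endpoint of each
  lattice edge rewired with probability β to a uniform non-neighbour;
  β interpolates from regular lattice to an essentially random graph at
  constant edge count.
* `generate_er(n, p)` — independent edges; `p = 1` gives the complete
  graph used for the collapse-state checks.

These emulate the degree heterogeneity, clustering and randomness ranges
of the study design but not, deliberately, community structure, weighted
or directed ties, or coevolving topology; conclusions from passing tests
extend only that far.

## Experiments

Two zones partition the interesting corners of the strategy square
(boundaries inclusive): **norm collapse** (mean boldness ≥ 6/7, mean
vengefulness ≤ 1/7) and **norm establishment** (mean boldness ≤ 1/7,
mean vengefulness ≥ 6/7). With positive mutation the simulation is an
ergodic finite Markov chain, so long-run zone frequencies approximate the
occupancy distribution; `occupancy()` counts them (no burn-in by default
— the initial transient is a vanishing fraction of the runs used).

`sample_network_ensemble()` draws networks across generator grids
(`m` 1-5, Watts `k` 2-12 with β from 0 to 1, Erdős–Rényi `p` 0.05-0.5,
half the sample expanded to radius 2), spanning average degrees ~2-49 and
√Λ up to ~34 at `n = 50`, so that degree and interconnectedness can be
disentangled across the sample.
`sweep_occupancy()` runs each network under deterministically spawned
child seeds. The headline topology effect is tested with
`occupancy_trend()`, whose default statistic is the *partial Spearman
rank correlation* (rank-residual method): over wide ensembles ⟨k⟩ and Λ
are strongly collinear, and coarse quantile bins fail to hold the
conditioning variable fixed — the binned heatmap-style estimate remains
available via `n_bins`. At the scales used in the test suite (40
networks × 3 seeds × 5000 generations) establishment time rises with
interconnectedness at fixed degree (partial correlation ≈ +0.6) and
falls with degree at fixed interconnectedness (≈ −0.3).

### Zone exhaustiveness at this population size

The claim that time outside the two zones is negligible does **not**
reproduce under these mechanics at 50 agents: the sweep above spends
roughly 40 % of generations in neither zone, and the suite's
corresponding check is expected to fail at its < 0.2 bound. Two
mechanisms account for it, both visible in single trajectories:

* During establishment episodes mean boldness settles near
  `b* = -T/(P⟨k⟩) ≈ 0`, defections — and with them punishment and
  meta-punishment events — become rare, selection on vengefulness almost
  vanishes, and `v` random-walks below the 6/7 zone boundary for long
  stretches while the population remains fully norm-compliant.
* On sparse, triplet-poor networks (⟨k⟩ ≈ 2-4) punishment is strong
  enough to hold boldness interior but selection is too weak against
  mutation noise to reach either corner: a mutation-selection stasis in
  mid-space.

Both persist whether or not the focal agent is in the selection pool.
The establishment-adjacent drift, in particular, means the 6/7 zone
boundary undercounts norm compliance; the trend results above are
unaffected (they compare zones across topologies, not against an
absolute bound).

### Empirical drift maps

`empirical_drift_map()` initializes the population homogeneously at each
grid cell's nearest 8-level strategy and measures the mean per-generation
displacement of the population means (defaults: 200 replicates, horizon
1 generation). One caveat discovered while validating it: from an exactly
homogeneous start, *one* generation of selection cannot move the means —
every candidate carries the same strategy, so horizon-1 displacement is
pure mutation drift (and is identical under any payoff matrix with the
same seed). A selection signal requires horizon ≥ 2, and the clean
comparison subtracts a payoff-free control map run with the same seed
and replication layout. Done this way (horizon 3, 80 replicates), drift
directions on the complete 20-agent graph align with the analytic
gradient field at a mean cosine similarity of about 0.8.

## Numerical choices

* Gradient zero threshold `1e-8`; ESS edge scan 201 points with
  `uniroot` refinement; bisection tolerance `1e-4` (threshold stable to
  < 1 % under tolerance halving).
* Analytic gradient map default 71 × 71; all-zero payoff configurations
  yield the zero field rather than an error.
* Degenerate roulette pools (all fitnesses equal) draw uniformly;
  isolated agents always retain themselves as sole candidate.
* Problem sizes in the test suite are the package's own defaults for
  routine verification: 10^5 rounds for Monte-Carlo/closed-form
  equivalence (3-standard-error band), 5000-generation runs for
  occupancy, 40-network ensembles. Full-scale experiments
  (50000 generations, thousands of networks) run through the same
  functions by changing `game_config()` and the ensemble size.

## Known limitations

* The ESS conditions implemented are necessary, not sufficient, for
  heterogeneous populations; the simulator is the arbiter of actual
  long-run behaviour.
* The analytic layer treats the mutant as embedded at the network's
  *average* degree and interconnectedness; on strongly heterogeneous
  networks per-node placement matters and is visible as the
  below-threshold establishment noted above.
* No community-structure generators, weighted/directed ties, dynamic
  topology, or asynchronous updating.
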