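---
title: "Modelling the co-evolution of cooperation and prejudice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the co-evolution of cooperation and prejudice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`prejsim` simulates a population of agents that cooperate through
*indirect reciprocity*: one-shot donation games in which a donor may pay a
cost $c$ to give a recipient a benefit $b > c$, with no prospect of direct
reciprocation. Donation decisions are driven by *social comparison of
reputations*, and the novel ingredient is *prejudice*: each agent carries a
level $\alpha_i \in \{0, 0.25, 0.5, 0.75, 1\}$ by which it discounts the
reputation of anyone outside its own group before comparing.

Each agent $i$ is described by a six-element social comparison heuristic

$$H_i = (s_i, u_i, d_i, \alpha_i, P_i, S_i)$$

* $s_i, u_i, d_i \in \{0,1\}$ — donate on *similarity* (equal reputation),
  *upward* self-comparison (recipient higher) or *downward* self-comparison
  (recipient lower);
* $\alpha_i$ — the prejudice level;
* $S_i$ — the probability of choosing an in-group recipient;
* $P_i$ — the probability of in-group (versus population-wide) strategy
  learning at the reproduction step.

Agents also carry an immutable trait $t_i$ partitioning the population into
sub-populations. A **prejudicial group** $G_{t,\alpha}$ is the maximal set
of agents sharing both trait $t$ and prejudice level $\alpha$: the
prejudicial attitude itself acts as a phenotypic tag around which groups
form. Groups partition each sub-population; everyone not sharing both the
trait and the attitude is out-group.

### Reputations and assessment

Every agent holds two integer reputations on $[-5, 5]$: a *universal*
reputation $r_i^U$ (standing as if no groups existed) and an *in-group*
reputation $r_i^G$ (standing as judged by the agent's own group, applying
its prejudice to out-group recipients). Both follow a generalized
*standing* norm:

* a donation increments the reputation (saturating at $+5$);
* a defection decrements it (saturating at $-5$) **unless** the recipient's
  relevant reputation is strictly below the donor's — "legitimate
  shirking". Equal standing is not legitimate.

For $r^U$ the comparison uses raw universal reputations. For $r^G$ an
in-group recipient is judged on $r_j^G$, while an out-group recipient is
judged on the discounted $r_j^U (1 - \alpha_i)$. Prejudice therefore
shields an agent's in-group standing when it defects on out-group members —
but never its universal standing.

### Action rule

A donor $i$ compares $r_i^G$ against the recipient's effective reputation
($r_j^G$ in-group, $r_j^U (1 - \alpha_i)$ out-group) and donates according
to the bit ($s_i$, $u_i$ or $d_i$) matching the comparison outcome. With
probability $S_i$ the recipient is drawn uniformly from the donor's group
(excluding itself), otherwise uniformly from outside the group. If the
donor's group is a singleton and the in-group branch is drawn, no
interaction occurs ("null event"): no cost, no donation, no assessment.

### Selection

A generation is `games_per_generation` (default 5000) games with the donor
drawn uniformly with replacement. At the end of a generation each agent
reproduces with probability 0.10 (the gate damps drift in small groups).
A reproducing agent copies another agent's entire heuristic — from its own
group with probability $P_i$, from the whole population otherwise — with
probability proportional to fitness

$$f_i = tp^{*} + tp_i + \delta,$$

where $tp_i$ is the agent's net payoff this generation, $tp^{*}$ is the
magnitude of the most negative payoff in the population (0 if none is
negative) and $\delta = 1$. The shift guarantees $f_i \ge \delta > 0$, so
proportional selection is always well defined; $tp^{*}$ is read as a
magnitude because a signed value would produce negative fitnesses. Each
element of a newly copied heuristic then mutates independently with
probability 0.01 (binary bits flip; $\alpha$, $S$, $P$ resample uniformly
from their grids). Mutation applies only to agents that reproduce: the
copied heuristic is what mutates, and non-reproducers carry their
heuristic forward unchanged. Traits are never copied. Reputations and
payoffs reset to zero at each generation boundary.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 100 | population size |
| `trait_sizes` | 5 × 20 | sub-population sizes (explicit list for imbalance) |
| `games_per_generation` | 5000 | donation games per generation |
| `b`, `cost` | 1.0, 0.7 | benefit and cost; only $c/b = 0.7$ is meaningful |
| `mutation_rate` | 0.01 | per-element mutation probability |
| `reproduction_chance` | 0.10 | per-agent reproduction gate |
| `delta` | 1 | fitness floor constant |
| `evolve_S`, `evolve_P` | `TRUE` | evolve on `{0, ..., 0.9}` or fix exogenously |
| `evolve_alpha` | `TRUE` | set `FALSE` to pin prejudice (base-model reduction) |
| `init_alpha` | 0 | initial prejudice (0, 1, or per-agent vector) |

Only the cost/benefit *ratio* matters for the dynamics up to the $\delta$
offset, because fitness is affine in payoff scale; we fix $b = 1$ and
expose both values. The action rules are initialized uniformly at random
in every scenario (the emergence scenario states this explicitly; the
fixed-$(S,P)$ scenarios state only the initial prejudice, and we adopt the
same random initialization, exposed as `init_sud`).

## Design choices

* **Quarter-unit integer arithmetic.** $\alpha$ is a multiple of 0.25 and
  reputations are integers, so every comparison is computed as
  `4 * r` versus `r_j^U * (4 - 4 alpha)` in exact integers. Discounted
  ties (e.g. $r_j^U = 4$, $\alpha_i = 0.5$ against $r_i^G = 2$) are exact,
  never float-sensitive.
* **Null events** occupy a game slot and are logged, but are excluded from
  the cooperation-rate denominator (`coop_rate`); the raw per-slot rate is
  also reported (`coop_rate_raw`). If the out-group branch is drawn when
  the whole population is one group, the event is likewise null rather
  than silently redrawn, keeping the branch probabilities honest.
* **Discounting negative reputations** literally applies
  $r_j^U(1-\alpha_i)$, which moves negative values toward zero (a
  prejudiced agent finds a disreputable out-group member *less* damning).
  We implement the formula as stated and flag the asymmetry here.
* **Synchronous reproduction.** All parent choices are made against a
  frozen snapshot of heuristics, group memberships and fitnesses, so the
  order in which agents are processed is irrelevant.
* **Prejudice-driven defections.** For every out-group event the engine
  also evaluates the donor's decision with $\alpha_i$ forced to 0, all
  else equal. The share of out-group events that are defections which
  would have been donations without prejudice is reported per generation
  (`prej_def_share`, denominator all out-group events; the raw count is
  kept so other denominators can be reconstructed).
* **Base-model reduction.** With one trait and $\alpha \equiv 0$ there is
  a single group and the two reputations receive identical updates, so
  $r^G \equiv r^U$ — the model collapses to the group-free
  social-comparison model it extends. The `evolve_alpha = FALSE` switch
  exists to hold that submodel under mutation of the action rules; the
  test suite asserts the reduction over 1000 generations.
* **Seed tree.** `run_experiment()` derives per-(config, run) child seeds
  by deterministic integer mixing, so adding configurations or replicates
  never changes existing runs, and one master seed reproduces every
  output byte.

## Engines and verification

The generational cycle is implemented twice: a compiled event loop (used
by `simulate_run()`) and a pure-R reference engine
(`simulate_run_r()`). Both consume R's uniform stream in the same order,
so from one seed they produce *bit-identical* event logs, final states
and trajectories — this equivalence is asserted in the test suite across
evolving, fixed and imbalanced configurations. Decision and assessment
rules are additionally checked exhaustively against independent
plain-float oracles over the full $(r_i^G, r_j, \alpha, s, u, d)$ space,
payoffs against the conservation law
$\sum_i tp_i = (b-c) \cdot \#\text{donations}$, and the stochastic
machinery (reproduction gate, mutation rate, copying weights) against
binomial/multinomial frequency bounds at $3\sigma$.

## What the simulations show — and what they do not

The test suite reproduces, at reduced scale, several of the published
qualitative findings: prejudice emerges from a prejudice-free population
under co-evolution (a sustained $\ge 10\%$ high-prejudice minority within
10,000 generations); tail mean prejudice increases with fixed in-group
interaction $S$ at $P = 0.5$; trait diversity reduces prejudice from an
entrenched fully prejudicial start at high out-group mixing; and two of
the three reported cooperation/prejudice pairs (low-$S$ global mixing and
high-$S$ in-group focus) land inside generous bands around their printed
values. At the medium-mixing, global-learning point ($S = 0.5$,
$P = 0.3$) our implementation settles at lower cooperation than reported:
the cooperative regime there is metastable across seeds, and the
corresponding assertion is left failing rather than widened — the run
data are in the test output for inspection. The suite runs at
5,000–12,000 generations with 3–5 replicates rather than the full
50,000–100,000 generations and 10 replicates, which we consider adequate
because the relevant transients settle within the first few thousand
generations; full-scale defaults remain available through the scenario
builders, including the balanced/imbalanced two-trait scenario
(`scenario_imbalance()`), whose per-trait prejudice distributions the
metrics tables expose.

These are simulations of minimal agents: binary action rules, public
integer reputations, no memory, no network structure, no migration between
traits, no assignment errors. Passing tests show the mechanism is
faithfully implemented and its reported consequences are reproducible at
scale — not that any particular human population behaves this way.

## A worked example

```{r example}
library(prejsim)

cfg <- scenario_coevolution(generations = 12000, record_every = 5)
run <- simulate_run(cfg, seed = 1)
first_emergence_generation(run$metrics, threshold = 0.10, window = 500)

tail(run$metrics[, c("gen", "coop_rate", "mean_alpha", "mean_S", "mean_P")])
```
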