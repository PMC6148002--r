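---
title: "Reputation-biased strategy adoption in spatial evolutionary games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation-biased strategy adoption in spatial evolutionary games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgame)
```

## The model and its assumptions

`repgame` simulates two-strategy evolutionary games on structured
populations in which a player's *reputation* coevolves with its strategy
and acts as its teaching ability: the more reputable a player, the more
readily its neighbours imitate it.

Each player $i$ holds a strategy $s_i \in \{C, D\}$ and a reputation score
$R_i \in [-\alpha, \alpha]$, initially $0$ for everyone so that no player
starts with preferential influence. Strategies are initialised i.i.d.
cooperator/defector with probability $1/2$. One synchronous Monte Carlo
step (MCS) consists of:

1. **Payoff accrual.** $P_i = \sum_{j \in N(i)} A(s_i, s_j)$, recomputed
   from scratch every step (no carry-over). Payoffs are totals, not degree
   averages; the degree normalisation enters only in the adoption rule.
2. **Model selection.** Every player draws one neighbour $j$ uniformly at
   random.
3. **Adoption.** All players simultaneously adopt their model's strategy
   with probability
   $$\mathrm{Prob}_i = \frac{1}{1 + \exp[(P_i - P_j)/(k_i K) - R_j]},$$
   every decision reading the *pre-step* snapshot of strategies, payoffs
   and reputations.
4. **Reputation update.** $R_i \leftarrow \mathrm{clip}(R_i \pm \delta,
   -\alpha, \alpha)$, $+\delta$ if $i$ cooperated in stage 1, $-\delta$
   if it defected.

The exponent is read as $(P_i - P_j)/(k_i \cdot K) - R_j$: the normalised
payoff difference $(P_i - P_j)/k_i$ divided by the selection intensity $K$,
shifted by the model's reputation. With $R_j \equiv 0$ (i.e. $\delta = 0$)
this is exactly the classical Fermi rule, which the test suite verifies
step for step against an independent minimal implementation sharing the
same RNG protocol.

Supported games (focal-player payoff $A$):

| game | $T$ | $R$ | $S$ | $P$ | parameter |
|---|---|---|---|---|---|
| weak prisoner's dilemma | $b$ | $1$ | $0$ | $0$ | $1 < b < 2$ |
| snowdrift | $1+r$ | $1$ | $1-r$ | $0$ | $0 < r < 1$ |

Topologies: periodic square lattices with von Neumann ($k = 4$) or Moore
($k = 8$) neighbourhoods, and Erdős–Rényi random graphs with mean degree 4
(quenched: sampled once per run).

## Parameters that matter

* $\delta \ge 0$ — per-round reputation increment (units of reputation).
  $\delta = 0$ is the traditional, reputation-free baseline.
* $\alpha > 0$ — reputation saturation bound. The *fluctuation ratio*
  $\delta/\alpha$ measures the intensity of the teaching-ability mechanism
  and is the natural control parameter; it may exceed 1.
* $K > 0$ — Fermi selection intensity; default $0.1$ everywhere, the
  customary weak-noise value for this class of models.
* `n_steps` — default 61000 MCS, with steady-state observables averaged
  over the final `averaging_window = 1000` steps and across 10–20
  independent replicates at full scale.

## Within-step ordering (a documented choice)

Whether the reputation increment lands before or after the adoption stage
within the same step is genuinely open: reputation summarises *past*
behaviour, which argues for imitators seeing the pre-step value. The
default (`rep_update = "after_adoption"`) therefore updates reputations
from the strategies played in the payoff stage, applied after adoption, so
the $R_j$ an imitator sees excludes the current round. The alternative
ordering (`"before_adoption"`) is implemented behind the same switch; at
desk scale the qualitative results (extinction of cooperators at the
baseline, monotone promotion of cooperation in $\delta/\alpha$) are
insensitive to the choice, and the compiled and pure-R engines implement
both orderings identically.

## Numerical and implementation choices

* **RNG discipline.** One R RNG stream per replicate, seeded from
  `(base seed, replicate index)` via a `sample.int` seed table. Draw order
  is fixed: $n$ uniforms for the initial strategies, then per step $n$
  model-choice uniforms followed by $n$ adoption uniforms. The compiled
  engine consumes R's own RNG, so `engine = "cpp"` and `engine = "r"`
  produce bit-identical trajectories — a standing cross-check in the test
  suite.
* **Overflow safety.** The logistic is evaluated in a branch-stable form
  (`plogis` in R, a guarded two-branch expression in C++), so payoff
  differences far beyond the saturation of `exp` still give probabilities
  in $[0, 1]$.
* **Absorbing states and early stopping.** All-C and all-D are absorbing
  for the strategy composition (every model holds the same strategy), even
  though reputations keep drifting to $\pm\alpha$. The engine may stop
  stepping once the population is homogeneous; observables are extended as
  constants and reputations fast-forwarded analytically, which is exactly
  what the full run would record.
* **Extinction predicate.** A run counts as cooperator-extinct iff its
  steady-state $\rho_c$ is *exactly* 0 — legitimate because extinction is
  absorbing, so the window mean of an extinct run is exactly zero. A grid
  point is extinct when all replicates are; the threshold $b_c$ (or $r_c$)
  is the smallest extinct grid value, and survival through the grid maximum
  returns an open lower bound. Grid sweeps (resolution 0.01 on lattices,
  0.1 on ER graphs, where thresholds are larger and runs costlier) are used
  instead of bisection so replicate noise at each point stays transparent.
* **Empty retention classes.** $\rho_{c \to c}$ with no cooperators left is
  0 by convention (and $\rho_{d \to d}$ mirrors it), matching the
  post-extinction values the retention curves should display.
* **Isolated ER vertices.** A $G(N, p)$ draw at mean degree 4 contains
  $\approx N e^{-4}$ isolated vertices, so drawing until none appear is not
  viable at $N \ge 2000$ ($P \approx e^{-N e^{-4}}$). Since the adoption
  rule divides by $k$ and an isolated player has no model, each isolated
  vertex is instead attached to one uniformly random other vertex. At
  $\bar{k} = 4$ this perturbs the realised mean degree by under 1% and
  leaves the degree distribution approximately Poisson, which the suite
  checks (the goodness-of-fit test runs at $\bar{k} = 8$, where the repair
  is inactive, so it probes the sampler rather than the repair).

## What the synthetic world does and does not establish

All inputs are generated internally: there is no empirical data. The
generator's defaults *are* the stated world — 50/50 random initial
strategies, zero initial reputations, $K = 0.1$, 61000 MCS with last-1000
averaging at full scale. Desk scale (50×50 lattices, 2000–5000 MCS,
window 500, 3–5 replicates, ER graphs with $N = 2000$) reproduces the
equilibrium trends with larger error bars and finite-size shifts; desk
thresholds are therefore slightly conservative (smaller lattices lose
cooperators a little earlier). A green desk-scale test establishes the
mechanism and the direction of its effects, not the exact full-scale curve
values. Nothing here models real human or corporate behaviour; the model
is a stylised statistical-physics dynamics.

## Known limitations

* Updating is synchronous only; random-sequential dynamics can shift
  thresholds in this model class.
* Reputation is visible to neighbours at no cost and enters only through
  the adoption rule — no reputation-based partner choice, migration, or
  payoff consequences.
* ER thresholds reported at desk scale ($N = 2000$) sit below the
  $N = 10^4$ values; the sweep grid's upper end caps what an open bound
  can certify.
* No finite-size scaling or cluster-geometry statistics are computed.
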