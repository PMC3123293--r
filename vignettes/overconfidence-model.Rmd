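---
title: "An evolutionary lattice model of overconfidence in interstate war"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary lattice model of overconfidence in interstate war}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(bellicose)
```

## The model

`bellicose` simulates territorial competition between states on a rectangular
lattice. Each cell is a *province*; a *state* is a contiguous
(4-connected) set of provinces containing exactly one *capital*. States carry
two state variables — a resource stock $R$ and a fixed, heritable *confidence
factor* $\alpha > 0$ — and compete by fighting wars over provinces. A state
with $\alpha > 1$ is overconfident: when deciding whether to attack, it acts
as if it owned $\alpha R$ resources. Crucially, the bias is private and
one-sided: other states always see its *true* strength (people overestimate
their own capabilities, not third parties', and a gullible world would make
bluffing trivially advantageous), and battle outcomes are always computed
from true resources. Confidence distorts *decisions only*.

Every step, all states synchronously execute five sub-procedures:

1. **Extraction** — each state adds one resource unit per province it owns.
2. **Decision** — each state computes its *perceived* probability of
   defeating every neighbour, $\hat p = p(\alpha R_A, R_T)$, from the full
   post-extraction stocks (diversions to other fronts cannot be
   anticipated), and attacks the neighbour with the highest $\hat p$,
   provided $\hat p$ strictly exceeds the attack threshold $w$. Ties among
   maximising targets break uniformly at random.
3. **Allocation** — every unordered pair at war this step is one *front*
   (mutual attacks collapse to a single front). Each belligerent splits its
   entire stock across its fronts in proportion to each opponent's size, so
   a state attacked by several enemies at once must divide its defence —
   the emergent "offensive alliance" that helps aggressive states gang up
   on weak neighbours.
4. **Interaction** — each front resolves by an independent Bernoulli draw
   with probability given by the conflict success function of the two
   sides' true allocations.
5. **Structural change** — each winner annexes one uniformly chosen loser
   province adjacent to its territory. A state whose capital is captured
   dissolves; a state whose territory is severed sheds the components cut
   off from its capital. Every dissolved province becomes an independent
   single-province state that *inherits the parent's* $\alpha$ (strategies
   replicate; nothing mutates) and starts with the per-province endowment.

Selection therefore acts on $\alpha$ purely through differential survival
and expansion: the model asks which confidence strategies persist.

## The conflict success function

The win probability for an attacker committing $r_A$ against a defender
committing $r_T$ depends on the attacker's share $r = r_A/(r_A+r_T)$, a
decisiveness parameter $k$ and the equal-odds share $r_0$ (0.5 throughout).
Two logistic forms are provided:

* `log_odds` (default): $p = \operatorname{logit}^{-1}\!\big(k[\operatorname{logit}(r) -
  \operatorname{logit}(r_0)]\big)$. At $r_0 = 0.5$ this is exactly the ratio
  contest $r_A^k/(r_A^k + r_T^k)$ — the classic contest success function of
  conflict economics — with win-probability asymptotes at 0 and 1 as the
  resource ratio diverges.
* `share_linear`: $p = \operatorname{logit}^{-1}(k(r - r_0))$, logistic in
  the share itself. Its range is bounded away from 0 and 1 for finite $k$.

A logistic "in the share" and asymptotes at 0 and 1 cannot both hold; the
two forms bracket the plausible readings. We default to `log_odds` because
the 0/1 asymptotes are an explicit property of the perceived-probability
curve (an infinitely overconfident state should be certain of victory), and
it keeps the convenient ratio-contest algebra. The form is a configuration
switch, never mixed within one experiment, and the analytic anchor —
$p = 1/2$ exactly for an unbiased state in an even contest — holds under
both:

```{r csf}
perceived_success_probability(alpha = 1, r_attacker = 10, r_target = 10)
perceived_success_probability(alpha = 4, r_attacker = 10, r_target = 10)
plot_csf_curve(csf_confidence_curve())
```

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `width`, `height` | grid dimensions | 30 x 30 | provinces |
| `torus` | wraparound topology | `FALSE` | — |
| `n_initial_states` | initial polarity N | 50 | states |
| `k` | decisiveness of conflict | 5 | — |
| `r0` | equal-odds share | 0.5 | share |
| `w` | attack threshold | 0.5 | probability |
| `q` | war-cost share | 0 | share of opponent's allocation |
| `alpha_mu`, `alpha_sigma` | lognormal confidence parameters | 0, 1 | log scale |
| `initial_resources_per_province` | birth endowment | 10 | resources |
| `peace_steps_to_stop` | peaceful steps before termination | 50 | steps |
| `max_steps` | hard cap | 10000 | steps |

With `alpha_mu = 0` the population *median* confidence is exactly
$e^{0}=1$: the initial population is unbiased as a whole, with a long upper
tail permitting a few wildly overconfident states and a hard lower bound at
zero. With `w = 0.5`, an unbiased state attacks only when the odds genuinely
favour it — the strict inequality makes a world of equal unbiased states
permanently peaceful, which pins the baseline.

## Design choices the model statement leaves open

* **Initial partition.** Only capitals are specified: one per state, placed
  uniformly at random on distinct cells. We grow territories by synchronous
  multi-source BFS from the capitals, each frontier cell joining the owner
  of a uniformly chosen already-owned neighbouring cell. This guarantees
  contiguous territories by construction (nearest-capital Voronoi on a
  lattice does not), gives approximately balanced sizes, and the robustness
  sweep shows results are insensitive to the partition's details.
* **Adjacency.** Von Neumann 4-connectivity everywhere (neighbourhood,
  contiguity, transfer eligibility); corner contact is not adjacency. This
  is the conservative lattice convention and makes "adjacent province"
  transfers unambiguous.
* **Allocation weights.** "In proportion to the size of each opponent" is
  read as the opponent's total resource stock, resources being the currency
  of every other combat computation; `allocation_weights = "provinces"`
  switches to province counts for sensitivity runs.
* **Fragment dissolution.** Cut-off provinces become *per-province*
  singleton states (not one rump state), matching the capital-capture rule;
  the dissolved parent's residual stock is destroyed, not transferred — the
  conqueror gains territory, not treasure.
* **Simultaneous claims.** Structural changes apply in uniformly random
  order with invalidation (a resolution is skipped if its loser has
  dissolved or adjacency was lost), avoiding any invented priority rule.
* **Coordinates.** 1-based `(row, col)`, the R convention.

## Numerical and procedural details

* All randomness flows through R's RNG, including inside the compiled
  engine, so `set.seed()` makes full trajectories bit-reproducible; batch
  run `i` uses the order-independent derived seed `child_seed(base, i)`.
* The threshold comparison is strict (`p-hat > w`); probability ties in the
  decision phase are exact floating-point ties (they arise from exactly
  equal stocks) and break uniformly at random.
* War costs floor at zero — a state never holds negative resources — and a
  living state is always solvent after extraction (at least one unit per
  province), so the CSF never sees a non-positive input.
* Wars last one step: fronts are rebuilt from fresh decisions every step,
  and every resolved battle yields a winner.
* Time series serialise with 17 significant digits, so CSV round-trips are
  exact.

## The experiment harness

`run_batch()` aggregates replicate runs (terminated runs carry their final
median forward so the aggregate curve is defined at every step);
`parameter_sweep()` crosses grid size, topology, polarity, decisiveness and
confidence spread (`s1_parameter_grid()` gives the full 162-cell factorial
or an 8-cell two-level fractional-factorial corner design);
`war_cost_experiment()` and `threshold_experiment()` sweep `q` and `w`. The
cell statistic is the median across runs of each run's final median
confidence over surviving states, unweighted by territory (with a single
survivor — the usual outcome — weighting is moot).

The package's standing checks run at these scales: 200 default-parameter
runs for the headline batch, 10-25 runs in each of the 8 corner cells of
the robustness design (25 where the cell *minimum* is the quantity of
interest, since the minimum of noisy cell medians is biased low at small
replicate counts), and 50 runs per arm of the war-cost and threshold
sweeps. A full 162-cell, 50-run factorial is supported
(`parameter_sweep(s1_parameter_grid(), 50)`) and is an overnight-scale job.

```{r small-run}
run <- run_simulation(war_config(width = 12, height = 12,
                                 n_initial_states = 10, seed = 7))
glance(run)
autoplot(run)
```

## What the simulation does and does not show

The generator *is* the study system: states are literal resource-maximising
automata on a homogeneous lattice. Passing checks show that, within this
system, overconfident strategies predominate through differential survival
— via more lottery tickets (more attempted conquests), emergent gang-ups on
weak neighbours, and threshold-induced shirking by unbiased states. They do
not show that real states are overconfident, nor calibrate $\alpha$ against
any empirical conflict data. Known departures from reality are deliberate:
no defensive alliances or coordination of any kind, no learning or strategy
copying, no negotiated settlement or multi-step sieges, zero-sum stakes
only (one province changes hands per battle), homogeneous province value,
and no resource transfer on conquest. Outcomes are distributions over runs;
any single trajectory is dominated by the survival lottery.

## Limitations

* Endgames between two well-matched overconfident giants can random-walk
  for a long time; the `max_steps` cap (10,000) records such stalemates
  rather than waiting them out.
* The per-province dissolution rule creates bursts of tiny newborn states
  that are usually absorbed quickly; their brief presence pulls the living
  median toward the dissolved parent's confidence.
* Run length and survivor identity are sensitive to the RNG stream; only
  aggregate statistics (batch medians, sweep cells) are stable quantities.
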