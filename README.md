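# bellicose

An evolutionary agent-based model of interstate war on a lattice, asking a
simple question: if states differ only in how accurately they judge their own
strength, which *confidence strategies* survive?

Each state on the grid carries a heritable confidence factor α that
multiplies its own perceived resources when it decides whether to attack a
neighbour (α > 1 overconfident, α = 1 unbiased, α < 1 underconfident). Other
states are never fooled, and battles are decided by *true* resources — the
bias distorts decisions only. States extract resources from their provinces,
attack the neighbour they think they are most likely to beat (if that
perceived probability exceeds a threshold *w*), split their stock across
simultaneous fronts, and fight battles whose outcomes follow a logistic
conflict success function

  p(r_A, r_T) = r_A^k / (r_A^k + r_T^k)   (the default, at equal-odds share r0 = 0.5)

with decisiveness *k*. Winners annex a province; states whose capital is
captured or cut off shatter into single-province successors that inherit the
parent's α. Selection on α acts purely through survival and expansion. The
headline result the package reproduces: despite fighting more (and more
hopeless) wars, **overconfident strategies come to predominate**, through
more attempted conquests ("more lottery tickets"), emergent gang-ups on weak
neighbours, and — when thresholds are high — unbiased states shirking wars
they would actually win. An optional war-cost share *q* (each battle costs a
belligerent q times the opponent's committed resources) erodes and
eventually reverses the advantage.

The simulation engine is compiled (Rcpp); all user-facing functions take and
return tibbles, results have `tidy()`/`glance()`/`autoplot()` methods, and
every run is bit-reproducible from its seed.

## Worked example

```r
library(bellicose)

# how confidence distorts the perceived chance of beating an equal opponent
perceived_success_probability(alpha = c(0.5, 1, 2, 4), 10, 10)
#> [1] 0.03030303 0.50000000 0.96969697 0.99902439

# one full run at the canonical settings: 30x30 grid, 50 states, k = 5, w = 0.5
run <- run_simulation(war_config(seed = 2026))
glance(run)
#> # A tibble: 1 × 6
#>   steps termination    final_n_states final_median_alpha total_battles  seed
#>   <int> <chr>                   <int>              <dbl>         <int> <int>
#> 1  1045 one_state_left              1               1.78          4696  2026
```

After 1045 steps and 4696 battles a single state holds the whole grid, and
its confidence factor is 1.78: the surviving strategy overestimates its own
resources by 78%. Single runs are lottery draws; the stable quantity is the
batch median:

```r
b <- run_batch(war_config(width = 15, height = 15, n_initial_states = 12),
               n_runs = 20, base_seed = 7)
glance(b)
#> # A tibble: 1 × 4
#>   n_runs median_final_alpha share_one_state mean_steps
#>    <int>              <dbl>           <dbl>      <dbl>
#> 1     20               1.73               1       255.

autoplot(b)           # aggregated confidence trajectory
autoplot(run$final_world)  # red = overconfident, green = unbiased/under
```

The median final confidence across runs is 1.73 — well above the unbiased
level 1 even on a small grid, and every run ended with one state standing.
Experiment harnesses sweep the model's main dials:

```r
parameter_sweep(s1_parameter_grid(reduced = TRUE), n_runs = 10)  # robustness corners
war_cost_experiment(q_values = c(0, 0.1, 0.2, 0.4), n_runs = 50) # costs erode it
threshold_experiment(w_values = c(0.3, 0.5, 0.7), n_runs = 50)   # thresholds boost it
```

A thin CLI over the same functions lives at `inst/cli/bellicose-cli.R`
(`simulate`, `batch`, `sweep`, `warcosts`, `thresholds`, `fig2-curve`). The
model, its assumptions and every open design choice are documented in
`vignettes/overconfidence-model.Rmd`.

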