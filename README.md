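# ceatree

Decision-tree cost-effectiveness analysis of smoking-cessation strategies
for health-technology assessment.

## What it does, and for whom

Health-economics analysts comparing cessation programmes in primary care
need the same machinery every time: a cohort model, incremental
cost-effectiveness ratios, dominance pruning, and sensitivity analysis.
`ceatree` packages that workflow for a stratified sequential decision
tree. A hypothetical cohort of smokers is split into nicotine-dependence
strata by Fagerstrom index (FI) score; each stratum receives an ordered
sequence of treatment stages — counselling (brief behavioural intervention
BI, or an enhanced counselling package EC) followed by pharmacotherapy
(NRT at a dose rising with dependence, then bupropion plain or
sustained-release for the high-dependence stratum). A stage is attempted
only by smokers who did not quit earlier, so with stage quit rates `q_j`:

- reach probability: `r_j = prod_{i<j} (1 - q_i)`
- stratum quit rate: `Q_s = 1 - prod_j (1 - q_j)`
- expected quitters: `N * sum_s w_s * Q_s` (weights `w_s` are normalized
  prevalences)
- cost: counselling charged to everyone entering the stratum,
  pharmacotherapy only to those reaching its stage (`r_j`)

Strategies are compared by `ICER = ΔC / ΔE` (rupees per additional person
quitting), classified against a willingness-to-pay threshold, and pruned
for simple and extended dominance. Uncertainty is handled by tornado-style
one-way analysis over the published parameter bounds and by Monte-Carlo
probabilistic sensitivity analysis with moment-matched Beta (probabilities)
and Gamma (costs) distributions, summarised as cost-effectiveness planes
and acceptability curves (CEAC).

## Worked example

```r
library(ceatree)

cfg <- base_case_config()          # packaged 100,000-smoker base case
totals <- strategy_totals(evaluate_strategies(cfg))
totals
#> # A tibble: 4 × 4
#>   strategy quitters   cost_inr cost_usd
#>   <chr>       <dbl>      <dbl>    <dbl>
#> 1 CS         82465. 189557714. 2258522.
#> 2 PS1        97019.  70582811.  840972.
#> 3 PS2        83231. 192279412. 2290950.
#> 4 PS3        97149.  71045500.  846485.

incremental_table(totals, comparator = "CS", wtp = cfg$wtp_threshold)
#> # A tibble: 3 × 6
#>   intervention comparator  delta_cost delta_effect   icer classification
#> 1 PS1          CS         -118974903.       14554. -8175. cost-saving
#> 2 PS2          CS            2721698.         766.  3553. cost-effective
#> 3 PS3          CS         -118512214.       14684. -8071. cost-saving
```

Adding enhanced counselling (PS1, PS3) produces more quitters at lower
cost than the current strategy — cost-saving — while swapping plain
bupropion for the sustained-release formulation alone (PS2) buys 766 extra
quitters at about ₹3,553 each, well under the threshold of ₹235,730 per
quitter, hence cost-effective. The probabilistic analysis puts PS1 in the
more-effective/less-costly quadrant in 100% of 1000 iterations and PS2 in
the more-effective/more-costly quadrant in ~95%:

```r
psa <- run_psa(cfg, comparator = "CS", n = 1000, seed = 20250101)
quadrant_proportions(psa, "PS2")
#> more_effective_less_costly more_effective_more_costly
#>                      0.000                      0.945
#> less_effective_less_costly less_effective_more_costly
#>                      0.000                      0.055
```

`owsa()` produces tornado tables, `ceac()` acceptability curves,
`dominance_prune()` the efficiency frontier, and `write_results()` a CSV
bundle with a run manifest. Configurations are human-editable YAML
(`load_config()` / `write_config()`; see `inst/extdata/base_case.yaml`
for the schema), and `generate_parameter_set()` /
`generate_dominance_scenario()` create synthetic scenarios with known
structure for testing. A thin command-line front end is installed at
`system.file("cli", "ceatree.R", package = "ceatree")` with subcommands
`run-base`, `owsa`, `psa`, `ceac`.

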