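---
title: "A stratified decision-tree model for smoking-cessation cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stratified decision-tree model for smoking-cessation cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ceatree)
```

## The model

`ceatree` implements a single-period decision-tree model for comparing
smoking-cessation strategies delivered at primary health care facilities.
A hypothetical cohort of $N$ smokers (default 100,000) is divided into four
nicotine-dependence strata by Fagerstrom index (FI) score — 0–2, 3–5, 6–7
and ≥8 — with stratum weights $w_s$ obtained by normalizing the raw
prevalences $p_s$:

$$ w_s = \frac{p_s}{\sum_{s'} p_{s'}}. $$

The published prevalence set sums to 0.98, not 1; normalizing allocates the
whole cohort and is required for internal consistency (the loader warns when
it happens, and raw values stay in the configuration untouched).

Within a stratum, a strategy prescribes an ordered sequence of treatment
stages: a counselling stage (brief behavioural intervention, BI, or the
enhanced counselling package, EC) followed by pharmacotherapy stages
(nicotine replacement therapy at a dose rising with the FI score, then — in
the high-dependence stratum only — bupropion, plain or sustained-release
depending on the strategy). Each stage $j$ has a quit probability $q_j$ and
a per-person unit cost $c_j$, and is attempted only by smokers who did not
quit at any earlier stage, so the probability of reaching stage $j$ is

$$ r_j = \prod_{i<j} (1 - q_i), \qquad r_1 = 1, $$

and the stratum's combined quit rate is $Q_s = 1 - \prod_j (1 - q_j)$.
Expected quitters are $N \sum_s w_s Q_s$. Costs accrue sequentially:
counselling is delivered to everyone entering the stratum (charged at reach
1), while pharmacotherapy is charged only to those who reach its stage
($r_j$). This sequential accrual is what makes the incremental cost between
the two bupropion formulations small — only the minority who fail both
counselling and NRT ever receive the drug.

Interventions that act together are combined under independence:
$1 - \prod_i (1 - q_i)$. In particular EC is modelled as the motivational
package layered **on** brief advice, so its counselling effect is the
combined EC+BI rate (0.918 at base case), not the EC singleton rate. The
published combined-effect rows are retained in the configuration purely as
a validation set for this rule.

Two willingness-to-pay constants circulate for the same year's GDP per
capita (₹235,730 and ₹216,590); both are carried in the configuration, the
former as the default threshold. Every classification in the base case is
identical under either.

## Incremental analysis

For strategies $A$ (intervention) and $B$ (comparator),
$\mathrm{ICER} = \Delta C / \Delta E$ with $\Delta E$ in persons quitting.
Classification against the threshold $\lambda$:

* **cost-saving** — $\Delta C < 0,\ \Delta E > 0$;
* **dominated** — $\Delta C > 0,\ \Delta E < 0$;
* **cost-effective** — $\Delta E > 0$ and $0 \le \mathrm{ICER} \le \lambda$;
* **not-cost-effective** — otherwise;
* **equivalent** — both differences exactly zero.

A negative ICER never drives a decision: its sign cannot distinguish
"cheaper and better" from "dearer and worse". The awkward corner
$\Delta C < 0, \Delta E < 0$ (cheaper but less effective, not strictly
dominated) is labelled not-cost-effective — the conservative choice, since
recommending it requires a value judgement about forgoing effect that a
single threshold comparison does not settle.

`dominance_prune()` builds the efficiency frontier: strategies beaten on
both axes are strictly dominated; then strategies whose incremental ICER
over their cheaper neighbour exceeds the next sequential ICER are removed
(extended dominance — a mixture of their neighbours does better) until the
sequential ICERs increase strictly. Ties are deterministic: equal
effectiveness keeps the cheaper strategy, exact duplicates keep the first
by input order. The implementation is tested against an independent oracle
that sweeps willingness-to-pay values and collects the maximizers of net
monetary benefit $\lambda \Delta E - \Delta C$.

```{r}
cfg <- base_case_config()
totals <- strategy_totals(evaluate_strategies(cfg))
totals
incremental_table(totals, comparator = "CS", wtp = cfg$wtp_threshold)
dominance_prune(totals)
```

## Sensitivity analysis

**One-way (tornado).** Each parameter moves to its published lower and
upper bound with everything else at base; the ICER of the chosen
comparison is recorded at both extremes and rows are ranked by swing. The
bounds are used verbatim (they are the printed data, uniformly ±25% of
base); a 95%-interval reading of those bounds drives the probabilistic
analysis below. A bound that makes $\Delta E = 0$ leaves that side's ICER
undefined (`NA`, with a warning) and the swing falls back to the defined
side.

**Probabilistic (PSA).** Every uncertain parameter gets a distribution by
moment matching, the standard convention when only a central value and an
interval are published: $\mathrm{sd} = (\text{upper}-\text{lower})/(2
\times 1.96)$, mean equal to base. Beta (via
$\alpha = m(m(1-m)/v - 1)$, $\beta = (1-m)(m(1-m)/v - 1)$) for
probabilities, Gamma ($k = m^2/v$, $\theta = v/m$) for non-negative costs,
Normal for the (economically inert) mean age. Moment matching preserves
mean and spread, not quantiles, so the fitted 2.5/97.5 percentiles only
approximate the printed bounds. Parameters are sampled independently — no
correlation structure is published — and singleton quit rates are sampled
and then recombined, so both arms of a comparison stay coherent within an
iteration; prevalences are renormalized per iteration. 1000 iterations run
in well under a second.

Quadrant proportions on the cost-effectiveness plane assign the
measure-zero boundary draws to the favourable side. The acceptability
curve reports, per threshold $\lambda$, the fraction of iterations with
$\lambda \Delta E - \Delta C > 0$; ties count as not cost-effective.

```{r}
psa <- run_psa(cfg, comparator = "CS", n = 1000, seed = 20250101)
quadrant_proportions(psa, "PS1")
head(owsa(cfg, "PS1", "CS"))
```

## Synthetic scenarios

`generate_parameter_set()` draws internally consistent random
configurations with the base case's structure: Beta-distributed quit
probabilities in a configurable range with symmetric ±25% bounds (clipped
to [0, 1]), Gamma-distributed positive costs, stratum prevalences from a
flat simplex, and a dose-escalation stage pattern (counselling everywhere,
more pharmacotherapy in higher strata). `generate_dominance_scenario()`
hand-constructs strategy totals with a *known* frontier: a planted
strictly dominated point (dearer and less effective than an existing
strategy), a planted extendedly dominated point (above the chord joining
two adjacent frontier strategies but below the next strategy's cost), or a
clean frontier with strictly increasing ICERs. These generators emulate
the statistical *structure* of the published parameter table, not real
heterogeneity: quit rates in practice correlate across interventions and
costs are not independent across components, so passing tests demonstrate
algorithmic correctness, not forecasts for any real programme.

## Numerical choices and limitations

* All person counts and rupee amounts are kept at full double precision;
  rounding (nearest integer; Indian digit grouping) happens only in the
  reporting layer. Source tables round inconsistently, which the tests
  accommodate explicitly rather than normalizing away.
* The path computation is closed-form; it is verified in the test suite
  against exhaustive enumeration of all $2^k$ quit/no-quit outcomes for
  pathways up to six stages (equality within $10^{-9}$ relative error).
* A quit probability of exactly 1 truncates all downstream reach to 0; a
  zero-weight stratum contributes nothing; a stage with zero quit rate and
  zero cost is a no-op. All are covered by tests.
* The model is a single-period tree: no relapse, no time horizon, no
  discounting, and the outcome is persons quitting, not QALYs. Absolute
  per-strategy totals are therefore sensitive to the stratum→treatment
  mapping, which is configuration, not code; the default mapping is the
  one consistent with the published incremental results. Incremental
  comparisons between strategies sharing a mapping are far more robust
  than the absolute totals.
* Problem sizes used throughout (100,000-person cohort, 1000 PSA
  iterations, 200,000-draw distribution checks, 100-seed fuzzing of the
  generators) keep the full suite and analysis scripts fast while leaving
  Monte-Carlo error well below the tolerances tested.
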