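---
title: "Methods: median-quadrant association, the positive-attributes index, and dietary EPA+DHA allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: median-quadrant association, the positive-attributes index, and dietary EPA+DHA allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seaomega)
```

## The scientific setting

National food-based dietary guidelines (FBDGs) often tell people to "eat
seafood", but seafood species differ enormously in long-chain omega-3
content (EPA+DHA, here "LCn-3"): a population can follow the advice by
eating shrimp and still consume very little LCn-3. `seaomega` implements a
country-level analysis of this problem in three statistical stages, plus a
synthetic-data generator that makes every stage testable without any
external download.

Country-level covariates compiled from heterogeneous published sources
(food-balance sheets, price rankings, GDP tables, FBDG surveys) carry
substantial measurement error, and dietary intake estimates are prone to
overestimation. The median-quadrant method is deliberately rank-based so
that only the ordering of countries matters, not the reported magnitudes.

## Median-quadrant (quadrate) association

For a pair of country-level variables $(x, y)$, each country is classified
as below or above the median of each variable, yielding a $2\times2$
quadrant table with counts $(n_{bb}, n_{ba}, n_{ab}, n_{aa})$ (first index:
$x$ side, second: $y$ side). Independence is tested with the uncorrected
Pearson chi-square in its closed form for a $2\times2$ table,

$$\chi^2 \;=\; \frac{n\,(n_{bb}n_{aa} - n_{ba}n_{ab})^2}
{(n_{bb}{+}n_{ba})(n_{ab}{+}n_{aa})(n_{bb}{+}n_{ab})(n_{ba}{+}n_{aa})},
\qquad \mathrm{df} = 1,$$

and the direction of association is read off quadrant concordance: positive
when $n_{bb} + n_{aa} > n_{ba} + n_{ab}$, negative when the discordant
quadrants dominate, none on a tie.

Numerical and procedural choices:

* **No Yates continuity correction.** The uncorrected statistic is the one
  that reproduces published quadrant chi-squares for this method exactly
  (e.g. 11.0029 on the serving-size table, see `fbdg_quadrant_counts()`);
  the corrected statistic would not.
* **Tie policy.** Whether a country exactly at the median counts as below
  or above is not fixed by the method's description; the package defaults
  to `strict_above` (above iff strictly greater than the median, so ties go
  below) and offers `exclude_ties`, which drops median-valued countries and
  reports which were dropped. With continuous data and an even sample size
  the split is exact (n/2 each side) under either policy.
* **Pairwise-complete medians.** Each comparison's medians are computed on
  that pair's complete cases, not on a single global complete-case subset;
  compiled country tables have different coverage per column, so the global
  subset would discard information and shift medians.
* **FBDG dichotomization.** `fbdg_status` entering as an x-variable is
  split on the presence of *any* seafood recommendation; both "no FBDG" and
  "FBDG without a seafood recommendation" count as Below by default
  (configurable via `fbdg_above`), since neither gives the consumer
  seafood-specific advice.
* **Degenerate tables.** A zero row or column margin makes the statistic
  undefined; it is reported as $\chi^2 = 0$, $p = 1$ with a warning rather
  than `NaN`, so batch runs never crash on a constant column.
* **Price is analyzed as recorded.** Its negative association is reported
  by the direction rule; the inversion of price happens only in the index
  stage below.

Multiplicity is handled Bonferroni-style: for a family of $m$ comparisons
at family-wise level $\alpha$, each comparison is judged at
$\alpha/m$ (`run_family()`; for the standard six-comparison family
$0.05/6 = 0.00833$, conventionally rounded to $0.008$ in reports — the
comparison itself always uses the exact value).

Two exact invariances are worth knowing (both are property-tested):
applying any strictly increasing transform to either variable changes
nothing (the method sees only ranks), and negating one variable mirrors the
table, preserves $\chi^2$ and flips the direction. The second is exact for
even samples of distinct values; with an odd sample size the observation
*at* the median sits on the Below side both before and after negation under
`strict_above`, so the mirror is off by one country.

## The four-point positive-attributes index

Four binary attributes mark conditions associated with higher dietary
LCn-3: GDP above its median, ranked fish price **below** its median (price
associates negatively, so it is inverted), total fish supply above its
median, and percent of fish supply of marine origin above its median. The
index is their count, $0$–$4$.

Only countries with all four variables present are scored, and by default
each attribute's median is taken over that complete-case set (the
`medians = "per_variable"` alternative uses each variable's full non-missing
set). Strict inequalities are used for all four components, consistent with
the quadrant module's default tie policy, so a country exactly at a median
earns no point. Under a null synthetic table each component is true for
just under half of the countries, so the mean score sits near 2.

Score distributions are compared across the four FBDG categories with a
fixed-effects one-way ANOVA (`anova_by_group()`, via
`stats::oneway.test(var.equal = TRUE)`), treating the integer score as a
continuous response — the classical F-test, not an ordinal model. A design
whose between-group sum of squares is zero returns $F = 0$, $p = 1$;
empty groups are dropped with a warning; a single-group design is rejected.

## Dietary EPA+DHA allocation

Given a national consumption profile — species $i$ eaten at $g_i$ grams per
capita per week with EPA+DHA density $d_i$ mg per 100 g edible portion —
each species contributes

$$\text{LCn-3}_i = \frac{g_i}{7}\cdot\frac{d_i}{100} \quad \text{mg/day}.$$

Listed species typically cover only a fraction $c$ of total seafood
consumption (0.748 for a top-ten list in published US data), so the implied
total is $\sum_i g_i / c$ and the unlisted residual, weighing
$(1-c)\sum_i g_i/c$ grams, is imputed at the consumption-weighted mean
density of the listed species, $\bar d = \sum_i g_i d_i / \sum_i g_i$.
Shares of consumption and of LCn-3 are computed over species plus residual
and each sum to 1; total LCn-3 equals the sum of all contributions
(conservation is property-tested to $10^{-9}$).

The *recommended-intake scenario* rescales the profile so total consumption
equals a guideline amount (8 oz/week). By default the whole mix — listed
species and residual alike — is scaled by `target/total`, which multiplies
total LCn-3 by exactly that factor and leaves every share unchanged.
Extending only the listed species is a defensible alternative reading of
"the top-ten pattern was extended", so it is available as
`scale_listed_only = TRUE` (the residual's grams held fixed); the
proportional default was chosen because it preserves the share-invariance
that makes the two scenarios directly comparable.

Unit conversions use 1 oz = 28.3495 g, with a `rounded_8oz` mode using the
guideline convention 8 oz = 226.7 g (so 226.7 g/week is 32.3857… g/day,
presented as 32.4). Values are rounded only at presentation. Densities are
per 100 g edible portion; no cooking-yield adjustment is applied, and no
nutrient beyond EPA+DHA is modelled.

## What the synthetic generator emulates — and what it does not

`generate_countries()` draws a one-factor Gaussian copula: a latent
standard normal drives LCn-3 and each covariate's latent correlates with it
at $2\sin(\pi\rho_S/6)$, the inverse of the Gaussian-copula Spearman
formula, so the configured `effect` *is* the population Spearman
correlation of the generated pair. Marginals are then free choices, since
the quadrant method and the index see only ranks:

| column | marginal | default | why |
|---|---|---|---|
| `lcn3_mg_day` | normal truncated at 0 | mean 150, sd 120 mg/day | right spread of country means around the global average with a long upper tail |
| `gdp_percap` | log-normal | meanlog $\log 12000$, sdlog 1.3 | standard income distribution shape |
| `price_rank` | rank permutation | $1..n$ | the variable is ordinal by construction |
| `total_fish` | gamma | shape 2, mean 20 kg/yr | skewed per-capita supply |
| `pct_marine` | $100\times$Beta(2, 1.2) | mean ≈ 62% | most countries' fish supply is majority marine |
| `recommended_g_day` | normal truncated at 0 | mean 32.9, sd 17.4 g/day | published summary of national serving-size recommendations |

FBDG categories are drawn independently with frequencies
$(41, 33, 65, 27)/166$ — 65 countries with a serving size and 92 with any
seafood recommendation match the margins of the published comparison table;
the split of the remaining 74 between "no FBDG" and "no recommendation" is
not published and was fixed once at 41/33. The serving size exists only for
`rec_with_serving` countries. Missingness, when enabled, is injected
independently per cell (MCAR) and never in `country_id`; the default is 0
so that calibration experiments run on clean margins.

`generate_consumption()` draws a Zipf-like share profile
($\propto i^{-\text{dominance}}$) normalized so the listed species cover
`top_coverage` of an implied weekly total (defaults 0.748 of
138.9 g/week), with densities uniform over a configurable range except that
the dominant species is forced into the lower third and at least one other
species into the upper third — the qualitative shrimp/salmon pattern. In
every such profile the dominant species' LCn-3 share is strictly below its
consumption share, which is the phenomenon the allocation stage is built to
expose.

What the generator does **not** emulate: real covariate marginals or their
joint tail behaviour (the copula is a stand-in, not an inference about the
compiled data), FBDG status correlated with wealth or geography, spatial
clustering of countries, non-MCAR missingness, or real species identities
and densities. Passing tests on synthetic data therefore validate the
*machinery* — calibration of the test under a true null, recovery of
planted rank effects, conservation laws of the allocation — not any claim
about real-world country tables, which enter only as published quadrant
counts.

## Calibration facts and problem sizes

Because a continuous variable with an even sample size splits exactly
$n/2$–$n/2$ at its median, the quadrant count under independence is exactly
hypergeometric; at $n = 166$ the uncorrected chi-square's true type-I rate
at nominal $\alpha = 0.05$ is 6.2% — the test is slightly liberal at this
sample size, which the Bonferroni protection more than absorbs (the exact
rate at $0.05/6$ is 1.3%).

The test suite and the reproduction script use these problem sizes, chosen
to make Monte-Carlo error small relative to the quantities checked:
2000 null replicates at $n = 166$ for type-I calibration (binomial sd
≈ 0.5 percentage points), 500 replicates for power against a planted
Spearman effect of 0.6, 1000 random tables for the chi-square oracle and
invariance properties, 2000 label permutations for the ANOVA-uniformity
check, and 100-200 random profiles for the allocation laws.

## Known limitations

* The method dichotomizes at medians, discarding within-half ordering; it
  is a deliberately coarse, robust screen, not an effect-size estimate.
* Bonferroni protection controls the family-wise error rate but is
  conservative when comparisons are correlated — and these six share the
  LCn-3 variable.
* The ANOVA treats an integer 0–4 score as continuous; with strongly
  unbalanced groups or extreme score distributions an ordinal model would
  be more faithful, but none is provided.
* The allocation model is a static accounting identity: no substitution
  behaviour, population subgroups, or nutrient interactions.
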