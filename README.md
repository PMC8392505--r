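# seaomega

Country-level analysis of the link between food-based dietary guidelines
(FBDGs) for seafood and dietary long-chain omega-3 intake (EPA+DHA,
"LCn-3"). The package is for nutrition and food-policy researchers who work
with compiled country tables — per-capita dietary LCn-3, FBDG status,
recommended seafood serving sizes, GDP, ranked fish prices, fish supply —
and with national species-consumption profiles.

Three analysis stages, plus a seeded synthetic-data generator:

1. **Median-quadrant association** (`run_family()`): each country is
   classified below/above the median of two variables; the 2×2 quadrant
   counts are tested with the uncorrected Pearson chi-square,

   χ² = n (n_bb·n_aa − n_ba·n_ab)² / [(n_bb+n_ba)(n_ab+n_aa)(n_bb+n_ab)(n_ba+n_aa)],  df = 1,

   direction is read from quadrant concordance (positive when below–below
   plus above–above dominate), and a family of m comparisons is judged at
   the Bonferroni-protected threshold α/m (0.05/6 ≈ 0.008 for the standard
   six comparisons).
2. **Positive-attributes index** (`attribute_index()`, `anova_by_group()`):
   a 0–4 country score counting GDP above median, fish price below median
   (the inverted attribute), total fish supply above median, and percent
   marine fish above median, compared across FBDG categories by one-way
   ANOVA.
3. **Dietary EPA+DHA allocation** (`allocate_diet()`,
   `scale_to_recommendation()`): per-species contributions
   (g/week ÷ 7 × mg-per-100g ÷ 100), weighted-mean imputation of the
   unlisted residual share of consumption, and proportional extension of
   the profile to a recommended total such as 8 oz (226.7 g) per week.

Synthetic country tables come from a one-factor Gaussian copula whose
`effect` parameter *is* the population Spearman correlation between a
covariate and LCn-3 (`generate_countries()`); synthetic consumption
profiles have a Zipf-skewed, omega-3-poor dominant species
(`generate_consumption()`). See the methods vignette
(`vignettes/median-quadrant-omega3.Rmd`) for the model, parameter
rationales and limitations.

## Worked example

```r
library(seaomega)

## published quadrant counts: serving-size recommendation vs dietary LCn-3
tab <- fbdg_quadrant_counts()$recommended_g_day
print(tab)
#> Quadrant table: recommended_g_day (x) vs lcn3_mg_day (y), n = 65
#>         y Below y Above
#> x Above       5      26
#> x Below      19      15
res <- pearson_chi2(tab)
c(res$chi2, res$p_value)        # 11.0029, 0.00091
association_direction(tab)      # "positive"
```

Countries recommending a specific seafood serving sit mostly in the
concordant quadrants: 26 of the 31 above-median recommenders are also
above-median LCn-3 consumers, and the chi-square of 11.00 (p ≈ 0.0009) is
significant even at the protected threshold 0.05/6.

```r
## a US-style consumption profile: 10 species covering 74.8% of 138.9 g/week
sp <- generate_consumption(consumption_scenario(seed = 1))
target <- convert_intake(8, "oz/week", "g/week", constants = "rounded_8oz")  # 226.7
d <- allocate_diet(sp, coverage = 0.748, target_g_week = target)
d$total_lcn3_mg_day           # 159.1  mg/day at observed consumption
d$scaled$total_lcn3_mg_day    # 259.7  mg/day at the 8 oz/week guideline
100 * d$per_species[1, c("share_consumption", "share_lcn3")]
#>   25.5% of consumption, 5.0% of EPA+DHA
```

The dominant species supplies a quarter of the seafood eaten but only 5% of
the EPA+DHA — the structural reason "eat more seafood" advice can fail to
raise omega-3 intake. Scaling the whole mix to the guideline multiplies
total EPA+DHA by 226.7/138.9 ≈ 1.632 while leaving every species' share
unchanged.

A command-line surface wraps the same functions
(`inst/scripts/seaomega`, subcommands
`simulate | quadrant | index | diet | report`); see `?seaomega_cli`.

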