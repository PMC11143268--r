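# phenostate

Tools for testing whether evergreen and deciduous forests form **alternative
stable states**, using two-census forest-inventory data. Written for forest
ecologists and quantitative ecologists who want to run the full chain of
evidence on their own inventories — or on the package's synthetic ones —
rather than re-deriving each piece.

The package implements four linked analyses over plot-level relative
evergreen abundance, `relEV_area = BA_EV / (BA_EV + BA_DE)` (and its
stem-count twin):

1. **Environmental null model.** Zero-adjusted Poisson (hurdle) models of
   per-plot evergreen and deciduous abundance over smooth functions of ten
   environmental principal components; 1000 simulated environment-only
   datasets give envelopes for the relEV histogram (bin width 0.05) and for
   the evergreen–deciduous Spearman correlation. Observed mass in the outer
   bins, and coupling more negative than every null draw, indicate structure
   beyond environmental filtering.
2. **Con-phenological demographic feedbacks.** Per-phenology GAMs of tree
   survival (binomial), growth (Gaussian) and plot recruitment (Poisson)
   with penalized thin-plate splines (basis dimension 5) and a linear relEV
   feedback term; contrasts `(con − hetero)/hetero × 100` predicted at
   relEV 0 and 1 (survival, growth) and the con:hetero rate ratio at
   relEV 0.9 vs 0.1 (recruitment), with 95% intervals from 100 posterior
   coefficient draws.
3. **Succession simulation.** An individual-based simulator (5-year steps,
   stand-replacing disturbance at 0.0036 yr⁻¹, recruits entering at
   12.7 cm) driven by the fitted models, in feedback and null variants, for
   generation, maintenance and hysteresis experiments along the −2…23 °C
   mean-annual-temperature gradient (12 sections, two 800:200
   initializations).
4. **Bimodality index and drivers.** Hartigan's dip statistic `D` (exact
   band-feasibility implementation), adapted dip `D' = √n·D`, and
   `BI = −exp(−6·D'²)·sign(S)` with the ±0.22 four-way classification
   (deciduous-dominated / bistable-deciduous / bistable-evergreen /
   evergreen-dominated), over fishing-net (10 arc-min) or environmental
   k-means clusters; bootstrap permutation importance (100 fits, 33%
   subsamples) of seven climatic and edaphic determinants.

A synthetic-data module (`generator_params()`,
`generate_two_census_inventory()`, …) emulates two-census inventories with
*exactly calibrated* feedback effect sizes, so every stage is testable
against known truth without any data download.

## Worked example

Generate an inventory with the default planted feedbacks (14%/17% survival
advantages, 43%/4% growth advantages, 5× recruitment ratio), fit the
feedback models and recover the contrasts:

```r
library(phenostate)

p   <- generator_params(n_plots = 3000, seed = 20240531)
env <- generate_environment(p)
inv <- generate_two_census_inventory(env, p)
m   <- fit_vital_rates(inv$trees, inv$plots, feedback = TRUE)

s <- predict_survival_growth_contrast(m, "survival", seed = 201)
g <- predict_survival_growth_contrast(m, "growth", seed = 202)
rbind(s, g)[, c("rate", "relev", "con", "rel_diff_pct", "lo95", "hi95")]
#>       rate relev con rel_diff_pct  lo95  hi95
#> 1 survival     0  DE        14.24 11.63 16.98
#> 2 survival     1  EV        16.72 14.29 20.35
#> 3   growth     0  DE         5.83  3.36  8.43
#> 4   growth     1  EV        43.78 41.68 47.17

predict_recruitment_ratio(m, seed = 203)[, c("relev", "con", "ratio", "lo95", "hi95")]
#>   relev con ratio lo95 hi95
#> 1   0.1  DE  4.58 3.85 5.63
#> 2   0.9  EV  4.95 4.11 6.05
```

Each row reads: in a stand dominated by the "con" phenology (relEV 0 =
fully deciduous, 1 = fully evergreen), the resident type's rate exceeds the
minority type's by `rel_diff_pct` percent (planted truths 14, 17, 4, 43),
and recruits of the resident type arrive about 5 times as fast (planted 5,
recovered 4.6–5.0).

A scaled succession experiment shows the feedback generating bimodality
where the null collapses:

```r
cfg <- sim_config(n_plots = 200, horizon_years = 500, step_years = 5,
                  init = "uniform", seed = 301)
x <- run_simulation(cfg, m, env)$final_relev
bimodality_result(x, p_value = TRUE, n_null = 999,
                  seed = 303)[, c("n", "D", "BI", "label", "p_dip")]
#>     n      D       BI              label p_dip
#> 1 200 0.1656 5.09e-15 bistable_evergreen     0
```

35% of the uniformly initialized plots end almost purely deciduous and 58%
almost purely evergreen; the dip test rejects unimodality (p < 0.001) and
the bimodality index sits at ~0 (bistable). The same run with the
null-variant models collapses to a unimodal evergreen-dominated state
(D = 0.0140, p = 1, BI = 0.79).

The numbered scripts under `analysis/` run the complete workflow
(`01_generate_data.R` … `06_bimodality_map.R`), writing tables under
`results/`; `run_pipeline()` offers the same stages behind a single
configuration list.

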