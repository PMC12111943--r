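# savrdemand

Demographic projection of surgical aortic valve replacement (SAVR) demand.

Degenerative aortic stenosis is overwhelmingly a disease of the elderly, so
the SAVR caseload a cardiothoracic referral centre should plan for is largely
a function of how its catchment population is aging. `savrdemand` is an R
package for planners and clinical researchers who have municipality-level
census panels (three decennial waves of age-band counts) and a departmental
surgery registry, and who want a transparent, auditable forecast of surgical
volumes one or two decades out.

The pipeline:

1. **Census data** — validated municipality × census-year panels of age-band
   counts (0–14, 15–64, 65+, optionally 75+ and by sex), with regional
   aggregation and pyramid summaries.
2. **Aging structure** — the aging index $AI = 100\,P_{65+}/P_{0\text{–}14}$
   and longevity index $LI = 100\,P_{75+}/P_{65+}$ per municipality and
   year, with Kruskal–Wallis + Dunn–Bonferroni comparison across census
   years.
3. **Growth** — geometric growth rates
   $r = 100[(P_t/P_0)^{1/t}-1]$ %/yr between waves, constant-rate projection
   $P_t = P_0(1+r/100)^t$, and doubling times $\ln 2/\ln(1+r/100)$.
4. **Scenarios** — two-phase projections of the total and 65+ populations
   under a *decreasing* scenario (the observed inter-decade slowdown, an
   absolute percentage-point decrement per decade, continues from the first
   projected decade) and a *stagnation* scenario (the last observed rate
   holds for one decade before the decrement applies).
5. **Demand** — the decade prevalence $\pi = 100\,S/P_{65+}^{end}$ (decade
   SAVR count over the end-of-decade elderly population) from the latest
   registry decade, applied to each scenario's projected elderly population
   to give expected surgeries and per-decade / per-year increases.

A synthetic census + registry generator (`synthetic_config()`,
`generate_panel()`, `generate_registry()`) reproduces the statistical
structure of such catchments so the whole pipeline is testable without any
data download.

## Worked example

Region-level inputs: a 2021 catchment of 2,319,319 people (535,894 aged 65+),
observed 2011–2021 growth rates of 0.19 %/yr (total) and 1.40 %/yr (65+),
inter-decade slowdowns of 0.30 and 0.29 percentage points, and 2,424 SAVR in
patients 65+ during 2011–2021.

```r
library(savrdemand)

tab <- scenario_table(
  p0_total = 2319319, p0_65plus = 535894,
  base_rates = c(total = 0.19, age_65_plus = 1.40),
  decrements = c(total = 0.30, age_65_plus = 0.29),
  base_year = 2021
)
tab
#>    scenario   stratum      year population  rate
#>  1 census     total        2021    2319319 NA
#>  2 census     age_65_plus  2021     535894 NA
#>  3 decreasing total        2031    2293932 -0.11
#>  4 decreasing total        2041    2201598 -0.41
#>  5 decreasing age_65_plus  2031     598439  1.11
#>  6 decreasing age_65_plus  2041     649362  0.82
#>  7 stagnation total        2031    2363765  0.19
#>  8 stagnation total        2041    2337892 -0.11
#>  9 stagnation age_65_plus  2031     615827  1.4
#> 10 stagnation age_65_plus  2041     687701  1.11
```

The elderly population keeps growing under both scenarios even while the
total population shrinks; the `rate` column shows the annual rate that
produced each decade (note the negative total-population rates). Applying the
latest decade prevalence (2424/535894 → 0.45 %) to the projected 2041 elderly
populations:

```r
demand_table(c(decreasing = 649362, stagnation = 687701),
             prevalence = 0.45,
             reference = surgery_decade(2011, 2021, 2424))
#>   scenario   projected_pop_65_plus projected_surgeries decade_increase
#> 1 decreasing                649362                2922             498
#> 2 stagnation                687701                3095             671
```

So the centre should expect roughly 500–670 additional SAVR per decade
(about 50–67 more per year) by 2041, depending on which growth scenario
materialises. At a constant 1.40 %/yr the elderly population doubles in

```r
round(doubling_time(1.40))
#> 50
project_population(535894, 1.40, 50, round = TRUE)
#> 1073932
```

years — passing the one-million mark around 2071.

For a full run on files or synthetic data, see `run_analysis()` /
`run_config()` (index tables, comparisons, scenario and demand tables, and a
versioned JSON summary), or the thin CLI wrapper in
`inst/scripts/savrdemand-cli.R` (verbs `validate`, `indices`, `project`,
`demand`, `generate`, `paper-mode`).

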