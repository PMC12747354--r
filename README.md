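# nuptiality

Tools for studying **first-marriage timing** free of age-structure and
mortality confounding, aimed at demographers and population scientists
working with census-style tabulations.

Comparing mean ages at first marriage across regions is distorted by the
population age pyramid and by mortality among the never-married. The
**net nuptiality table** removes both: a synthetic birth cohort of
$l_0 = 100{,}000$ is depleted by two decrements — first marriage (ages
15–49) and death — via

$$n_x = \frac{2\mu_x}{2+\mu_x},\qquad q_x = \frac{2m_x}{2+m_x},\qquad
l_{x+1} = l_x - f_x - d_x,\quad f_x = l_x n_x,\ d_x = l_x q_x,$$

with midpoint person-years $L_x = (l_x+l_{x+1})/2$,
$T_x=\sum_{i\ge x}L_i$, expected years in the single state
$e_x = T_x/l_x$, and the headline summary

$$fma_0 = e_{15} + 15,$$

the expected duration of singlehood since birth. Around this core the
package provides:

* a parametric Gompertz–Makeham (+ infant) mortality model calibrated to
  a target life expectancy (`hazard_schedule()`, `calibrate_to_e0()`);
* table construction and summaries (`build_table()`, `gross_table()`,
  `never_married_proportion()`, `table_summary()`);
* synthetic census-like generators with known ground truth and a
  discrete-time microsimulation oracle (`gen_marriage_schedule()`,
  `gen_census_counts()`, `gen_panel()`, `microsim_cohort()`);
* cross-province analytics: peak marriage ages, low/medium/high k-means
  profile clusters, urban–rural and male–female gap tables, global
  Moran's I with a permutation test (`cluster_provinces()`,
  `gap_table()`, `morans_i()`);
* two-way fixed-effects panel regression of log first-marriage age with
  province-clustered (CR1) standard errors and region-interaction
  specifications (`fit_fe()`, `fit_interaction()`, `lsdv_oracle()`);
* CSV readers/writers for the census-counts, life-expectancy and panel
  schemas, and a small CLI (`run_cli()`, wrapper in `inst/cli/`).

See the methods vignette (`vignettes/net-nuptiality-methods.Rmd`) for
the model, its assumptions and the design choices.

## Worked example

Build a net nuptiality table for one stratum: a bell-shaped marriage
schedule (mean age 27, spread 4 years, 97% ever marrying) against
mortality calibrated to a life expectancy of 78 years.

```r
library(nuptiality)
mort <- calibrate_to_e0(78, "male")
mar  <- gen_marriage_schedule(mean_age = 27, spread = 4,
                              ultimate_proportion = 0.97,
                              province = "P01", sex = "male",
                              residence = "total")
tab <- build_table(mar, mort)
round(tab[tab$x %in% 25:29, ], 4)
#>     x    n_x   q_x      l_x     d_x      f_x      L_x      T_x    e_x
#> 26 25 0.1291 5e-04 68411.32 34.4556 8832.146 63978.02 423356.8 6.1884
#> 27 26 0.1576 5e-04 59544.72 31.7917 9385.993 54835.83 359378.8 6.0354
#> 28 27 0.1869 6e-04 50126.94 28.4313 9369.723 45427.86 304543.0 6.0754
#> 29 28 0.2157 6e-04 40728.78 24.5910 8786.221 36323.38 259115.1 6.3620
#> 30 29 0.2425 6e-04 31917.97 20.5554 7739.318 28038.03 222791.8 6.9801
attr(tab, "fma0")
#> [1] 28.53913
never_married_proportion(tab, mort, 49)
#> [1] 0.02991196
```

Reading the output: of 100,000 newborns, 68,411 are still alive and
never married at exact age 25; 8,832 marry during that year and 34 die.
The cohort expects to spend 28.54 years single from birth (`fma0`), and
3.0% of survivors reach age 49 never married.

The panel stage estimates determinants of log first-marriage age on a
balanced 31-province × 25-year panel (here synthetic, with a true
schooling elasticity of 0.10):

```r
pan <- gen_panel(31, 25, seed = 42)
fit_fe(pan, spec = "twoway_fe")
#> <fe_result>  spec: twoway_fe,  N = 775,  clusters = 31
#>              term estimate cluster_se        p
#>           edu_log   0.0982     0.0157 6.88e-07 ***
#>      ethnic_ratio  -0.0042     0.0358    0.908
#>        income_log   0.0188     0.0069   0.0108  **
#>        urban_rate   0.0198     0.0295    0.508
#>  dependency_ratio   0.0009     0.0005   0.0661   *
#> Year fixed effects: yes
#> Province fixed effects: yes
#> within R-squared: 0.955
```

The schooling elasticity is recovered (0.098 against a truth of 0.10,
well within one clustered standard error); coefficients are identical to
the explicit dummy-variable (LSDV) estimator.

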