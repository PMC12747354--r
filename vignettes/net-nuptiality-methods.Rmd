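---
title: "Net nuptiality tables and first-marriage timing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net nuptiality tables and first-marriage timing: models and methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuptiality)
```

## The problem

Comparing average ages at first marriage across regions or over time is
confounded by population age structure and by mortality: a region with a
young age pyramid mechanically shows a younger mean marriage age, and the
never-married population is also depleted by death. The net nuptiality
table removes both confounders by pushing a synthetic birth cohort of
fixed size (the radix, 100,000) through a double-decrement life table in
which never-married people exit either by first marriage or by death. Its
headline summary, the expected duration of singlehood since birth
(`fma0`), is a pure period measure of marriage timing, free of age
structure.

## The double-decrement model

Inputs are age-specific occurrence/exposure rates: the first-marriage
rate $\mu_x$ (first marriages during the year divided by the mid-year
never-married population at age $x$) and the death rate $m_x$. Both are
converted to single-year probabilities with the linear-exposure formula

$$n_x = \frac{2\mu_x}{2+\mu_x}, \qquad q_x = \frac{2m_x}{2+m_x},$$

implemented in `rate_to_probability()`. The conversion assumes events are
spread evenly over the year; its domain is $0 \le r \le 2$ and $r = 2$
maps to probability 1.

First marriage is confined to ages 15–49: marriage before exact age 15 is
rare enough to ignore, and the open age group from exact age 50 has no
further first marriages. The survivorship recursion in `build_table()` is

$$l_{x+1} = \begin{cases} l_x - d_x & x < 15\\
l_x - f_x - d_x & 15 \le x \le 49 \end{cases}
\qquad f_x = l_x n_x,\; d_x = l_x q_x,$$

with $l_0$ the radix. Competing events within the same year (marry then
die, or die while about to marry) are deliberately not modelled: at the
very low mortality of marriageable ages their joint probability is
second-order, and including them would require data on the marital status
of decedents that census tabulations do not provide. The sum $n_x + q_x
\le 1$ is enforced as a hard validity check rather than renormalised,
because renormalising would silently change the model the inputs claim to
describe.

Person-years in the never-married state use the midpoint (uniform
decrement) convention $L_x = (l_x + l_{x+1})/2$ — equivalently, every
event happens at mid-interval. One sometimes sees this formula written
with an index shifted by one year, which reads as $l_x$ plus half a
*negative* increment and cannot be a person-years quantity for a
decreasing cohort; the midpoint form is the standard convention and the
only one offered, so tables built here are always comparable with one
another. Mid-interval timing is used consistently everywhere: in the
table, in the microsimulation, and in the brute-force mean-age oracle.

**The open age group.** Never-married survivors at exact age 50 no longer
marry, but they go on living — and living single. Under the default
policy (`open_age_policy = "mortality_expectancy"`) they contribute
$L_{50+} = l_{50} \, e_{50}$ person-years, where $e_{50}$ is the
remaining life expectancy at 50 under the mortality schedule. A
`"censor"` option ($L_{50+} = 0$) is provided for users who prefer to
count single years only inside the 15–49 window; the choice matters
exactly in proportion to $l_{50}$, i.e. to the fraction never marrying.

Cumulating, $T_x = \sum_{i \ge x} L_i$, the expected years remaining in
the single state are $e_x = T_x / l_x$ (undefined, not zero, where the
cohort is exhausted), and

$$fma_0 = e_{15} + 15.$$

With zero mortality and everyone marrying by 49, $fma_0$ reduces exactly
to the mean age at marriage $\sum_x f_x (x + 0.5) / \sum_x f_x$ — a
closed-form identity the tests verify to machine precision.

`gross_table()` builds the same table with mortality forced to zero
(marriage the only decrement); comparing gross and net tables isolates
the — small, at modern mortality — contribution of never-married deaths.
`never_married_proportion()` divides $l_x$ by the mortality-only
survivorship from the same radix, giving the share never married among
survivors under the assumption that death is unrelated to marriage.

## The mortality model

Published model life tables are external data; the package instead uses a
self-contained parametric family (`hazard_schedule()`),

$$m_x = \text{makeham} + \text{level}\cdot e^{\text{slope}\cdot x}
      + \text{infant}\cdot e^{-\text{decay}\cdot x},$$

a Gompertz–Makeham senescent hazard plus a decaying infant component,
evaluated at integer ages 0–100 with $q_x = 1 - e^{-m_x}$ (constant
hazard within the year) and a closed-out table: survivors to exact age
100 die there. This is adequate because the nuptiality results depend on
mortality only through (a) the low hazards at ages 15–49 and (b) $e_{50}$
for the open group — any smooth schedule with the right level reproduces
both. `calibrate_to_e0()` solves for the level by bisection (log scale,
converged when the implied $e_0$ is within 0.01 years of target), with
sex-specific fixed shape constants: slope 0.095/0.100/0.097 per year and
small background and infant components for male/female/total. Targets
between 40 and 95 years are accepted; outside the achievable range of the
family an error reports the attainable bounds.

Note one deliberate asymmetry: the table builder applies the $2m/(2+m)$
conversion to whatever $m_x$ it is given (keeping the double-decrement
arithmetic internally consistent), while the mortality object's own
$q_x$ and life expectancy use the exact constant-hazard conversion. At
the hazards involved the two differ at second order in $m$.

## Synthetic data with known ground truth

No census micro-tabulations ship with the package; every pipeline stage
is instead exercised on generated data whose truth is known.

**Marriage schedules** (`gen_marriage_schedule()`) are discretized
Gaussian bells over ages 15–49, parameterised by the cohort mean age at
marriage, the spread (standard deviation, years) and the ultimate
proportion ever marrying. The bell centre is solved internally so the
truncated, discretized mean equals the requested mean age exactly; the
per-age marriage probabilities are then recovered from the implied
marriage-age density, so a gross table built from the schedule reproduces
the requested distribution exactly (the calibration contract is tested at
±0.1 years and ±0.005 in proportion). Combinations whose bell centre
would fall outside the age span (say, mean age 16 with a large spread)
are rejected rather than degenerated into a boundary spike. A
Coale–McNeil standard schedule would be more realistic in its long right
tail; the bell is simpler, fully self-contained, and sufficient for
testing order relations and calibration contracts. Real schedules'
asymmetry is the main feature the generator does *not* emulate, so
passing tests say nothing about fit to any observed population.

**Census counts** (`gen_census_counts()`) draw first-marriage counts per
age cell as Binomial$(2E, \mu_x/2)$ around a constant never-married
exposure $E$ (default $10^5$; the empirical rate is then unbiased for
$\mu_x$ and bounded by 2). Default stratum designs place male mean ages
two years above female and urban one year above rural, with provinces
spread over ±2 years — the orderings, not the magnitudes, of real
tabulations. Province sizes, real age pyramids and non-binomial
overdispersion are not emulated.

**The microsimulation oracle** (`microsim_cohort()`) realises the same
decrement process one individual at a time: one uniform draw per
person-year, marriage if $u < n_x$, death if $n_x \le u < n_x + q_x$,
events at mid-interval, mortality-only before 15 and after 49. Because
it shares the analytic table's probabilities exactly (the $2m/(2+m)$
conversion through age 49, the exact conversion past 50 where the
open-group expectancy is defined), it is an independent check of the
table *arithmetic*, not of the model assumptions. Agreement is asserted
within three binomial/empirical standard errors at $n = 200{,}000$.

**Panels** (`gen_panel()`) generate a balanced province × year panel
(default 31 × 25 = 775 rows) from a log-linear process: log
first-marriage age is linear in log years of schooling (default
elasticity 0.10), the ethnic-minority proportion (−0.03), log per-capita
income, urbanization rate and dependency ratio, plus province effects,
year effects and i.i.d. noise (default sd 0.01, matching the small
within-province variation of a slow-moving demographic outcome).
Regressors carry province-level components *correlated with the province
effects*, so pooled OLS is biased by construction and the within
transformation is genuinely load-bearing — a property the tests assert.

## Fixed-effects estimation

`fit_fe()` estimates the determinants of log first-marriage age by the
within estimator: all variables are demeaned by province, and under
`spec = "twoway_fe"` year indicators are added, so coefficients equal the
least-squares-dummy-variable estimator (verified against `lsdv_oracle()`
to 1e−8 relative on random panels). Log transforms follow the usual
elasticity reading: outcome, schooling and income logged; proportions
(ethnic share, urbanization) and the dependency ratio in levels.

Standard errors are clustered by province with the CR1 small-sample
correction $\frac{G}{G-1}\frac{N-1}{N-k}$ — the most common default in
applied panel work at $G \approx 31$ clusters — where $k$ counts slopes
plus absorbed fixed effects; p-values use a $t$ reference with $G-1$
degrees of freedom, and stars mark 0.01/0.05/0.1. With singleton
clusters this reduces exactly to the HC1 heteroskedasticity-robust
estimator, a reduction the tests check against an independent
implementation. The reported $R^2$ is the within-$R^2$ (share of
demeaned outcome variance explained), labelled as such because other
$R^2$ flavours are not comparable across software.

`fit_interaction()` adds a focal × region interaction (schooling or
ethnic share, with East/Central/West indicators) to the two-way
specification. The region indicator itself is province-constant and
absorbed by the province effects; identification comes from the focal
regressor's time variation, and a focal regressor that is constant
within provinces correctly triggers a rank-deficiency error. A planted
regional slope offset of −0.05 is recovered within two clustered
standard errors in the simulation checks, and 95% confidence intervals
cover the true schooling elasticity at close to the nominal rate over
200 replications (reported, not hard-asserted, since 200 replications
resolve the rate only to a couple of percentage points).

## Cross-province summaries

`cluster_provinces()` groups first-marriage probability profiles (rows =
provinces, columns = ages 15–49) by k-means with 25 restarts under a
fixed seed, then relabels clusters low/medium/high by ascending mean
probability. k-means on raw profiles is the simplest method consistent
with a three-way level categorisation; rows are sorted by province name
before clustering so results are invariant to input order. `peak_age()`
breaks ties toward the younger age. `morans_i()` computes global Moran's
I over a user-supplied spatial weights matrix (row-standardised by
default) with a two-sided permutation pseudo p-value (≥999 seeded
permutations; null expectation $-1/(n-1)$). No geographic adjacency for
any real country is bundled: weights are the caller's responsibility,
and tests use synthetic lattices. `gap_table()` reports per-province
male−female and urban−rural differences in `fma0` and `e15`
(first-listed minus second-listed; missing counterpart strata are
flagged, never dropped).

## Numerical choices and limitations

* Ages are integers; intervals are half-open $[x, x+1)$; "exact age $x$"
  is the lower endpoint; events are mid-interval everywhere.
* Calibration tolerance 0.01 years on $e_0$; bisection on the log level
  with a bracket spanning hazard levels $10^{-12}$–$1$.
* The simulation-based checks use $n = 200{,}000$ individuals for the
  microsimulation, 100 random schedule pairs for conservation, 50 random
  panels for the estimator identity and 200 replications of the 31 × 25
  panel process — sizes at which the Monte-Carlo bounds above are tight
  while the whole suite runs in seconds.
* Period (synthetic-cohort) tables only: no cohort tables, no abridged
  five-year age groups, no remarriage or divorce decrements.
* The dependent variable of the panel stage is the *average* age at
  first marriage, not `fma0`: constructing `fma0` for every province-year
  would need yearly never-married mortality, which census-style inputs
  do not provide. The two measures track each other but are not
  identical, a limitation inherited from the data situation the package
  models.
* Calendar alignment of the input tabulations (e.g. a census year whose
  enumeration window is incomplete) is the caller's responsibility and
  is logged, not corrected.
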