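---
title: "Methods: simulating the cost-utility of sweetened-beverage taxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the cost-utility of sweetened-beverage taxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbtaxsim)
```

# The model

`sbtaxsim` implements a comparative cost-utility model for specific
(per-litre) excise taxes on sweetened beverages, of the proportional
multi-state life-table family widely used in preventive-health economic
evaluation. The causal chain is:

1. **Tax to price.** A specific tax of rate $\tau_j$ (currency per
   litre) on category $j$, with pass-through $\varphi \in [0,1]$ and a
   mean retail price $P$ per litre, raises the consumer price by the
   fraction $\Delta p_j = \varphi \tau_j / P$. Excluded categories have
   $\tau_j = 0$ and hence no price change. With the bundled defaults
   ($P = 45.05$, $\varphi = 1$) a 10/litre rate is a 22.2% price rise
   and a 6/litre rate 13.3%; because the map is linear, any two uniform
   rates produce consumption responses in the exact ratio of the rates.
2. **Price to consumption.** The fractional change in consumed volume
   of category $j$ is the elasticity-weighted sum of all price changes,
   $\Delta q_{j,g} = q_{j,g} \sum_k \varepsilon_{jk} \Delta p_k$, a
   point (arc-free) response with no second-order terms. Own-price
   entries $\varepsilon_{jj}$ are negative; positive cross-price
   entries on the coffee- and milk-based rows generate substitution
   towards those categories whenever they are exempt. Baseline
   consumption $q_{j,g}$ is reported for five age bands and assigned
   (not interpolated) to every single year of age in the band — the
   resolution at which consumption surveys report.
3. **Consumption to energy.** $\Delta E_g = \sum_j \Delta q_{j,g}
   e_j / 100$ with energy densities $e_j$ in kJ per 100 ml, so
   zero-calorie categories contribute nothing.
4. **Energy to weight and BMI.** The steady-state energy-balance form
   $\Delta w = \Delta E / \rho(a)$ converts a sustained intake change
   into an equilibrium weight change, attained immediately and
   maintained for life; $\Delta \mathrm{BMI} = \Delta w / h_g^2$ with
   the group's mean height. The within-group BMI distribution shifts by
   location only: the spread is untouched.
5. **BMI to disease.** For each of nine obesity-related diseases (type
   2 diabetes, hypertensive heart disease, ischaemic heart disease,
   stroke, osteoarthritis of the hip and knee, and kidney, colorectal,
   endometrial and breast cancers) with a log-linear risk relation
   $RR(\mathrm{BMI}) = e^{\beta_d \mathrm{BMI}}$, a pure location shift
   gives the potential impact fraction in closed form,
   $\mathrm{PIF}_d = 1 - e^{\beta_d \Delta \mathrm{BMI}}$. A quadrature
   route that integrates $RR$ over the full normal BMI distribution is
   provided as a numerical cross-check; for pure shifts the two agree
   to machine-level precision (the package tests assert $10^{-6}$).
6. **Disease to survival and HALYs.** Each sex-by-age cohort of the
   closed population (ages 2–100, no births or migration) carries one
   zero-remission illness-death process per disease: healthy to
   diseased at incidence scaled by $1-\mathrm{PIF}$, diseased to
   dead-of-disease at the case-fatality rate. Total mortality each year
   is an other-cause background schedule plus current modelled disease
   mortality, so averted disease deaths extend survivorship. Morbidity
   $Y$ is prevalence-weighted disability over the nine diseases; below
   age 19 it additionally includes utility decrements per unit
   prevalence of overweight and obesity, computed from the (shifted)
   within-group BMI distribution against BMI-for-age cut-offs.
   Health-adjusted person-years accrue as $L (1 - Y)$ with midpoint
   person-years $L = (\ell_t + \ell_{t+1})/2$. Incremental HALYs are
   the intervention-minus-baseline HAPY stream discounted at 3% to the
   reference year.
7. **Economics.** Healthcare cost offsets price cancers on
   incident-case deltas and other diseases on prevalent case-year
   deltas, discounted at 3%; averted cases are savings. Net cost is
   offsets plus the policy implementation/monitoring cost. Taxation
   revenue — post-tax volume times the rate, survivorship-weighted and
   discounted over the cohort's lifetime — is a transfer between
   consumers and government: it is reported, but never enters net cost
   or the ICER. An intervention with negative net cost and positive
   HALYs is *dominant* and reported categorically; otherwise the ICER
   is compared with the threshold (168,236 per HALY by default, a
   per-capita-GDP convention), equality counting as cost-effective.

# Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| pass-through $\varphi$ | 1.0 | – | full pass-through of a producer-levied specific tax; configurable for sensitivity use |
| mean price $P$ | 45.05 | currency/litre | single economy-wide mean; per-category prices can be supplied by using per-category rates with adjusted ratios |
| $\rho$ adult | 94 | kJ/day per kg | `hall94` profile; the `paper_calibrated` profile re-anchors at 107.8, the population-level factor implied by published tax-evaluation intake/weight pairs. Children get $\rho(a) = \rho_{adult} + 2(19-a)$, declining to the adult value at 19 |
| discount rate $r$ | 0.03 | /yr | applied to HALYs, offsets, revenue; incident-case counts are reported undiscounted |
| threshold | 168,236 | currency/HALY | inclusive comparison ("less than or equal") |
| implementation cost | 5,400,016 per 10M population (base year) | base currency | converted with an explicit exchange rate (45.11) and annual CPI factors (cumulative ≈ 1.25); `fixed_total` mode (default) treats the converted figure as the national total, `scaled` multiplies by population/10M |
| Monte Carlo repetitions | 2000 | – | percentile 95% uncertainty intervals |

The `fixed_total` default deserves a note: a strict linear scale-up of a
per-10-million-population cost to a ~100M-person population yields a
total roughly tenfold the published convention for this intervention
class, whose printed totals sit close to the *unscaled* converted
figure. Both modes are implemented; the bundled default mirrors the
published accounting, and the choice only matters for the (small)
implementation-cost term — under every bundled scenario the
intervention remains dominant in either mode.

# The synthetic-data generator

All inputs are synthetic and generated by pure functions of a seed, so
the full pipeline runs and is testable without any external data. The
generator emulates the *statistical structure* the analysis assumes:

* a closed population with one cohort per sex and single year of age
  2–100 (198 cohorts, ≈100M persons), an exponentially decaying age
  pyramid, a child growth curve, and mean BMI rising from the
  mid-teens in early childhood to the low twenties in adulthood;
* per-capita consumption of nine beverage categories across five age
  bands, with energy densities fixed at food-composition-table values
  (soft drinks 174 kJ/100 ml, sports/energy 191, juices 184, milk- and
  grain-based 266, coffee-based 260, lighter values for teas and
  reconstituted powders);
* own-price elasticities near −1 and small positive cross-price
  elasticities on the coffee and milk rows, plus an alternative
  elasticity set with ~35% stronger own-price responses for sensitivity
  use;
* for each disease, smooth adult-onset incidence and case-fatality
  curves — and **prevalence derived from them** by the forward
  illness-death cohort recursion with zero remission. Consistency of
  the three rate sets is therefore exact by construction rather than
  imposed by an external rate-balancing tool; `check_consistency()` is
  the public contract and the test suite holds every generated disease
  to a residual below $10^{-9}$;
* an all-cause mortality envelope containing the modelled disease
  deaths (the engine nets them out to form the other-cause schedule);
* child BMI-for-age cut-offs rising monotonically to the adult 25/30 at
  age 18, with two utility-decrement sets (a default and a smaller,
  review-style alternative).

Magnitudes are loosely calibrated so pipeline outputs land at realistic
orders for a large lower-middle-income country — tens of ml/day of
consumption reduction, a few tenths of a BMI unit, millions of HALYs,
tens of billions in healthcare savings — and the adult consumption
levels were sized once, from the arithmetic structure of published
per-category responses to 13.3%/22.2% price rises, before any test was
written. No synthetic default is presented as an estimate for any real
population: passing tests demonstrate the correctness and coherence of
the *machinery*, not the accuracy of any country-specific projection.
Real consumption microdata, real disease registries and a real
elasticity matrix would differ in level, correlation structure and
measurement error in ways the generator does not emulate.

One convention worth noting: band-level consumption is reported for men
and women combined (the survey convention); a sex-stratified mode
exists in the generator configuration but is off by default.

# Numerical and design choices

* **Annual cycles, ages 2–100, extinction at 100.** Person-years by the
  midpoint rule. Rates convert to one-year probabilities as
  $p = 1 - e^{-r}$, keeping probabilities in $[0,1]$ for any
  non-negative rate; the same conversion is used in the generator's
  recursion, the engine, and the consistency check, so the three are
  mutually exact.
* **Remission is zero** for all nine diseases (illness-death model).
* **No risk lag:** disease risk responds to the BMI shift from the
  first simulated year at adult ages. The nine diseases are adult-onset
  in the generator (zero incidence below 19), so child cohorts
  accumulate no disease change until they age into adulthood — their
  childhood HALYs accrue only through reduced overweight/obesity
  disutility — and their BMI shift persists for life.
* **Each cohort keeps its initial-age consumption delta and BMI shift
  for life** (the tax's behavioural effect is assumed permanent); the
  alternative — re-assigning band consumption as cohorts age — would
  mix the intervention effect with cross-sectional age patterns.
* **Overweight disutility is applied to overweight-but-not-obese mass**
  and the obesity decrement to the obese tail, avoiding double
  counting.
* **Degenerate inputs:** zero baseline consumption gives zero response;
  an empty disease submodel cell ($S + C = 0$) contributes zero
  prevalence; morbidity is capped just below 1; negative post-tax
  volumes are clamped to zero with a warning.
* **Baseline and intervention arms always share every input** except
  the BMI shift, including the child-utility set of the scenario under
  evaluation, so sensitivity scenarios that swap a valuation set change
  both arms coherently.
* **Incremental analysis is always against do-nothing**;
  scenario-versus-scenario contrasts are computed from headline
  metrics afterwards (`comparative_stats()`), never by differencing
  life tables directly.
* **PSA.** Distribution families per input type: truncated normal for
  elasticity and consumption multipliers, normal for energy density,
  lognormal for the relative-risk multiplier, a domain-bounded
  multiplier for disability/utility weights, gamma for cost
  multipliers. Truncation is honoured by resampling. One master seed
  derives all per-repetition substreams up front, so results are
  independent of evaluation order; percentile (not BCa) intervals are
  reported, and the dominance verdict is tallied per draw so an ICER
  interval can be reported as "Dominant–Dominant".

# Problem sizes

The bundled fixture is the full 198-cohort population over its whole
lifetime; one scenario evaluation (two life-table arms) takes well
under a second. The test suite's Monte Carlo convergence checks run the
complete pipeline at 250/1000/4000 repetitions on the 60+ sub-population
(82 cohorts), whose shorter horizon keeps per-repetition cost low while
exercising every pipeline stage; the analysis scripts default to 400
repetitions on the full fixture and accept a repetition count on the
command line for full-scale (e.g. 2000-repetition) runs.

# Known limitations

* The energy-balance factor is a steady-state linear rule; dynamic
  body-composition trajectories, growth in children, and non-caloric
  metabolic effects of sweeteners are out of scope.
* Elasticity responses are linear in the price change and ignore
  income effects, demand-system restrictions (adding-up, symmetry) and
  substitution to foods outside the nine beverage categories.
* Disease processes are independent given BMI: no comorbidity
  correlation, no trends in future incidence, no open-cohort
  replenishment.
* Revenue assumes constant per-capita consumption within surviving
  cohorts; product reformulation and deadweight loss are excluded.
* The qualitative finding on the bundled fixture — every positive tax
  scenario is dominant — is a property of the synthetic inputs'
  realistic-order magnitudes, not evidence about any particular
  jurisdiction.
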