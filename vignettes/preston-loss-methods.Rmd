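---
title: "Extended Preston curves and pandemic progress-loss projections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended Preston curves and pandemic progress-loss projections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package estimates, for each health-related SDG indicator, an extended
Preston curve: a log-log panel relationship between the indicator and
per-capita income, augmented with two further health determinants and a
region-varying income elasticity,

$$
\ln \mathrm{SDG}_{i,t} \;=\; \alpha
  + \beta_1 \ln \mathrm{GDPpc}_{i,t}
  + \beta_2 \ln \mathrm{Gini}_{i,t}
  + \beta_3 \ln \mathrm{HE}_{i,t}
  + \beta_4 \,\ln \mathrm{GDPpc}_{i,t} \times R_i
  + f_i + \tau_t + \varepsilon_{i,t},
$$

where $i$ indexes countries and $t$ five-year periods, $\mathrm{HE}$ is
health expenditure as a share of GDP, $R_i$ is the country's region (the six
WHO regions plus China and India, with AFR the baseline so $\beta_4$
measures each region's *additional* GDP elasticity), $f_i$ are country fixed
effects and $\tau_t$ period fixed effects. All variables enter in natural
logarithms, so $\beta_1 + \beta_4[R_i]$ is the percent response of the
indicator to a 1% change in per-capita GDP — the quantity everything
downstream consumes.

Yearly observations are averaged into fixed five-year windows before the log
transform (`build_periods()`). Period averaging suppresses serial
correlation and year-to-year measurement noise and is what makes $t$ a
period index; windows tile forward from the configured start year, partial
windows are kept with their year count recorded, and empty windows are
absent rather than zero-filled. Whether covariates are averaged over the
same windows as the outcome is not dictated by the data model; the package
windows both sides identically, which keeps the two panels aligned by
construction.

## Estimation

`fit_panel_fe()` implements the within estimator: every variable is demeaned
within country, period effects enter as dummy columns, and the slopes are
obtained by least squares on the demeaned system. The slopes are numerically
identical to explicit-dummy least squares (LSDV); the test suite enforces
agreement to 1e-8 on randomly generated unbalanced panels, with plain
`lm()` on country dummies as the independent oracle. Reported fit statistics
follow the panel-software convention: within/between/overall R² are squared
correlations of the linear predictor with the response on the demeaned,
country-mean, and raw scales.

Columns that lose all variation after demeaning, or that are exactly
collinear, are removed by a greedy rank-revealing sweep (relative tolerance
1e-10) that walks columns in a fixed priority order — main effects, then
regional interactions, then period dummies — so, for example, a subsample
containing a single non-baseline region keeps `ln GDPpc` and drops that
region's interaction. Dropped terms are recorded by name in the fit object
and surface as missing estimates in coefficient tables.

Indicators whose series reduce to a single usable period (one survey round)
cannot support unit or time effects; `balance_check()` flags them and
`fit_all()` routes them to single-period cross-sectional OLS
(`fit_cross_section_ols()`), which reports overall R² only. With fewer than
two countries a cell is recorded as failed, never silently skipped.

Standard errors are conventional homoskedastic within-estimator errors by
default, with a country-clustered (CR1) option (`run_config(cluster_se =
TRUE)`); the joint statistic is labelled with the assumption used.

## Subsamples, coverage and income groups

Because residual structure correlates with development level, each indicator
is fitted globally *and* within four World Bank income groups, classified
from anchor-year (2019) per-capita GDP with brackets
$[0, 1045]$, $(1045, 4095]$, $(4095, 12695]$, $(12695, \infty)$ — the
one-dollar gaps in the published bracket edges are closed so the
classification partitions any input. An (indicator, group) cell enters
estimation only if at least 40% of the group's countries report the
indicator at least once (`apply_coverage_filter()`; threshold configurable).
The rule is implemented as *retain iff reporting fraction ≥ threshold* — the
conservative reading, since dropping thinly reported cells avoids overstating
group losses from unrepresentative countries.

## Projection

Projections hold the Gini index, health expenditure, the country effect and
the last period effect fixed, so every level term cancels and the projected
path depends only on the GDP ratio and the elasticity:

$$
\widehat{\mathrm{SDG}}_{i,y} = \mathrm{SDG}_{i,\mathrm{last}}
  \left( \frac{\mathrm{GDP}_{i,y}}{\mathrm{GDP}_{i,\mathrm{anchor}}} \right)^{\beta_1 + \beta_4[R_i]},
$$

with the GDP path compounded from the anchor level through the scenario's
yearly growth rates. Anchoring on the last *observed* value (rather than the
fitted level) makes the loss independent of the unknown country effect. Two
design points deserve note:

* **Twelve growth applications.** The growth-rate tables are interpreted as
  applying from the anchor year through the horizon (2019–2030 inclusive),
  i.e. the anchor GDP is the start-of-anchor-year level. This is the only
  convention under which constant paths at the published mean group rates
  reproduce the published 2030 GDP forecasts for all four income groups to
  within 2%; with eleven applications, the low-income forecast is
  unreachable by *any* yearly path averaging the published rate (arithmetic
  mean bounds the compound product from above).
* **Elasticity lookup.** Under the default `subsample_mode =
  "by_income_group"`, a country's elasticity comes from its income group's
  fit plus its region's interaction where estimable (a dropped interaction
  contributes zero); `"global"` mode uses the pooled fit. Countries lacking
  a retained fit or scenario coverage are skipped with a logged reason.

Both scenario vintages are projected per country and indicator; projections
are restricted to the configured projection years (default 2021–2030).

## The loss statistic

For each (country, indicator), with final-year forecasts $\hat v^{\mathrm{post}}$
and $\hat v^{\mathrm{pre}}$:

$$
\mathrm{loss} = 100 \cdot s \cdot
  \frac{\hat v^{\mathrm{post}} - \hat v^{\mathrm{pre}}}{\hat v^{\mathrm{pre}}},
\qquad s = \begin{cases} +1 & \text{higher is better} \\ -1 & \text{lower is better,} \end{cases}
$$

so negative always means foregone progress. The default denominator is the
baseline 2030 forecast (loss relative to where the country would have been);
`loss_denominator = "anchor_value"` divides by the last observed value
instead — the convention the published GDP-loss row uses
(`gdp_loss_proportion()` divides the forecast revision by anchor-year GDP).
Direction metadata for the 43 real indicator codes ships with the package
(`read_indicator_meta()`), assigned from each indicator's definition:
mortality/incidence-type indicators are lower-is-better,
coverage/personnel-type higher-is-better.

Aggregates (`aggregate_losses()`) are single-stage unweighted means of all
(country, indicator) records in a cell — theme × income group, indicator ×
income group, per country, or per income group — with contribution counts
that sum to the number of input records. `disparity_ratio()` reports the
magnitude ratio of two group means.

## The synthetic world

No bundled copy of the UN SDG, IMF or World Bank inputs exists, so
`gen_world()` draws complete worlds from the generative model the estimator
assumes, with known parameters:

* **Countries.** Regions and income groups drawn from configurable mixtures;
  anchor GDP log-uniform inside the income bracket.
* **GDP paths.** Back-cast geometrically from the anchor with group-level
  drift (2010s decade averages per group), a persistent country offset
  (sd 1.5 pp/yr) and transitory yearly jitter (sd 3 pp/yr). These two
  dispersions were fixed once at values typical of observed cross-country
  growth variation; they also supply the within-country variation that
  identifies the GDP elasticity once common period effects are absorbed.
* **Covariates.** Gini per country uniform in [25, 55] with a small yearly
  lognormal wiggle (a within estimator needs *some* time variation to
  identify its coefficient at all); health expenditure lognormal around
  group means 5.85/5.75/7.14/9.00 % of GDP, rising with income.
* **Indicators.** Log period values follow the model exactly with
  $f_i \sim N(0, \sigma_c)$, $\tau_t \sim N(0, \sigma_p)$,
  $\varepsilon \sim N(0, \sigma_\varepsilon)$ (defaults 0.25/0.05/0.10);
  default elasticities span the range typical of fitted health indicators
  (−1.4 to +0.9), with per-income-group overrides available. Yearly values
  are held constant within each five-year window, so period-averaging then
  logging reproduces the log-linear model without aggregation bias — this
  is what makes the noiseless closure (generator → fit → project → loss,
  exact to machine precision) a meaningful oracle, and it is also the
  generator's main departure from real yearly series, which vary within
  windows. Passing tests therefore certify the pipeline's arithmetic and
  statistical behaviour under the model's own assumptions, not the model's
  adequacy for any real indicator.
* **Scenarios.** Per-country rates are the group scenario means
  (5.20/4.27/3.07/2.12 pre vs 4.36/3.45/2.71/2.02 post, percent per year)
  plus a persistent country offset shared between vintages, so the revision
  is a clean group-level shock. Missingness removes whole (country,
  indicator) series at a configurable per-group rate — the minimal
  mechanism the coverage rule needs.

Seeding is pinned to a fixed generator (Mersenne–Twister / inversion /
rejection sampling), so identical seeds give bit-identical worlds across
platforms, and the caller's RNG state is restored.

## Numerical and degenerate-input choices

* Collinearity tolerance 1e-10 (relative, rank test); keep-priority as
  above; ties cannot arise because the sweep is sequential.
* Values of exactly 0 are treated as missing for log-modelled indicators
  and counted separately in load reports; negative values are dropped as
  invalid. Load reports always satisfy kept + dropped = total.
* Full-precision CSV output is written with 17 significant digits and read
  back through the C library's correctly rounded parser, so results files
  round-trip bit-exactly.
* Degenerate cells (one country, all-collinear designs, underdetermined
  cross-sections, empty groups, missing scenario years) raise typed errors
  or recorded failures rather than producing numbers.

## Problem sizes used in the checks

The bundled analysis scripts and acceptance checks use worlds of 40–160
countries, 20 years, and 1–4 indicators; the parameter-recovery study runs
100 replicates of 150 countries × 4 periods with $\sigma_\varepsilon = 0.1$
on a single-region world (so the study isolates $\beta_1$ rather than a
region composite). At these sizes the full pipeline runs in well under a
minute on one core.

## Known limitations

* Within-window dynamics of real indicator series are not emulated
  (piecewise-constant years), and residuals are homoskedastic and serially
  independent by construction.
* The projection freezes period effects after the last estimated period;
  the model offers no law of motion for $\tau_t$, so any secular drift
  beyond GDP is outside the forecast.
* No population weighting in aggregation (means are per-country), and no
  uncertainty intervals on projections or losses.
* The GDP series' price basis (PPP vs market rates) is not interpreted;
  only GDP *ratios* enter projections, and classification thresholds are
  applied to whatever units the inputs carry.
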