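# esmrel

Variance decomposition and reliability for dyadic experience-sampling
scales.

## The problem

Experience-sampling (ESM) studies of couples deliver short self-report
scales several times a day, over days or weeks, to both partners. A score
from such a study can be aggregated — and should be reliable — at four
different levels: the couple, the person, the person-day, and the single
survey (person-day-moment). Classical reliability coefficients answer none
of these questions directly, because every observation simultaneously
reflects couple, person, day, moment and item effects.

`esmrel` implements a generalizability-theory (GT) model for this design.
Item responses are decomposed by a crossed/nested random-effects model: for
person *p* nested in couple *c*, answering item *i* at moment *m* of day
*d*,

    Y_cpdmi = mu + C_c + P_p(c) + D_d + M_m + I_i
            + (CD) + (CM) + (CI) + (PD) + (PM) + (PI) + (DM) + (DI) + (MI)
            + (CDM) + (CDI) + (CMI) + (PDM) + (PDI) + (PMI) + (DMI)
            + (CDMI) + e_cpdmi,

with one independent normal random intercept per level combination of each
term — 22 estimable terms plus residual error (the person x couple
interactions are structurally void, and the four-way P x D x M x I
interaction has no replicates and is confounded with *e*). From the
estimated variance components σ²_f and the replication counts (*j* items,
*l* moments per day, *k* days, 2 partners) GT reliability coefficients are
built at each focal level as ratios R = σ²_T / (σ²_T + σ²_E), where the
numerator collects the focal term and its interactions with the fixed
facets (items, moments), and the denominator adds the random terms varying
within the focal units, each divided by the number of replications averaged
over. Moments and items are treated as fixed, days as random. The package
also decomposes scale scores into the four levels by sequential centering
and computes level-specific scale intercorrelations.

Intended users: researchers running intensive longitudinal (dyadic or
individual) studies who need psychometrics for their state scales.

## What is in the package

* `read_esm_csv()`, `esm_dataset()`, `validate_esm()` — long-format survey
  tables (one row per response) with structural validation.
* `reverse_code()`, `zstandardize_items()`, `compute_scale_scores()` —
  preprocessing exactly as scale scores are formed in practice.
* `esm_facets()`, `enumerate_terms()` — the estimable term set of a
  declared facet design (22 terms for couples; P, D, I, PD, PI, DI for a
  non-dyadic daily design).
* `fit_components()` — ML (default) or REML estimation; an exact
  stratum-likelihood engine for complete balanced designs and an
  [lme4](https://cran.r-project.org/package=lme4) engine for unbalanced
  data; `anova_balanced()` as a closed-form EMS oracle; `neg_loglik()` as a
  sparse exact likelihood kernel; broom-style `tidy()`/`glance()`.
* `reliability_dyadic()`, `reliability_nondyadic()`, `reliability_table()`,
  `build_reliability_spec()`, `effective_replications()`,
  `reliability_bounds()` — the four-level coefficients, their generic
  term/divisor construction, effective replication counts under
  missingness, and rounding-sensitivity intervals for plug-in inputs.
* `center_to_levels()`, `correlate_at_levels()` — four-level score
  decomposition and level-specific Pearson correlations.
* `simulate_esm()`, `simulate_esm_bivariate()`, `sim_spec()` — a simulator
  drawing every term's effects with known variances, optional latent
  between-scale correlations per level, and survey-level missingness.
* `esm_reference_components()` and friends — published variance tables of
  five motivation/relationship scales from two couple studies, for the
  plug-in reliability path (raw data of those studies are restricted).
* `cmd_simulate()`, `cmd_decompose()`, `cmd_reliability()`,
  `cmd_correlate()` plus a thin CLI (`inst/cli/esmrel`) and YAML/JSON
  configs.

## Worked example

Simulate a 50-couple study (14 days, 4 surveys per day, 3 items) with
known variance components, refit the model, and read off the four
reliabilities:

```r
library(esmrel)

spec <- sim_spec(n_couples = 50, n_days = 14, n_moments = 4, n_items = 3,
                 sigma2 = c(C = .16, P = .11, PD = .07, PDM = .12, PI = .13),
                 sigma2_e = .24, missing_rate = 0, seed = 2026)
d   <- simulate_esm(spec)
fit <- fit_components(d)       # exact stratum likelihood: design is balanced
fit
#> <esm_vc: ML (strata engine), 22 terms + residual, n = 16800>
#>   mu = 0.0031  sigma2_e = 0.2416  -2logL = 31164.25  converged: TRUE
#>   nonzero components:
#>  term sigma2 n_groups boundary
#>     C  0.138       50    FALSE
#>     P  0.124      100    FALSE
#>    PD  0.068     1400    FALSE
#>    PI  0.107      300    FALSE
#>   PDM  0.120     5600    FALSE
#>   ...

reps <- effective_replications(d, scale_def("scale_1", paste0("i", 1:3)))
reliability_table(fit, reps)
#> # A tibble: 4 x 2
#>   level reliability
#> 1 BC          0.623
#> 2 BP          0.950
#> 3 WPD         0.829
#> 4 WPM         0.599
```

The couple-level coefficient (`BC`, 0.62) is the reliability of the grand
mean of all of a couple's responses; `BP` (0.95) of a person's study-long
mean; `WPD` (0.83) of day-level deviations from the person mean (averaging
the day's 4 surveys and 3 items); `WPM` (0.60) of single-survey deviations
from the person-day mean (averaging only the 3 items). The estimates sit
close to the generating values (e.g. person-day-moment variance 0.120 vs.
a generating 0.12), and the reliabilities follow the usual GT pattern:
more averaging, higher reliability.

Reliabilities can also be computed without raw data, directly from a
published variance table:

```r
library(dplyr)
comp <- filter(esm_reference_components(), sample == "S1", scale == "communal")
des  <- filter(esm_reference_design(),     sample == "S1", scale == "communal")
reliability_dyadic(comp, replication_counts(j = des$j, k = des$k, l = des$l_eff), "BC")
#> [1] 0.4938497   # reported for that scale: .50
```

## Notes

* The methods vignette (`vignettes/gt-esm-reliability.Rmd`) documents the
  model, its assumptions, the formula-construction rules, numerical
  choices, and known limitations.
* Partners are treated as indistinguishable; negative within-couple
  dependence is outside the model and triggers a diagnostic warning.
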