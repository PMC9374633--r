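---
title: "Generalizability-theory reliability for dyadic experience sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizability-theory reliability for dyadic experience sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmrel)
library(dplyr)
```

## The measurement model

An experience-sampling study of couples produces item responses indexed by
couple *c*, person *p* (nested in couple), day *d*, moment *m* (the
scheduled survey slot within a day, crossed with days), and item *i*.
`esmrel` models each response as an additive sum of independent normal
random intercepts, one per level combination of every estimable facet
subset, plus residual error:

$$Y_{cpdmi} = \mu + \sum_{f \in \mathcal{T}} u_{f,\,g_f(c,p,d,m,i)} + e_{cpdmi},
\qquad u_f \sim N(0, \sigma^2_f),\; e \sim N(0, \sigma^2_e).$$

The term set $\mathcal{T}$ contains all non-empty subsets of
$\{C, P, D, M, I\}$ except (i) subsets containing both a nested facet and
one of its ancestors — persons belong to exactly one couple, so no
couple-by-person interaction can exist — and (ii) the maximal subset
(*PDMI*), whose groups contain a single observation each in a
one-observation-per-cell design and which is therefore confounded with the
residual. Twenty-two terms remain ($2^5 - 1 - 8 - 1 = 22$). The same rules
generate related designs: a non-dyadic daily diary (facets P, D, I) yields
P, D, I, PD, PI, DI plus residual, with *PDI* absorbed into the error.

Assumptions inherited from this model class: effects and errors are
mutually independent (no autoregressive carry-over between consecutive
surveys, no partner covariance beyond the shared couple intercepts),
variances are homogeneous across units, and items load equally on the
state being measured. Section "Limitations" returns to these.

Subscripts are aligned, not calendrical: `day` counts study days since the
couple's start and `moment` counts the within-day survey slot, identical
for both partners. Partners are indistinguishable; no role or gender
factor is consumed, so systematic gender variance is absorbed by the
person terms.

## Preprocessing

Scales are declared as item sets (`scale_def()`). Reverse-keyed items are
recoded as $min + max - y$ *before* standardization, so signs agree with
the scale's orientation. Each item is then z-standardized across **all**
of its observations (both partners, all days and moments), with the
sample standard deviation (denominator $n-1$); this puts items with
different response formats on a common metric and is exactly how practice
forms scale scores from heterogeneous items. Scale scores are the mean of
the available standardized items of a survey — partially answered surveys
contribute the items they have (item-level "listwise" handling: every
observed item row enters the variance model).

## Estimation

`fit_components()` maximizes the Gaussian likelihood over $\mu$ and the 23
variances, on the log scale (floor $10^{-10}$), so estimates are never
negative; estimates below $10^{-6}$ are reported as boundary zeros.
Maximum likelihood is the default — in these heavily crossed designs it is
less sensitive to starting values than REML — and REML is available, both
for small samples and because on balanced data it reproduces the classical
ANOVA estimator, which is the package's estimation oracle.

Two engines stand behind the same interface:

* **Stratum likelihood (balanced complete designs).** A balanced
  crossed/nested design has an orthogonal block structure: the
  observation space splits into ANOVA strata (one per term, plus the
  residual and the grand-mean direction), each stratum is an eigenspace of
  the marginal covariance, and its eigenvalue is
  $\lambda_S = \sigma^2_e + \sum_{T \supseteq S} c_T\,\sigma^2_T$ with
  $c_T$ the number of observations per group of $T$ (containment taken on
  nesting closures, so person terms contribute to the couple stratum).
  The $-2\log L$ becomes
  $N\log 2\pi + \log\lambda_0 + \sum_S \left[df_S \log\lambda_S +
  SS_S/\lambda_S\right]$, with all sums of squares computed once by
  Möbius inversion over group totals. The 23-parameter optimization
  (`nlminb` with analytic gradients) then costs seconds even for tens of
  thousands of rows, and the value is the *exact* likelihood (verified in
  the test suite against a dense-covariance evaluation at machine
  precision). Starting values are truncated method-of-moments solutions
  of the expected-mean-squares equations; convergence requires a relative
  $-2\log L$ change below `tol` (default $10^{-8}$).
* **Mixed-model engine (unbalanced data).** With missing surveys the
  orthogonality is lost and the model is fitted by `lme4::lmer()` with
  one scalar random intercept per term, ML or REML — the standard tool
  for crossed random effects, and the one the original analyses of such
  data use. Fits with 22 crossed terms are practical at small-to-moderate
  sizes; at large scale the balanced engine or complete subsets are
  preferable.

`neg_loglik()` evaluates the exact $-2\log L$ for any data and components
through the Woodbury identity with one sparse Cholesky factorization —
the $n \times n$ covariance is never formed. It serves as an audit kernel
and as the bridge that proves the stratum form exact. `anova_balanced()`
solves the EMS equations in closed form on balanced data (negative
solutions reported raw and truncated); on balanced data with an interior
optimum REML and EMS agree to $10^{-4}$, a classical identity the
acceptance tests assert.

The model carries no partner covariance beyond the shared couple
intercepts. Positive within-couple dependence is representable (it moves
variance to the couple level); negative dependence is not, and biases the
decomposition. `fit_components()` therefore checks the within-couple
correlation of person means post hoc and warns when it is below $-0.1$
with at least 8 couples (the threshold keeps tiny toy datasets from
raising spurious alarms).

## Reliability construction

Reliability at a focal level is the GT ratio $R = \sigma^2_T / (\sigma^2_T
+ \sigma^2_E)$. `build_reliability_spec()` constructs numerator and
denominator generically:

* Moments and items are *fixed* facets (the scheduled slots and the item
  set are the universe of interest), days are *random*. Purely fixed
  terms — $\sigma^2_M$, $\sigma^2_I$, $\sigma^2_{MI}$ — never enter any
  coefficient; this is enforced structurally, not numerically.
* The **numerator** collects the focal term and its interactions with
  fixed facets (e.g. for the person level: $P$, $PI/j$, $PM/l$,
  $PMI/(lj)$): idiosyncratic but stable item or moment effects are true
  score at that level.
* The **denominator** adds the random terms that vary within the focal
  units: at couple level every remaining non-fixed term; at person level
  the couple-free ones; at person-day level the day family ($D$, $DM/l$,
  $DI/j$, $DMI/(lj)$); at moment level nothing but error. Every term is
  divided by the replication counts of its facets outside the focal
  unit's closure — $k$ days, $l$ moments, $j$ items, and the constant 2
  partners at couple level — and the error by all of them.

The four dyadic coefficients this yields (R_BC, R_BP, R_WPD, R_WPM) are
asserted term-for-term against hand-written versions of the formulas in a
regression test, and the non-dyadic person- and day-level formulas arise
from the reduced term set with the same rules.

One asymmetry is inherited deliberately from the formulas as they are
used in this literature: couple-shared time terms ($CD$ family) are
treated as couple-level and excluded from the person- and day-level
denominators although they vary within persons across days, and likewise
the day-moment family is excluded at the moment level. The builder
reproduces this printed structure; it does not invent corrected variants.

**Replication counts.** With skipped surveys the scheduled counts
overstate the averaging. `effective_replications()` uses: $l_{eff}$ =
answered surveys / (persons × declared days) — the response rate times
the scheduled moments; $k_{eff}$ = mean days with at least one answered
survey per person; $j_{eff}$ = mean items answered per answered survey.
Scheduled counts are available behind a flag for sensitivity analysis
(the choice moves day-level reliability at the second decimal). The
partner replication is the constant 2, never an effective value — the
formulas average exactly two persons.

## The plug-in path and rounding sensitivity

Because the variance table is all the reliability formulas need,
coefficients can be recomputed from *published* component tables.
`esm_reference_components()` ships the variance decompositions of five
scales (state relationship satisfaction, independence, power, agency and
communal motivation) from two couple studies whose raw data are
restricted, together with the design constants
(`esm_reference_design()`) and the reliabilities reported for them
(`esm_reference_reliabilities()`). Plugging the printed components into
the formulas — scheduled $j$, study days $k$, effective $l$ — reproduces
the reported coefficients to about two decimals across the forty
scale-by-level cells.

Printed tables are rounded, so exact agreement is not attainable —
and for some cells not even two-decimal agreement is guaranteed.
`reliability_bounds()` quantifies this: each printed cell is an interval
of half-width 0.005 (blank cells: $[0, 0.005)$), the coefficient is
monotone in every component, so interval propagation gives exact
attainable bounds. Most cells are pinned to within ±0.01–0.02. The
day-level coefficient of the pooled agency scale is the instructive
exception: its numerator is small and the day-family blanks enter the
denominator undivided, giving a propagated half-width near 0.06 — the
printed inputs simply underdetermine that cell, and the plug-in value
deviates from the reported one by 0.03 while remaining well inside the
propagated interval. The acceptance suite therefore asserts two-decimal
reproduction only where the propagated half-width is at most 0.02, and
interval containment everywhere. Small cells (≤ 0.01) of the published
tables whose column attribution is typographically ambiguous are recorded
as zero in the shipped data; each enters the formulas only through
divisors of at least the moment count, bounding their effect on any
coefficient below 0.01 (their effect on the relative variance *shares* is
larger, up to about one percentage point).

## Level scores and intercorrelations

`center_to_levels()` decomposes per-survey scale scores hierarchically:
couple scores are means over all observed surveys of both partners;
person scores are person means of couple-centered residuals; person-day
scores are day means after couple and person centering; moment scores are
the remainder. The four components reconstruct each raw score exactly by
construction, and with complete data the residuals average to zero within
their parent units (asserted at $10^{-10}$ in the tests; under
missingness the means are over observed values and these sums are only
approximately zero). `correlate_at_levels()` computes Pearson
correlations pooling all units of a level as rows ("computed across the
full sample"), with pairwise-complete deletion — scales may cover
different surveys — and no disattenuation: the level-specific
correlations inherit the attenuation implied by the level-specific
reliabilities, which is material at the moment level.

## The simulator

`simulate_esm()` draws every term's effects once per group — shared terms
(day, moment, their interactions with items) are drawn once and reused
across all persons, which is precisely what makes them shared — composes
them additively with residual noise, and deletes whole surveys completely
at random (item-level missingness is a separate option emulating partial
surveys). `simulate_esm_bivariate()` draws the couple, person,
person-day and person-day-moment effects of two scales from bivariate
normals with declared correlations and everything else independently, so
level-specific correlation recovery can be tested against analytic
attenuation factors computed from the generating variances. Defaults
mirror a two-week couple study: 65 couples, 14 days, 5 moments, a
four-item scale with communal-motivation-like components in z-score
units, and a 17% survey missing rate. Generation is fully reproducible
(Mersenne–Twister, inversion normals; the generator is recorded in the
serialized spec).

What the simulator does *not* emulate — and hence what passing tests do
not establish about real data: autoregressive dependence between
consecutive surveys, informative (non-MCAR) missingness, unequal item
loadings or response-style heterogeneity, floor/ceiling effects of rating
scales, and negative dyadic covariance. These are exactly the model's own
assumption violations; simulation-based checks validate the estimator
under the model, not the model against nature.

## Problem sizes and numerical choices

The test and acceptance suites use sizes chosen to make Monte-Carlo noise
small relative to the tolerances they assert: the parameter-recovery
study runs 20 replicates of 50 couples × 14 days × 4 moments × 3 items
(16,800 responses each; mean estimates within ±0.02 of the generating
components, implied reliabilities within ±0.03); the estimator-oracle
check runs ten 8 × 6 × 4 balanced crossed replicates (REML vs. EMS within
$10^{-4}$ on interior solutions); bivariate correlation recovery uses 250
couples; partners' centered person scores are mirror images, so couples
are the effective sampling units and a person-level correlation carries a
sampling error near 0.06, inside the ±0.07 recovery band asserted at the
fixed simulation seed. Unbalanced mixed-model fits in the
tests stay at toy sizes, where `lmer` with 22 crossed terms runs in
seconds.

Other numerical choices: term labels and orderings are canonical
(C, P, D, M, I), so reports align across functions; group indices are
assigned by sorted level keys and are invariant to row order; convergence
requires relative $-2\log L$ change below $10^{-8}$ with an iteration cap
of 500; reported tables round to 2 decimals in CSV while JSON keeps full
precision.

## Limitations

Exact third-decimal agreement with any particular historical fit is not
claimable: optimizer settings and starting values of other software are
not reproduced here, and boundary estimates make the likelihood surface
flat in several directions. The model's independence and equal-loading
assumptions are idealizations; violation (autocorrelation, unequal
loadings) biases reliabilities — typically downward for unequal
loadings. Negative within-couple covariance is flagged but not modeled.
Designs with more than one nesting level, rotating day panels, or
distinguishable partners are out of scope.
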