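---
title: "Measurement and sampling uncertainty of diagnostic accuracy measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement and sampling uncertainty of diagnostic accuracy measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaguncert)
```

## The model

A quantitative screening or diagnostic test measures a measurand whose
values (possibly after a log or other normalizing transform) are assumed
normally distributed in each of two populations: non-diseased, with mean
$\mu_{\bar D}$ and standard deviation $\sigma_{\bar D}$, and diseased,
with $\mu_D$ and $\sigma_D$. A subject whose measurement exceeds the
diagnostic threshold $d$ is classified test-positive; a measurement at or
below $d$ is test-negative. A gold-standard reference method is assumed to
classify disease status without error, and sampling is simple random.

Under this binormal model the two conditional classification probabilities
have closed forms,

$$Se = P(X_D > d) = \Phi\!\left(\frac{\mu_D - d}{\sigma_D}\right), \qquad
  Sp = P(X_{\bar D} \le d) = \Phi\!\left(\frac{d - \mu_{\bar D}}
  {\sigma_{\bar D}}\right),$$

and the remaining nine accuracy measures are algebraic functions of
$(Se, Sp)$ and, for the prevalence-dependent ones, of the prevalence rate
$r$: the predictive values $PPV$ and $NPV$, overall diagnostic accuracy
$ODA = r\,Se + (1-r)\,Sp$, the diagnostic odds ratio
$DOR = Se\,Sp / ((1-Se)(1-Sp))$, the likelihood ratios
$LR^+ = Se/(1-Sp)$ and $LR^- = (1-Se)/Sp$, Youden's index
$J = Se + Sp - 1$, the Euclidean distance of $(Se, Sp)$ from the perfect
corner $ED = \sqrt{(1-Se)^2 + (1-Sp)^2}$, and the concordance probability
$CZ = Se\,Sp$. `all_measures()` evaluates all eleven;
`dams_from_counts()` computes the same measures as natural frequencies
from a 2x2 contingency table.

Two precision choices matter here. First, the tail probabilities and
their complements are evaluated directly with upper- and lower-tail
normal probabilities rather than as `1 - pnorm(z)`, so that quantities
like $1 - Se$ keep full relative precision even at $|z| > 6$; without
this, the diagnostic odds ratio and its gradient lose all significant
digits long before the probabilities themselves underflow. Second, the
point estimates treat the observed sample mean and SD as plug-in values
for the population parameters: the measurement uncertainty does not
broaden the distributions used for the point value, because in the
uncertainty budget below it attaches to the uncertainty *of the
estimates*, not to the measurand distribution itself.

## The uncertainty budget

Each input estimate carries a standard uncertainty:

* sampling uncertainty of a sample mean, $u_s(m_P) = s_P/\sqrt{n_P}$,
  and of a sample SD, $u_s(s_P) = s_P/\sqrt{2(n_P - 1)}$;
* standard measurement uncertainty $u_m$ of the test (estimated from
  $n_u$ measurements; bias, where relevant, is folded into $u_m$ by the
  caller), combined with the sampling parts in quadrature,
  $u_c(m_P) = \sqrt{s_P^2/n_P + u_m^2}$ and
  $u_c(s_P) = \sqrt{s_P^2/(2(n_P-1)) + u_m^2}$;
* sampling uncertainty of the prevalence rate by the Agresti–Coull
  adjusted-Wald standard error,
  $u_s(r) = \sqrt{(2+n_{\bar D})(2+n_D)/(4+n_{\bar D}+n_D)^3}$.

`propagate()` carries these to any measure $x$ by the first-order
(delta-method) rule $u_i(x) = |\partial x/\partial\theta_i|\,u(\theta_i)$
over the five inputs $(\mu_D, \sigma_D, \mu_{\bar D}, \sigma_{\bar D},
r)$, treated as mutually independent, and combines the components in
quadrature. The components are grouped into two budgets — the four
location/scale inputs with their sampling uncertainties plus the
prevalence (the *sampling* budget), and the same four inputs each with
uncertainty $u_m$ (the *measurement* budget) — so that
$u_c^2 = u_{meas}^2 + u_{samp}^2$ holds by construction. Gradients are
analytic throughout (normal-density chain rule for $Se$ and $Sp$, closed
forms for the algebraic layer); `numeric_gradient()` provides an
independent central-difference check with relative step
$10^{-6}\max(|\theta|, 1)$.

Effective degrees of freedom come from the Welch–Satterthwaite formula
$\nu_{eff} = u_c^4 / \sum_i u_i^4/\nu_i$, which always lies between the
smallest component df and the sum of all component dfs. The published
budget does not state the df of each component; this package assigns the
conventional values — $n_P - 1$ to the sampling components of $m_P$ and
$s_P$, $n_u - 1$ to each measurement component, and
$n_D + n_{\bar D} - 1$ to the prevalence component — and records them in
the per-component table of every `propagate()` result so that
alternatives are auditable. $\nu_{eff}$ is used as-is (non-integer) in
Student-$t$ quantiles: the expanded uncertainty at confidence level $p$
is $\pm t_{(1+p)/2,\nu_{eff}}\, u_c$, and the confidence interval adds
those offsets to the point estimate, clipped to the measure's admissible
range ($[0,1]$ for probability-type measures, $[0,\infty)$ for $DOR$,
$LR^\pm$ and $ED$, $[-1,1]$ for $J$) with per-bound flags.

The threshold $d$ and the confidence level $p$ are decision parameters
and carry no uncertainty. The possible correlation of the $u_m$
contributions across the two populations (same instrument measures both
samples) is not modelled: the components enter as plain quadrature, and
at the reference example below the independent treatment reproduces all
published behaviour.

## Degenerate inputs and tie-breaks

A measure like $DOR$ is unbounded when $Se$ or $Sp$ reaches 1. Such
values are returned as `Inf` with an explicit `"unbounded"` flag (0/0
forms are `"undefined"`), never as a silent `NaN`, and `propagate()`
returns a flagged breakdown with `NA` uncertainty fields instead of
raising — so sweep tables stay rectangular. In double precision there is
also a narrow band where the measure itself is still representable but
its gradient overflows (for example $DOR \sim 10^{190}$); those cells
are flagged `"undefined"` for the same reason. A simulated measurement
exactly equal to the threshold is classified test-negative, which is
irrelevant for the continuous model but binding when tabulating
simulated data. Relative uncertainties at $|x| < 10^{-12}$ are reported
as `NA` with an `"undefined-relative"` flag rather than infinities.

## The reference example

The built-in `glucose_example()` encodes an oral glucose tolerance test
survey of 2667 Malay adults (179 diabetic, 2488 non-diabetic).
Quantities are standardized log-transformed glucose, in units of the
non-diseased sample's SD: $\mu_{\bar D} = 0$, $\sigma_{\bar D} = 1$,
$\mu_D = 2.99$, $\sigma_D = 0.75$, $u_m = 0.046$ (from $n_u = 80$
measurements; this folds a 2% CV into the standardized scale — the
mapping from the instrument's raw CV and bias is taken as given, not
re-derived), threshold $d = 2.26$ (the standardized ADA 2-h cutoff) and
$p = 0.95$.

```{r example}
s <- glucose_example()
print(calculator_tables(s)$relative, digits = 4)
```

Three regimes are visible in the relative combined uncertainties:
below 0.5% for $Sp$, $ODA$ and $NPV$; between 3.5% and 5.5% for $Se$,
$PPV$, $J$ and $CZ$; and between 18% and 39% for $DOR$, $LR^\pm$ and
$ED$. The measurement budget dominates the sampling budget for $Sp$,
$ODA$, $PPV$, $DOR$ and $LR^+$. The acceptance test suite asserts
exactly these statements.

## Sweeps and the command-line interface

`sweep_threshold()`, `sweep_measurement_uncertainty()` and
`sweep_sample_size()` recompute the full breakdown along one axis with
everything else fixed; each grid point is an independent evaluation
identical to the single-point calculator (a property the tests assert),
and the sample-size sweep splits each total $n$ as
$n_D = \max(2, \mathrm{round}(r\,n))$ with the complement floored at 2 —
rounding was chosen because round(0.067 x 2667) recovers the example's
(179, 2488) split exactly. Default grids use 101 points on continuous
axes and a log-spaced integer grid for $n$. `calculator_tables()`
produces the three standard tables (absolute, relative-percent, CI).
The `inst/cli/diaguncert` script exposes `calc`, `relative`, `ci`,
`sweep`, `validate` and `example` subcommands over a YAML configuration
(the population size key is `size`, not `n`, because YAML 1.1 readers
interpret a bare `n` as a boolean); tables are written as CSV or JSON
with full-precision columns plus 4-significant-digit display twins, and
fractions become percentages only at the rendering layer.

## Stochastic validation and its limits

Two independent stochastic checks back the analytic chain.

`mc_propagate()` perturbs the five summary parameters with their
component uncertainties (SDs drawn non-positive are rejected and
redrawn; prevalence draws are clipped to $(10^{-6}, 1-10^{-6})$) and
estimates the combined uncertainty as the Monte-Carlo SD of the
recomputed measure. Agreement with the first-order value is a statement
about the validity region of the Taylor approximation: with input
relative uncertainties around 0.5% (population sizes of 20 000 and
$u_m \le 0.01$) every measure agrees within 5% at $10^5$ draws, whereas
at survey-scale inputs the curvature of $DOR$, $LR^+$ and $PPV$ already
contributes several percent of second-order spread. The tests pin the
5% bound in the small-uncertainty regime and treat the graceful
degradation outside it as documented behaviour, not an error.

`mc_ci_coverage()` is a parametric bootstrap of the whole estimation
chain: raw samples are simulated (each measurement perturbed by
independent $N(0, u_m)$ error), the summary statistics re-estimated, the
confidence interval recomputed, and the fraction covering the generating
value reported. At a reduced nominal level with a sampling-dominated
budget the empirical coverage tracks the nominal one. At the glucose
example, however, the intervals *overcover* (about 0.98 for $Se$ and
essentially 1.00 for $Sp$ at nominal 0.95, 500 replicates): i.i.d.
per-measurement error largely averages out of a sample mean
(contributing $u_m/\sqrt{n}$, not $u_m$), while the GUM-style budget
adds $u_m$ in full to the uncertainty of both the mean and the SD
estimate, treating it as a study-level systematic component that
resampling cannot reproduce. No raw-data generating mechanism is
consistent with both combined-uncertainty formulas at once (a shared
per-study offset recovers the mean's budget but not the SD's), so
conservative coverage for measurement-dominated measures is a structural
property of this uncertainty model, not an implementation artifact. The
acceptance suite states the nominal-coverage check at the reference
example and reports this expected failure rather than weakening it.

The synthetic-data generator `random_scenario()` draws non-degenerate
scenarios with standardized separation in $[0.5, 5]$, SD ratios in
$[0.3, 3]$, sample sizes log-uniform in $[30, 5000]$, $u_m/\sigma_{\bar
D}$ in $[0, 0.15]$ and the threshold strictly between the two means —
ranges that bracket realistic screening settings and exercise both
measurement-dominated and sampling-dominated budgets. What it does not
emulate: non-normal measurands, heteroscedastic measurement error,
imperfect gold standards, or correlated measurement effects; passing
property tests therefore validate the propagation algebra under the
model's assumptions, not those assumptions themselves.

## Problem sizes used by the test suite

Property tests run the full propagation over 1000 generated scenarios,
gradient cross-checks over 200, Monte-Carlo agreement at 20 scenarios
with $10^5$ draws each, and bootstrap coverage with 500 replicates of
the 2667-subject example; the complete suite and the acceptance script
each run in a few minutes on a single core.

## Known limitations

First-order propagation only (no higher-order Taylor terms); the
adjusted-Wald prevalence uncertainty rather than exact binomial
intervals; homoscedastic measurement uncertainty; no modelling of
correlation between the two populations' measurement components; and the
binormal, gold-standard, simple-random-sampling assumptions above.
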