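---
title: "Growth dynamics of screen-detected lung nodules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth dynamics of screen-detected lung nodules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulegrowth)
```

## The growth model and its assumptions

Nodule volume is assumed to follow the von Bertalanffy scaling law

$$\frac{dV}{dt} = \alpha V^{\beta},$$

with analytic solution $V(t)^{1-\beta} = V_0^{1-\beta} + (1-\beta)\alpha t$
for $\beta \ne 1$ and $V(t) = V_0 e^{\alpha t}$ at $\beta = 1$. The model
assumes growth is smooth and monotone over the observation window and that
measurement error is multiplicative (segmentation error scales with lesion
size), which is why all least-squares objectives and the perturbation
analysis work on log-volumes. The exponent $\beta$ is dimensionless; the
coefficient $\alpha$ carries units $\mathrm{mm}^{3(1-\beta)}/\mathrm{month}$
and is therefore comparable between nodules only through derived,
unit-stable quantities such as the doubling time. For $\beta > 1$ the
solution reaches infinite volume at the finite blow-up time
$t^* = V_0^{1-\beta}/((\beta-1)\alpha)$; `vb_solve_forward()` refuses times
at or beyond $t^*$, and fitted accelerated trajectories always place the
observed scans strictly below it.

Fitted exponents are binned into five growth patterns with upper-inclusive
boundaries: decelerated ($\beta \le -0.1$), linear ($-0.1 < \beta \le 0.1$),
subexponential ($0.1 < \beta \le 0.9$), exponential ($0.9 < \beta \le 1.1$),
accelerated ($\beta > 1.1$). The bins partition the real line, so every
finite exponent maps to exactly one category. The $\pm 0.1$-wide bands
around 0 and 1 acknowledge that an estimated exponent is never exactly 0
or 1; "linear" and "exponential" are read as neighbourhoods of those
idealized dynamics.

## Fitting

**Three scans (the default).** With three strictly increasing volumes the
pair $(\alpha, \beta)$ is exactly identified. Writing $c = 1-\beta$,
$a_i = \ln(V_i/V_0)$ and re-basing times to $t_0 = 0$, the solution
passes through all three points iff

$$g(c) = \frac{e^{c a_1} - 1}{e^{c a_2} - 1} = \frac{t_1}{t_2}.$$

For increasing data $g$ is strictly decreasing from 1 to 0 while
$t_1/t_2 \in (0,1)$, so the root — hence $\beta$ — is unique. The solver
uses `uniroot()` on `expm1` forms (the $c \to 0$ limit $a_1/a_2$ is the
exponential branch) at tolerance `.Machine$double.eps^0.75`, recovering
forward-solved parameters to better than $10^{-6}$ across
$\beta \in [-3, 3]$. The default search bracket is $\beta \in [-10, 10]$;
a root outside it raises a convergence error rather than clamping, because
a silently clamped exponent would corrupt the downstream category table.
Exponents within $10^{-8}$ of 1 switch to the exponential closed form to
avoid catastrophic cancellation.

**Longer series.** `vb_fit_ls()` minimizes the sum of squared log-volume
residuals over $(\alpha, \beta)$ with $V_0$ fixed at the baseline
measurement, started from the exact fit on the first, middle and last
points and refined with `nlminb` (relative tolerance $10^{-15}$). `nlminb`
reports "false convergence" when started at or driven to the optimum; the
implementation restarts once from the returned parameters and accepts the
solution if the restart cannot improve it. A three-point series returns
the exact fit. Which scans to fit when more than three exist is a genuine
design choice; the default pipeline fits the first three (matching the
$(V_0, V_1, V_2)$ parameterisation of all derived quantities), with the
all-scan least-squares fit available via `fit_method = "least_squares"`.

## Rates, doubling times, and attenuation features

For scans $i \to f$ separated by $\Delta t$ months:
$\nu_{if} = (V_f - V_i)/\Delta t$ (mm³/month) and
$\lambda_{if} = (\ln V_f - \ln V_i)/\Delta t$ (month⁻¹). The logarithm is
natural, so that $\mathrm{VDT} = \ln 2 / \lambda$ is exact. Three-point
variants are ordinary least-squares slopes of $V$ (resp. $\ln V$) against
time. Two doubling times are computed: the modified Schwartz estimate
$\mathrm{VDT}_{\exp} = \ln 2/\lambda_{01}$ (exponential growth assumed
from the first interval) and the scaling-law estimate

$$\mathrm{VDT}_{\beta} =
  \frac{(2V_0)^{1-\beta} - V_0^{1-\beta}}{(1-\beta)\,\alpha},$$

evaluated in the cancellation-free form
$V_0^{c}\,\mathrm{expm1}(c \ln 2)/(c\alpha)$ with $c = 1-\beta$. Exponents
within $1.5\times10^{-6}$ of 1 take the limit $\ln 2/\alpha$ directly:
near $\beta = 1$ the $V_0^{c}$ factor makes the exact formula deviate from
the limit by a few parts in $10^6$ (about $5\times10^{-6}$ relative at
$V_0 = 100$, $|c| = 10^{-6}$), so a branch this wide keeps the function
numerically continuous across the exponential point at the $10^{-6}$
level. Shrinking nodules produce signed (negative) rates and doubling
times and a zero rate produces `Inf`, rather than errors, so a mixed
cohort flows through the evaluation stage. Attenuation features are the
baseline mean HU and the lesion "mass" $V_0 \cdot \mathrm{HU}_0$; missing
attenuation yields missing features, never zeros. Doubling times are
reported in months; `months_to_days()` converts at 30.4375 days/month.

## Sensitivity of the exponent to volumetry error

Segmentation error is emulated as independent multiplicative noise:
each of the three volumes is multiplied by $1 + u$,
$u \sim \mathrm{Uniform}(-\varepsilon, +\varepsilon)$ with
$\varepsilon = 0.05$ by default. A bounded error range is read literally
as a uniform distribution; all three volumes are perturbed, including the
baseline. Each of the 200 replicates is refitted with the exact
three-point solver; replicates whose perturbed volumes are no longer
strictly increasing (or whose fit fails) are dropped from the median and
counted in `n_failed` — redrawing them would bias the distribution toward
easy configurations. The nodule is declared robust when
$|\mathrm{median}(\beta^*) - \beta| < 0.5$. The procedure is fully
reproducible from its seed. Flat trajectories are the informative failure
mode: a nodule growing 100→101→102 mm³ has log-increments comparable to
the noise itself, so its refitted exponents spread over orders of
magnitude more than a clearly growing nodule's.

## Benign-versus-malignant evaluation

Every candidate feature is evaluated as a univariate classifier by
ROC/AUC (via pROC), where the AUC equals the tie-aware concordance
probability $P(s_{\mathrm{mal}} > s_{\mathrm{ben}}) +
\tfrac12 P(\mathrm{equal})$. The scoring direction is chosen so the
reported AUC is always $\ge 0.5$ and is recorded explicitly
(`higher_is_malignant` / `lower_is_malignant`); relabelling flips the
direction, never the AUC. Operating points maximize the Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$, with ties broken toward higher
specificity — in a screening population false positives carry the larger
cost (work-up of benign disease), so among equally informative cut-points
the conservative one is reported.

The multivariable score is a binomial GLM (logit link) on the candidate
set, with CT morphology entering as two indicator terms (solid as
reference), followed by backward elimination of the term with the largest
Wald p-value until all remaining terms have $p \le$ `p_stay` (0.05 by
default; `p_stay = 1` forces entry of every candidate). A binary
benign/malignant outcome with no event times calls for logistic
regression rather than a hazard-type model; the stepwise-Wald elimination
retains the spirit of classical stepwise model building. Complete
separation (vanishing residual deviance or IRLS non-convergence — the
glm warning alone proved an unreliable signal) falls back to a weakly
ridge-penalized fit, flagged `penalized`, without elimination, since Wald
statistics are undefined there. Evaluation is in-sample by default,
mirroring how such models are typically reported at this cohort size;
the score's AUC is therefore optimistic and should be read comparatively.

Group comparisons are always rank-based (Kruskal–Wallis, with
Holm-adjusted pairwise Wilcoxon tests beyond two groups); Holm is chosen
over Bonferroni as uniformly more powerful without an independence
assumption. The Kolmogorov–Smirnov normality screen is a descriptive
report only and never switches the pipeline to parametric tests.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical skeleton of a screening cohort
of 180 nodules (40 benign, 140 malignant):

* **Growth-pattern mixtures** — benign 20/0/8/1/11 and malignant
  37/1/13/6/83 across the five categories; exponents are drawn uniformly
  within each category's interval, offset $10^{-3}$ from the bin
  boundaries so that a refit accurate to $10^{-6}$ can never flip a
  category.
* **Baseline volumes** — log-normal per group, calibrated to median (IQR)
  103.5 (49.5–414.3) mm³ (benign) and 179.3 (64.3–527.2) mm³ (malignant)
  by least squares on the three log-quantiles: $\mu$ is the mean of the
  log quartiles and $\sigma = \ln(q_{75}/q_{25})/(2 z_{0.75})$. Two
  parameters cannot match three asymmetric quantiles exactly, so the
  median is matched in expectation (generated benign medians fall inside
  the printed IQR across seeds).
* **Scan schedule** — follow-up times drawn from asymmetric triangular
  distributions pinned to median (IQR) 12.2 (6.2–13.9) and 24.3
  (14.37–30.8) months, with draws redrawn until $t_2 > t_1 + 1$ month.
* **Growth magnitude** — each nodule receives a target fold change at its
  second follow-up, drawn per category (decelerated 1.2–1.8 up to
  accelerated 1.8–4.0; all > 1 since the pipeline studies growing
  nodules), and $\alpha$ is then *derived* analytically so the trajectory
  hits that fold change. This guarantees increasing, finite, blow-up-safe
  trajectories and makes the generating truth exactly recoverable — the
  basis of the noiseless round-trip test in which the fitted category
  table equals the generator's mixture exactly.
* **Attenuation** — group-level HU trajectories stable around
  (−146, −156, −131) for benign and rising around (−314, −291, −233) for
  malignant, with between-nodule heterogeneity (sd 150 HU) plus per-scan
  jitter (sd 20 HU). The large between-nodule scale matches the observed
  reality that baseline attenuation is an informative but far-from-perfect
  classifier; with per-scan jitter alone it would separate the groups
  almost perfectly.
* **Morphology** — malignant 81/28/31 solid/part-solid/non-solid; the
  benign mix is configurable and defaults to all-solid.

It does **not** emulate: true per-nodule effect sizes (the fold-change
ranges are calibration choices, so cohort-level AUCs are qualitative and
deliberately not matched to any reported values), correlation between
growth rate and baseline size or morphology, measurement attrition,
segmentation bias, or histology/stage structure (labels are carried but
uninformative). Passing tests on generated cohorts therefore validates
the *machinery* — fitting, classification thresholds, feature extraction,
evaluation bookkeeping — not clinical effect sizes.

```{r roundtrip}
cohort <- generate_cohort(cohort_spec(), seed = 11)
analysis <- run_growth_analysis(cohort, n_reps = 0)
analysis$category_table
```

## Numerical choices and degenerate inputs

* Root-finding tolerance `.Machine$double.eps^0.75`; exponent bracket
  $[-10, 10]$ with an explicit convergence error at the edge.
* $|1-\beta| < 10^{-8}$ switches forward solver and exact fitter to the
  exponential branch; the doubling-time limit branch is wider
  ($1.5\times10^{-6}$) for the continuity reason given above.
* Volumes must be strictly positive and times strictly increasing;
  duplicate (nodule, time) pairs and non-numeric fields are validation
  errors with row context, never silent drops.
* Nodules that cannot be fitted (after passing the filter with
  `require_increase = FALSE`, or under perturbation) yield `NA` rows or
  counted failures, not aborts.
* Report JSON rounds to 6 significant digits for hash-stable
  reproducibility checks; CSVs keep full precision.

## Problem sizes used by the test-suite

The suite exercises the full 180-nodule default cohort for round-trip,
evaluation and permutation checks (200 label permutations across all 16
features), 200 replicates for perturbation protocols (500 where a
monotonicity curve over the noise grid is examined), 1000 random
instances for the AUC-versus-pair-counting and root-bracketing
properties, and 200 random parameter draws for the doubling-time ODE
cross-check. These sizes make the stochastic checks stable under their
fixed seeds while keeping the default run fast on a single CPU.

## Known limitations

* Wald-based backward elimination inherits the Hauck–Donner phenomenon:
  a strongly separating covariate can receive a *large* Wald p-value and
  be eliminated. With the default all-solid benign morphology mix, the
  morphology indicators quasi-separate the groups and stepwise selection
  at `p_stay = 0.05` can empty the model; forced entry (`p_stay = 1`) is
  the appropriate setting for evaluating a pre-chosen combination.
  Likelihood-ratio-based selection would avoid this but is a different
  procedure.
* In-sample AUCs for the multivariable score are optimistic; no
  cross-validation is applied by default.
* The exact three-point fit uses only the first three scans; information
  in later scans is ignored unless the least-squares method is selected.
* The inclusion filter's "growing nodule" criterion is monotonicity over
  the first three scans plus a configurable minimum fold change
  (default 1, i.e. monotonicity only); there is no single agreed
  quantitative definition of a "noticeable" size increase, so the
  threshold is exposed as a parameter rather than hard-coded.
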