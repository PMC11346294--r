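# nodulegrowth

Growth dynamics and malignancy classification of screen-detected lung
nodules from longitudinal CT volumetry.

## The problem

Pulmonary nodules found in low-dose-CT lung cancer screening are
followed over repeated annual scans. Management guidelines implicitly
assume the nodule volume grows exponentially, and summarize growth by a
volume doubling time (VDT). Whether growth actually is exponential — and
which volumetric summary best separates benign from malignant nodules —
is an empirical question. This package implements a complete analysis
pipeline for that question, aimed at researchers working with
longitudinal nodule volumetry (scan times, segmented volumes in mm³,
mean attenuation in Hounsfield Units, CT morphology and a
benign/malignant label).

## The model

Nodule growth is modelled by the von Bertalanffy scaling law

    dV/dt = α V^β

whose analytic solution is `V(t)^(1−β) = V0^(1−β) + (1−β) α t` for
β ≠ 1 and `V(t) = V0 e^{αt}` for β = 1. The dimensionless exponent β
indexes the growth pattern:

| pattern        | exponent         |
|----------------|------------------|
| decelerated    | β ≤ −0.1         |
| linear         | −0.1 < β ≤ 0.1   |
| subexponential | 0.1 < β ≤ 0.9    |
| exponential    | 0.9 < β ≤ 1.1    |
| accelerated    | β > 1.1          |

For β > 1 the solution blows up at a finite time
`t* = V0^(1−β)/((β−1)α)`; fitted accelerated trajectories always keep
the observed scans below t*. From three scans `(V0, V1, V2)` the pair
(α, β) is identified exactly by a one-dimensional root-find; longer
series use least squares on log-volumes. Around the fit the package
computes:

* pairwise linear rates ν_if = (V_f − V_i)/Δt and exponential rates
  λ_if = (ln V_f − ln V_i)/Δt, plus their least-squares analogues;
* the modified Schwartz doubling time VDT_exp = ln2/λ₀₁ and the
  scaling-law doubling time
  VDT_β = ((2V0)^(1−β) − V0^(1−β))/((1−β)α);
* a Monte-Carlo robustness analysis of β (±5% multiplicative volume
  errors, 200 refits, criterion |median(β*) − β| < 0.5);
* ROC/AUC evaluation of every candidate discriminator, Youden operating
  points, rank-based group comparisons, and a stepwise logistic score
  combining a growth rate with CT morphology;
* a calibrated synthetic cohort generator (180 nodules by default) so
  the whole pipeline is testable without patient data.

## Worked example

```r
library(nodulegrowth)

# one nodule: baseline 103.5 mm^3, roughly doubling per year
fit <- vb_fit_exact3(times = c(0, 12, 24), volumes = c(103.5, 181.8, 400.2))
fit
#> von Bertalanffy fit (exact3, n = 3)
#>   alpha = 0.0039613  beta = 1.50307  [accelerated]
#>   RMS log-volume residual = 5.13e-16  converged = TRUE

vdt_beta(103.5, fit$alpha, fit$beta)          # 14.32 months
vdt_schwartz(exp_rate(103.5, 181.8, 12))      # 14.77 months

sensitivity_analysis(times = c(0, 12, 24),
                     volumes = c(103.5, 181.8, 400.2), seed = 7)
#> Growth-exponent sensitivity (200 reps, +/-5% errors)
#>   beta = 1.503, median(beta*) = 1.513, |deviation| = 0.01036
#>   robust (< 0.5): TRUE   failed replicates: 0
```

The fitted exponent 1.50 means faster-than-exponential (accelerated)
growth; the scaling-law doubling time (14.3 months) is slightly shorter
than the Schwartz estimate extrapolated from the first interval (14.8
months), as expected when growth accelerates. The median refitted
exponent moves by only 0.010 under ±5% volumetry errors, so the
classification of this nodule is robust to segmentation noise.

The full pipeline on a synthetic 180-nodule screening cohort:

```r
cohort <- generate_cohort(cohort_spec(), seed = 1)
report <- run_report(cohort, seed = 1,
                     multivariable = c("nu_02", "morphology"), p_stay = 1)
report
#> Inclusion filter: 180 of 180 nodule(s) retained
#>
#> Growth categories by malignancy:
#> # A tibble: 5 x 3
#>   category       benign malignant
#> 1 decelerated        20        37
#> 2 linear              0         1
#> 3 subexponential      8        13
#> 4 exponential         1         6
#> 5 accelerated        11        83
#>
#> Sensitivity: 153/180 nodules robust (|median(beta*) - beta| < 0.5)
#>
#> Per-feature discrimination (benign vs malignant):   (excerpt)
#>    feature      auc sensitivity specificity
#>  1 beta       0.662       0.614       0.725
#>  5 nu_02      0.589       0.736       0.5
#> 15 hu0        0.827       0.7         0.825
#> 16 mass0      0.708       0.607       0.75
#>
#> Multivariable malignancy score (stepwise logistic)
#>   terms: nu_02 + morphology
#>   AUC = 0.755
```

The category table reproduces the generator's mixture exactly (a
round-trip check of the fitting and classification thresholds), and
combining the two-year growth rate with CT morphology improves on the
rate alone (0.755 vs 0.589). Cohort-level AUCs depend on the
generator's effect-size choices and are qualitative; see the methods
vignette (`vignettes/growth-dynamics.Rmd`).

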