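# dicheff

Dichotomization efficiency for skew-normal covariates in randomized trials.

## The problem

Two-arm randomized trials with a continuous outcome gain precision by
adjusting for a prognostic baseline covariate in a linear model,

```
y = α + γ z + β x + ε,    ε ~ N(0, σ_ε),    x ~ SN(φ, ω, λ),
```

with `z` the arm indicator (1:1 allocation) and `x` a skew-normal (SN)
covariate — the family that fits right-skewed measurements such as BMI,
weight and lipids. In practice `x` is often dichotomized at a threshold
before entering the model, e.g. because the randomization was stratified on
the same split. That discards information: the treatment-coefficient
variance rises from the fully adjusted `V(γ̂; m_f) = 4σ_ε²/n` towards the
unadjusted `V(γ̂; m_r) = 4(σ_ε² + β²σ_x²)/n`.

`dicheff` is for trial statisticians who need to know how much of the
adjustment benefit survives a dichotomization at percentile `τ`, and where
to put the threshold if a split is unavoidable. The core quantity is the
**dichotomization efficiency**

```
D = [V(γ̂;m_r) − V(γ̂;m_p)] / [V(γ̂;m_r) − V(γ̂;m_f)] = V(x_d) / σ_x²,
```

the retained fraction of the precision gain, where `x_d` replaces the
covariate by its conditional mean below/above the threshold and `m_p` is
the model with the dichotomized covariate. `D` is a closed-form function of
the shape `λ` and the percentile `τ` alone (location and scale cancel),
built from the skew-normal truncated means and Owen's T function.

The package provides: a self-contained SN kernel (`sn_pdf`, `sn_cdf`,
`sn_quantile`, moments, truncated means, sampling), the closed-form model
variances and `dichotomization_efficiency()`, optimal cut-point tables
(`cutpoint_table()`), a Monte-Carlo trial simulator with the
regression-slope estimator of D (`simulation_study()`), and maximum
likelihood fitting of SN parameters to published percentile summary tables
(`fit_sn_to_percentiles()`).

## Worked example

Splitting a normal covariate at its median keeps `2/π ≈ 64%` of the
adjustment benefit; for a right-skewed covariate the best split moves above
the median:

```r
library(dicheff)

dichotomization_efficiency(0, 0.5)
#> [1] 0.6366198
dichotomization_efficiency(5, c(0.5, 0.66))
#> [1] 0.6157863 0.6623080

cutpoint_table()
#>   shape optimal minimum maximum
#> 1     0    0.50    0.35    0.65
#> 2     2    0.59    0.44    0.73
#> 3     5    0.66    0.48    0.81
#> 4    10    0.67    0.48    0.82
#> 5    20    0.67    0.48    0.82
```

Each row gives, for a covariate of that shape, the percentile that
maximizes D and the range over which D stays above 0.6: a symmetric
covariate is best split at the median, while for substantial right skew the
optimum is near the 67th percentile with an acceptable range of roughly
0.48–0.82.

Concrete trial numbers — a 200-participant trial, treatment effect 15,
residual SD 30, covariate slope 20, and a covariate shaped like female BMI
(location 17.7, scale 6.66, shape 7.49), split at the median:

```r
d <- trial_design(200, gamma = 15, beta = 20, sigma_eps = 30)
efficiency_summary(d, sn_params(17.7, 6.66, 7.49), tau = 0.5)
#> Treatment-effect estimator variances (shape 7.49, tau 0.5):
#>   full 18 | dichotomized 69.062 | unadjusted 150.9
#>   dichotomization efficiency D = 0.6158
```

Full adjustment cuts the variance of the treatment effect from 150.9 to
18; the median split only gets it down to 69.1, i.e. 61.6% of the possible
reduction. Monte-Carlo corroboration of the closed form:

```r
empirical_efficiency(d, sn_params(0, 1, 2), tau = 0.5, n_reps = 200, seed = 1)
#> Empirical dichotomization efficiency at tau = 0.5: 0.6220 (95% CI 0.5539 to 0.6900), 200 replicates
dichotomization_efficiency(2, 0.5)
#> [1] 0.6240203
```

And recovering SN parameters from a 9-point percentile summary (the form
in which public reference data are published):

```r
tab <- percentiles_from_params(sn_params(17.7, 6.66, 7.49))
fit_sn_to_percentiles(tab)
#> Skew-normal fit to percentile table
#>   location 17.7, scale 6.66, shape 7.49  [converged]
#>   grouped loglik: SN -1.91147 vs normal -2.00157; max CDF dev 2.564e-07
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dicheff", package = "dicheff"))')
Rscript $CLI cutpoints --shapes 0,2,5,10,20 --threshold 0.6 --out cutpoints.csv
Rscript $CLI efficiency --shape 5 --tau 0.1,0.2,0.3,0.4,0.5,0.6,0.7,0.8,0.9 --out curve.csv
Rscript $CLI simulate --shapes 2,10 --reps 500 --seed 1 --out sim.csv
Rscript $CLI fit --input table.csv --out fit.json
```

Every run writes a `.meta.json` record with the effective parameters, seed
and package version next to its output.

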