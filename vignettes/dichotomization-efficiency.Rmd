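---
title: "Dichotomization efficiency for skew-normal covariates: model and methods"
author: "dicheff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomization efficiency for skew-normal covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicheff)
```

## The problem

Two-arm randomized trials with a continuous outcome are commonly analysed
with a linear model, adjusting for baseline covariates that predict the
outcome. When a continuous covariate (age, BMI, triglycerides, a risk
score) has first been used to stratify the randomization, it is often
entered into the analysis model in the same dichotomized form — above vs
below some threshold. Dichotomization discards information and inflates the
variance of the treatment-effect estimate. Many of the covariates this
happens to are visibly right-skewed, and the skew changes where the least
harmful threshold sits.

`dicheff` quantifies exactly how much of the precision gain from covariate
adjustment survives dichotomization when the covariate follows a
skew-normal (SN) distribution, and where the threshold should be placed.

## Model and assumptions

The data model for participant $i$ is

$$y_i = \alpha + \gamma z_i + \beta x_i + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma_\varepsilon), \qquad
x_i \sim \mathrm{SN}(\varphi, \omega, \lambda),$$

with $z_i \in \{0,1\}$ the arm indicator under 1:1 allocation ($n/2$ per
arm), $x$ a baseline covariate linearly associated with the outcome, and
the SN density
$f(x) = \tfrac{2}{\omega}\phi\!\big(\tfrac{x-\varphi}{\omega}\big)
\Phi\!\big(\lambda\tfrac{x-\varphi}{\omega}\big)$. Shape $\lambda = 0$
recovers the normal; the variance is
$\sigma_x^2 = \omega^2\big(1 - \tfrac{2\lambda^2}{\pi(1+\lambda^2)}\big)$.
Key assumptions: linearity of the covariate–outcome relationship, 1:1
allocation (so $S_{zz} = n/4$), and independence of $x$ and $z$ by
randomization. Results are asymptotic in $n$ but already accurate at 100
per arm.

Three analysis models are compared: the **full** model (raw covariate), the
**restricted** model (covariate omitted), and the **partially restricted**
model (covariate dichotomized at threshold $u$). Their treatment-coefficient
variances are

$$V(\hat\gamma; m_f) = \frac{4\sigma_\varepsilon^2}{n}, \qquad
V(\hat\gamma; m_r) = \frac{4(\sigma_\varepsilon^2 + \beta^2\sigma_x^2)}{n},
\qquad
V(\hat\gamma; m_p) = \frac{4\big(\sigma_\varepsilon^2 +
\beta^2(\sigma_x^2 - V(x_d))\big)}{n},$$

where $x_d$ is the two-point variable taking the conditional mean of $x$
below/above $u$ ($u_-$, $u_+$). This coding makes $x_d$ and the residual
$x - x_d$ uncorrelated, so the covariate variance partitions exactly:
$\sigma_x^2 = V(x_d) + V(x_r)$. Any affine recoding of $x_d$ — including
the usual 0/1 indicator — spans the same column space, so the regression
fit and $V(\hat\gamma; m_p)$ are unchanged; the simulator therefore codes
the dichotomized covariate as an indicator.

## The dichotomization efficiency

With $\tau = F(u)$ the probability mass below the threshold, the fraction
of the full-adjustment precision gain retained after dichotomization is

$$D = \frac{V(\hat\gamma;m_r) - V(\hat\gamma;m_p)}
           {V(\hat\gamma;m_r) - V(\hat\gamma;m_f)}
    = \frac{V(x_d)}{\sigma_x^2},$$

which depends only on $(\lambda, \tau)$: location and scale cancel
exactly, which is why `dichotomization_efficiency()` takes just those two
arguments (a wrapper accepting a full parameter set is provided). For a
normal covariate split at the median, $D = 2/\pi \approx 0.637$.

```{r}
dichotomization_efficiency(0, 0.5)
cutpoint_table()
```

The table shows the grid optimum and the range keeping $D > 0.6$: for
symmetric covariates split at the median (acceptable 0.35–0.65); once the
skew is substantial ($\lambda \ge 5$) the best split moves to about the
67th percentile, acceptable roughly 0.48–0.82.

## Numerical choices

* **SN distribution function.** No closed form exists; we use the identity
  $F(x;\lambda) = \Phi(x) - 2T(x,\lambda)$ with Owen's $T$ computed by
  adaptive quadrature of its defining integrand (relative tolerance
  1e-13). For $|\lambda| > 1$ the standard reduction
  $T(h,a) = \tfrac12\Phi(h) + \tfrac12\Phi(ah) - \Phi(h)\Phi(ah) -
  T(ah, 1/a)$ keeps the quadrature argument in $[0,1]$, which avoids
  cancellation noise in the far tails.
* **Quantiles** invert the CDF by bracketed root-finding (`uniroot`,
  bracket seeded at the normal quantile shifted by the SN mean, tolerance
  1e-12; round-trip accuracy is tested at 1e-8).
* **Truncated means.** The doubly truncated mean of the standard SN is
  evaluated in closed form from $f$, $F$ and
  $\delta = \lambda/\sqrt{1+\lambda^2}$, then generalized by the
  location–scale transform. We use the *signed* $\delta\sqrt{2/\pi}$
  coefficient so the formula is valid for left-skewed ($\lambda < 0$)
  covariates as well; correctness is verified against direct quadrature of
  $\int x f(x)\,dx$ in the test suite.
* **Degenerate thresholds.** $\tau$ outside $[10^{-6}, 1-10^{-6}]$ is
  rejected rather than evaluated: $D$ involves division by $\tau(1-\tau)$
  and values there are numerically meaningless.
* **Cut-point search** is a grid search at resolution 0.01 with 2-decimal
  reporting; that granularity makes the "smallest/largest percentile with
  $D$ strictly above the threshold" semantics exact. Ties at the argmax
  (within 1e-12) break towards the median. A golden-section `refine`
  option polishes the optimum when a continuous answer is wanted. The
  acceptable range uses strict $D >$ threshold; at threshold 0.6 and
  $\lambda = 0$ this puts the boundary at 0.35 ($D(0.35) \approx 0.603$,
  $D(0.34) \approx 0.598$). An unattainable threshold returns an explicit
  empty range rather than an error.
* **Unimodality of $D$ in $\tau$** is checked numerically over the studied
  shape range in the tests, not assumed.

## The simulator and what it emulates

`generate_trial()` draws trials under the model above with exactly
balanced arms. Defaults throughout the simulation functions mirror the
study conditions used to corroborate the closed forms: treatment effect
$\gamma = 15$, covariate slope $\beta = 20$, residual SD
$\sigma_\varepsilon = 30$ (a standardized effect of 1/2), 100 participants
per arm, 500 replicates per setting, and thresholds
$\tau = 0.1, \dots, 0.9$. Sampling uses the conditioning representation
$X = \delta|Z_0| + \sqrt{1-\delta^2}Z_1$ with a mandatory seed; replicate
$r$ uses `seed + r`, and each grid cell gets a disjoint seed block, so any
subset of a study is independently reproducible.

`fit_three_models()` takes each model's variance of $\hat\gamma$ as the
squared standard error reported by the OLS fit (the model-based variance),
which is the quantity the closed forms predict. The threshold is the
*population* quantile $F^{-1}(\tau)$, not the sample quantile, so the
simulated $\tau$ matches the analytic one exactly.

Because the empirical $D$ is a ratio whose denominator is random,
replicates with small denominators would blow up a direct ratio estimate.
`empirical_efficiency()` instead regresses
$V(\hat\gamma;m_r) - V(\hat\gamma;m_p)$ on
$V(\hat\gamma;m_r) - V(\hat\gamma;m_f)$ across replicates and reports the
slope with a t-based 95% CI. The regression includes an intercept by
default (recorded in the output; a no-intercept option exists) — with an
intercept the slope is consistent for $D$ whether or not the small-sample
intercept is exactly zero.

What passing simulation tests shows — and what it does not: the simulator
draws from exactly the assumed model (SN covariate, normal errors, perfect
balance, linearity), so agreement corroborates the algebra, not the
model's fit to any real trial. Real data bring non-linearity, measurement
error, covariate distributions that are only approximately SN, and
imperfect balance; none of these are emulated.

The acceptance checks run 200 replicates per cell over
$\lambda \in \{2, 10\} \times \tau \in \{0.1,\dots,0.9\}$ and 300
replicates for the variance-formula comparison; these sizes give
Monte-Carlo standard errors comfortably inside the tested tolerances while
keeping the whole suite fast on a single CPU.

## Fitting SN parameters to percentile tables

Public reference data (growth charts, lipid tables) publish percentile
summaries, not microdata. "Maximum likelihood on a percentile table" is
under-determined, so the package adopts the grouped (multinomial)
likelihood: the tabulated values cut the line into bins (open tails
included), the target mass of each bin is the gap between consecutive
percentiles, and the objective is $\sum_i m_i \log\{F(v_i;\theta) -
F(v_{i-1};\theta)\}$ — a proper likelihood on exactly the information the
table carries. A least-squares fit of the model CDF to the tabulated
percentiles is available (`objective = "cdf_ls"`) as a sensitivity check;
on noiseless tables the two agree, and a material discrepancy on real
tables is itself a diagnostic worth reporting.

Optimization is Nelder–Mead (the shape likelihood can be flat near zero)
with a log-parameterized scale, multi-started from shapes $\{-5, 0, 5\}$
plus a moment-matching start (median/IQR for location/scale, Bowley
quantile skewness mapped to a shape guess). A normal fit (shape fixed at
zero) of the same objective is always reported; since it is the nested
submodel, its grouped log-likelihood can never exceed the SN one. A
percentile table carries no sample size, so the likelihood is per unit
mass; the qualitative normal-vs-SN verdict in `compare_to_normal()`
scales the likelihood-ratio statistic by a nominal `pseudo_n` (default
1000) and compares to the chi-square(1) 99.9% quantile, with both choices
recorded in the output metadata. Reproducing published fits to specific
national reference datasets requires those external files; the package
ships the method and generates its own test tables from known parameters
with `percentiles_from_params()`.

## Known limitations

* Linearity of the covariate–outcome relationship is assumed; a genuine
  change point at the threshold could alter or even reverse the
  conclusions, and non-linear relationships are out of scope.
* Only 1:1 allocation and a single two-level split are covered — no
  unequal allocation, no multi-category stratification, no
  covariate–treatment interactions.
* The SN family itself is the modelling choice; heavier-tailed skew
  families (skew-t) and transformation approaches (log, Box–Cox) are not
  implemented.
* Closed forms are asymptotic; at very small $n$ the model-based variances
  carry finite-sample error of relative order $1/n$.
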