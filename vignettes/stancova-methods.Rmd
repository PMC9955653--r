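---
title: "Methods: exact inference and precision planning for standardized ANCOVA contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact inference and precision planning for standardized ANCOVA contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancova)
```

## Model and estimands

The package works with the fixed-effects ANCOVA model
$$Y_{ij} = \mu_i + \textstyle\sum_{k=1}^P X_{kij}\,\beta_k + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$
for $i = 1,\dots,G \ (\ge 2)$ groups, $j = 1,\dots,N_i$ subjects and
$P \ (\ge 1)$ covariates with common slopes.  A treatment comparison is a
zero-sum linear contrast of adjusted means,
$\psi = \sum_i c_i \mu^*_i = \sum_i c_i \mu_i$, and the estimand of interest
is its standardized form $\psi^* = \psi/\sigma$ — an effect size in error-SD
units, comparable across studies with different outcome scales.

`fit_ancova()` solves the pooled within-group normal equations
$S_{XX}\hat\beta = S_{XY}$ directly (`solve()`, never an explicit inverse);
a condition number of $S_{XX}$ above $10^{12}$ is rejected as collinear
rather than silently producing noise.  The residual degrees of freedom are
$\nu = N_T - G - P$ and $\hat\sigma^2 = \mathrm{SSE}/\nu$.
`contrast_estimate()` assembles
$a = \sum_i c_i^2/N_i$, the observed covariate disparity
$Q = (\sum_i c_i \bar X_i)^\top V_{XX}^{-1} (\sum_i c_i \bar X_i)$, the
variance factor $V = a + Q/(N_T - G)$, and the observed statistic
$T^*_O = \hat\psi^*/\sqrt{V}$.  Group labels are mapped to indices in order
of first appearance and contrast coefficients are matched to that order;
this is documented in the CLI help because no convention is universal.

Because $E[1/\hat\sigma] > 1/\sigma$, the plug-in $\hat\psi^*$ is biased
upward; `unbias_factor()` supplies
$u(\nu) = \Gamma(\nu/2)\,/\,\{(\nu/2)^{1/2}\Gamma((\nu-1)/2)\}$ through
`lgamma` (stable for any $\nu$), defined for $\nu > 1$ only — requesting the
unbiased estimate at $\nu \le 1$ is an error rather than an extrapolation.

## The three intervals

`exact_ci()` inverts the pivot $T^* \sim t(\nu, \lambda)$,
$\lambda = \psi^*/\sqrt V$, in its noncentrality parameter: the lower limit
is $\lambda_L\sqrt V$ with $P[t(\nu,\lambda_L) \le T^*_O] = 1-\alpha_1$, the
upper $\lambda_U\sqrt V$ with tail $\alpha_2$.  Equal tails
$\alpha_1=\alpha_2=\alpha/2$ are the default; one-sided forms return
$(L,\infty)$ and $(-\infty,U)$.  The CDF is continuous and strictly
decreasing in $\lambda$, so each equation has a unique root.  The solver
brackets it starting from a window of half-width $2+|T^*_O|$ around
$T^*_O$ (where the root concentrates), doubles the window until the target
is straddled (an error after 64 doublings, never a silent return), and runs
`uniroot` at tolerance $10^{-12}$; a property test confirms the returned
limits reproduce their tail levels to $10^{-8}$.  Targets in the far upper
tail are solved on the survival scale so small probabilities retain relative
precision.  At $T^*_O = 0$ the CDF at zero is exactly $\Phi(-\lambda)$ and
the limits collapse to $\mp z_{1-\alpha}\sqrt V$ — used as a closed-form
anchor in the tests.  Internally everything is kept in full precision;
rounding to 4 decimals happens only in printed output.

`asymptotic_ci()` uses
$\hat\psi^* \mp z_{\alpha/2}\{V + \hat\psi^{*2}/(2\nu)\}^{1/2}$ and
`direct_ci()` uses $\hat\psi^* \mp t_{\nu,\alpha/2}V^{1/2}$, the
unstandardized interval divided by $\hat\sigma$ (`unstandardized_ci()`
provides the response-scale original).  Both are equidistant about the
estimate, which is exactly why direct division fails for $\psi^* \ne 0$:
the exact interval is asymmetric, and the simulation suite shows the
direct interval's coverage deficit growing with the effect size while the
exact and asymptotic intervals stay near nominal.

## Precision under stochastic covariates

At the design stage covariate values do not exist yet.  With
$X_{ij} \sim N_P(\mu_{Xi}, \Sigma_X)$ the variance factor is random:
$V = a(1 + bF_X)$, $b = P/(\nu+1)$, with
$F_X \sim F(P, \nu+1, \xi)$, $\xi = \theta/a$, where
$\theta = (\sum_i c_i\mu_{Xi})^\top \Sigma_X^{-1}(\sum_i c_i\mu_{Xi})$ is
the population covariate disparity (`covariate_disparity()`; zero under
randomization).  All precision quantities depend on the covariate model
only through $\theta$, a property the tests check to $10^{-10}$ by feeding
the same $\theta$ through two parameterizations.

The exact interval's two limits are both $\sqrt V$ times a noncentrality
root, so its width factorizes as $W = \sqrt V\, d(T^*)$ where
$d(t) = \lambda_U(t) - \lambda_L(t)$ (`ncp_width()`) is *free of $V$* — an
even, analytic function of $t$ with minimum $2z_{1-\alpha/2}$ at zero.
This factorization is the computational backbone: expected width and
assurance probability are
$$\Omega = E_F\!\left[\sqrt V\, E_T\, d(T)\right], \qquad
  \Gamma = E_F\!\left[P_T\{d(T) \le \omega/\sqrt V\}\right],$$
with $T \mid V \sim t(\nu, \psi^*/\sqrt V)$.  The approximate variants
(`method = "approximate"`) replace $V$ by $a$ throughout — a single
noncentral-t layer with $\lambda_a = \psi^*/\sqrt a$ — reproducing the
shortcut that treats the covariate-mean contrast as negligible.

### Quadrature design

Both expectations are computed by Gauss–Legendre rules mapped through the
relevant quantile function on the probability scale $(\varepsilon,
1-\varepsilon)$, $\varepsilon = 10^{-7}$; the omitted tail mass
$2\varepsilon$ is reported in the result's diagnostics.  Two refinements
make the rules converge uniformly over the sizes the planner visits:

* **Log-substituted tail blocks.**  For small $\nu$ the noncentral t and F
  quantiles grow polynomially as $u \to 1$ (at $\nu = 2$, $q_t(u) \sim
  (1-u)^{-1/2}$), so a plain rule on $(\varepsilon, 1-\varepsilon)$ stalls.
  Each layer therefore uses a central rule on $(\delta, 1-\delta)$,
  $\delta = 10^{-2}$, plus tail rules under the substitution $u = e^{-s}$,
  which turns the mapped integrand into a smooth decaying exponential in
  $s$.  The width-spline abscissae follow asinh spacing for the same
  reason: near-unit resolution where $d$ curves, geometric growth where it
  is asymptotically linear.
* **Square-root substitution at the assurance boundary.**  The inner event
  $\{d(T) \le \omega/\sqrt V\}$ has positive probability only while
  $V < (\omega/d(0))^2$; at that boundary $u^*$ the inner probability
  vanishes like $\sqrt{u^* - u}$.  When $u^*$ falls inside the domain the
  outer rule substitutes $u = u^* - (u^* - \varepsilon)w^2$, which removes
  the kink; otherwise the composite rule above applies.

$d$ is expensive (two root solves per abscissa), so per evaluation it is
cached as a cubic spline of $|t|$ over the range the nodes actually need
— legitimate because $d$ is even and analytic — cutting the cost by the
product of the node counts.  The inner probability for $\Gamma$ uses the
observation that $d$ is unimodal with minimum at $t = 0$: the single
positive crossing of $d(t) = \omega/\sqrt V$ is solved on the spline and
the probability is one CDF difference.  Unimodality is observed, not
proven, so every evaluation is double-checked by a run-detecting indicator
integration on a 2,000-point grid that makes no shape assumption; a
disagreement beyond $10^{-4}$ raises an error instead of returning a
plausible number (`precision_control(check_event = )`).

Node counts (64 outer, 96 inner, 161-point width grid by default) and the
grid double until two successive evaluations agree to $10^{-4}$ — matched
to the 4-decimal scale on which these quantities are conventionally
reported — and failing to converge within three levels is an error carrying
the diagnostics.  Reported results always come from the finer level.

## Sample-size determination

`sample_size_width()` and `sample_size_assurance()` search the lattice
$N_i = r_i n$, $n = 1, 2, \dots$, starting at the smallest $n$ with
$\nu \ge 2$ and every $N_i \ge 2$, ascending linearly until
$\Omega \le \omega$ or $\Gamma \ge 1-\gamma$.  Monotonicity of these
criteria in $N_T$ is an empirical regularity rather than a theorem, so the
search does not bisect; instead every plan carries a minimality
certificate — the criterion value at the preceding lattice size, which
violates it.  Equality counts as feasible (the criteria are non-strict
inequalities).  Ratios must be positive integers: rounding a fractional
ratio would silently change $a$ and hence every downstream quantity, so it
is an error.  A cap (`NT_max`, default 20,000) turns an unattainable
criterion into an explicit failure.

## The simulation suite

Two Monte Carlo designs validate the analytical machinery and double as
the package's synthetic-data generator.

**Conditional coverage** (`simulate_coverage()`) holds the covariate
statistic fixed — $V = \sum_i c_i^2/N_i + Q/(N_T-G)$ with supplied $Q$ —
and draws $\hat\psi \sim N(\psi, \sigma^2 V)$ and
$\hat\sigma^2 = \sigma^2\chi^2_\nu/\nu$ independently, which is exactly the
sampling distribution of the fitted quantities given the covariates.  The
defaults ($Q = 0.2131$, $\sigma^2 = 3.2728$, contrast $\{-1, 1/2, 1/2\}$,
balanced $G = 3$) mirror the learning-disabilities study from which the
benchmark coverage table was built.  Exact-interval coverage is evaluated
through the pivotal identity — the interval contains $\psi^*$ iff
$P[t(\nu, \psi^*/\sqrt V) \le T^*_O] \in (\alpha_2, 1-\alpha_1)$ — which is
the same event as forming the interval, without per-replicate root solves;
the tests assert the equivalence against explicitly formed intervals.

**Full-model precision** (`simulate_precision()`) generates covariates from
the design's covariate model, responses from the ANCOVA model (slopes are
nuisance parameters, set to $0.5$ by default; intercepts placed so the
contrast equals $\psi^*\sigma$), refits every replicate, and records the
exact interval's width.  Covariates and errors come from separate seeded
streams so each source of randomness is independently reproducible;
identical seeds give bit-identical results.  Singular replicate fits are
redrawn and counted, and more than 0.1% of them is an error.  Non-normal
options standardize each named law — Exponential(1), Gamma(5, $5^{-1/2}$),
Laplace(0,1), Lognormal(0, 1/4), Uniform(0,1), and $t(10)$ errors — to the
target means and unit variance before use, so $\theta$ is held fixed across
laws and only the shape changes.  (After standardization the Gamma
scale-versus-rate reading is immaterial — the skewness depends only on the
shape parameter — but both readings are exposed.)

What the generator does *not* emulate: heteroscedastic errors, group-specific
slopes, measurement error in covariates, clustered or longitudinal
structure, and missing data.  Passing tests therefore certify the
distribution theory under the stated model, not robustness to violations
beyond the moderate non-normality probed above.

## Default study conditions

The planning defaults are the benchmark conditions: $G = 3$ balanced
($r = \{1,1,1\}$), $c = \{1, -0.5, -0.5\}$, $\psi^* = 0.5$, $\sigma^2 = 1$,
$1-\alpha = 0.95$, $\theta \in \{0, 0.25, 0.5\}$ spanning randomized to
visibly imbalanced designs (on the $f^2{}^* = \theta/a^*$ scale these are
conventional small-to-medium disparities), width bounds
$\omega \in \{1.0, 1.25, 1.5\}$ in $\psi^*$ units, assurance level $0.80$,
and 10,000 replicates for simulations (tests scale down to 2,000 with
correspondingly widened Monte Carlo tolerances; the acceptance script keeps
10,000 for its one stochastic quantity).

## Known limitations

* Single contrasts only: no simultaneous bands or multiplicity adjustment.
* Precision criteria are computed for the exact interval only; the
  asymptotic and direct intervals are assessed by simulation, not planned
  for.
* The noncentral-F reduction of the covariate factor is exact under
  multinormal covariates and a good approximation otherwise; for severely
  heavy-tailed covariates the simulation route is the honest check.
* `stats::pt` with a noncentrality parameter can emit "full precision may
  not have been achieved" warnings; the achieved accuracy (order $10^{-10}$)
  is far inside every tolerance used here, and the engine suppresses the
  warning where it is expected.  Extremely large $|T^*_O|$ (beyond a few
  hundred) would degrade the inversion and is outside the intended regime.
* Residual degrees of freedom below 2 are rejected by the precision engine
  (the expected width is barely finite at $\nu = 2$ and undefined below),
  and the unbiased estimator requires $\nu > 1$.
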