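---
title: "Projecting the accuracy of combined polygenic and environmental risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting the accuracy of combined polygenic and environmental risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsproject)
library(dplyr)
```

## The question this package answers

A polygenic risk score built from a finite GWAS is a noisy estimate of an
individual's genetic liability. Its accuracy depends on the training sample
size $n$, the number of independent markers $m$, the proportion $\pi_0$ of
markers with no effect, the chip heritability $R^2_{GY}$ of the outcome, and
the two-sided P-value window $(p_0, p_1]$ used to admit markers into the
score. When an environmental (more generally, nongenetic) risk score $X$
already exists, two questions follow: how much does adding genetic
information improve prediction now, and what is the ceiling as training
samples grow? Both are complicated by the fact that many "environmental"
scores are themselves heritable, so the two predictors are correlated
through the genome.

`prsproject` answers these questions analytically — every published-style
number it produces is a deterministic evaluation of normal-theory formulas
— and ships an individual-level Monte-Carlo simulator whose only job is to
validate those formulas by brute force.

## The quantitative model

The outcome $Y$ is standardized; genotypes are independent and
standardized, with marker effects $\beta_i$ drawn from a normal-null
mixture: zero with probability $\pi_0$, otherwise
$N(0,\, R^2_{GY}/((1-\pi_0)m))$. The environmental score $X$ has a unit
effect on $Y$, so $\mathrm{var}(X) = R^2_{XY}$, the variance it explains.
$X$ may be heritable with chip heritability $R^2_{GX}$ and genetic
correlation $\rho$ with the outcome, giving chip covariance
$\rho\sqrt{R^2_{GY} R^2_{XY} R^2_{GX}}$ between the full polygenic score
and $X$.

Marginal per-marker OLS estimation with P-value selection leaves the
estimated score $\hat S$ with moments that all flow through one function,
the normal second-moment tail integral
$T(x_0, x_1) = \int_{x_1}^{x_0} z^2 \varphi(z)\,dz
  = \Phi(x_0) - \Phi(x_1) + x_1\varphi(x_1) - x_0\varphi(x_0)$,
implemented by `truncation_factor()`. Selection quantiles
$q_j = \Phi^{-1}(1 - p_j/2)$ apply to estimated effects; the same
quantiles multiplied by the shrinkage factor
$\theta = (n R^2_{GY} / ((1-\pi_0) m) + 1)^{-1/2}$ apply to true effects
(`selection_quantiles()`). Then

* $\mathrm{cov}(\hat S, Y) = 2 R^2_{GY}\, T(r_0, r_1)$,
* $\mathrm{var}(\hat S)$ adds the surviving true-effect variance and the
  surviving estimation noise, the latter weighted by $T(q_0, q_1)$ for
  null markers,
* $\mathrm{cov}(\hat S, X) = 2\rho\sqrt{R^2_{GY} R^2_{XY} R^2_{GX}}\,
  T(r_0, r_1)$.

For a binary outcome we use the liability-threshold model: disease when a
standard-normal liability exceeds $\tau = \Phi^{-1}(1-K)$ at prevalence
$K$. Training on the observed 0/1 scale with case fraction $P$ scales
effects by $c = \varphi(\tau) P(1-P) / (K(1-K))$ and estimation noise to
$P(1-P)/n$; `score_moments()` back-transforms everything to the liability
scale, where all downstream metrics live.

Two details are handled as exact limits rather than numerically: $p_0 = 0$
maps to an infinite selection quantile (with $\Phi(\infty) = 1$,
$x\varphi(x) \to 0$), and $n = \infty$ sets $\theta = 0$, so
infinite-training rows of the report tables are limits, not large-$n$
surrogates.

One caveat worth stating: the control-side conditional variance used for
AUC has the factor $\varphi(\tau)/(1-K) + \tau$. We verified numerically
that only this form reproduces the model's own discrimination grid (e.g.
the infinite-training AUC of 0.782 in the CVD setting); a variant with
$\varphi(\tau)/K$ in that position does not.

## Combining the scores, and the downstream metrics

`combine_scores()` forms $w_1 \hat S + w_2 X$ either unweighted
($w_1 = w_2 = 1$, the common field practice) or with the least-squares
weights from the 2×2 normal equations, solved in closed form with a
$10^{-12}$ determinant guard that falls back to the environment-only
score. Polygenic-only and environment-only results use the same code path
with weights $(1,0)$ and $(0,1)$, so every metric has a single
implementation. The calibration coefficient
$\gamma = \mathrm{cov}(\hat S_{comb}, Y)/\mathrm{var}(\hat S_{comb})$
rescales the combined score so its variance equals its liability $R^2$;
least-squares weights give $\gamma = 1$ identically, which the tests
assert to machine precision.

From the combined $R^2$ at prevalence $K$ the package derives:

* **AUC** (`liability_auc()`), the normal concordance probability of the
  case and control conditional distributions;
* **categorical NRI** (`categorical_nri()`), rectangle probabilities of
  the trivariate normal joint distribution of liability, $X$, and the
  calibrated combined score across an absolute-risk threshold;
* **continuous NRI** (`continuous_nri()`) and **IDI** (`idi()`), the
  category-free analogues;
* **case capture** (`case_capture()`), the Lorenz-curve view used in
  screening; and **sensitivity/specificity** at a risk threshold
  (`sens_spec()`).

Multivariate-normal rectangles are assembled by inclusion–exclusion over
deterministic CDF evaluations (`mvtnorm`'s TVPACK algorithm, absolute
tolerance $10^{-8}$, tiny negative results clipped to zero), so repeated
runs are bit-identical — no quasi-Monte-Carlo jitter enters the report
tables. The IDI is computed by adaptive quadrature of the printed
liability integral (`stats::integrate`, relative tolerance $10^{-10}$);
the test suite cross-checks it against the closed form obtained by
collapsing the normal mixture into a single probit.

We report two-category NRI at each requested threshold rather than a
multi-category table; multi-category extensions, predictiveness curves
and net-benefit measures are out of scope, as is estimating any of the
input parameters from genotype data.

## Decision support

`optimize_threshold()` maximizes any metric over $p_1$ (200-point log
grid on $[10^{-10}, 1]$, then golden-section refinement in $\log p_1$ to
relative tolerance $10^{-3}$, ties toward smaller $p_1$). A recurring
finding is that liberal selection — around nominal significance, far from
genome-wide thresholds — maximizes projected accuracy at current consortium
sizes, because the false discovery rate, not the family-wise error rate,
governs a score's explanatory power.

`required_sample_size()` inverts the accuracy-versus-$n$ curve by
bisection on $\log_{10} n$ (optionally re-optimizing $p_1$ at each $n$),
reports the smallest $n$ to three significant figures, and refuses
targets above the exact infinite-training asymptote, naming the limit.
Binary designs also report the equivalent case count $nP$, the convention
used for consortium sizes at a fixed controls-per-case ratio.

### Family history as the environmental score

For a strongly heritable continuous trait, the natural benchmark is the
mean-parental value. Under an additive model with no shared environment,
the offspring–mid-parent genetic covariance is $h^2/2$ and the variance
explained is twice its square, $R^2_{XY} = h^4/2$ — 0.32 at $h^2 = 0.8$ —
with genetic correlation $1/\sqrt 2$. A genuinely open design choice is
the chip heritability of the family-history score. Treating the score as
the mid-parent phenotype rescaled to unit effect, rescaling preserves
variance *proportions*, so $R^2_{GX} = R^2_{GY}$ (the trait's own chip
heritability) and the implied chip covariance is $h^2 \cdot h^2_{chip}/2$.
Plausible-looking alternatives — taking the chip covariance to be
$h^2_{chip}/2$ outright, or halving the chip heritability — are refuted by
a direct trio simulation (parent genotype pairs, Mendelian segregation,
offspring chip scores) included in the test suite, which reproduces
$\mathrm{cov}(S, X) = h^2 h^2_{chip}/2 = 0.192$ at the defaults. This
choice does not touch the headline family-history results ($R^2_{XY} =
0.32$ and the polygenic crossing near $n = 301{,}000$), which involve no
environmental chip terms.

## The simulator: what it emulates and what it does not

The simulator is the package's brute-force oracle, not a data generator
for applied use. It draws shared-null effect pairs $(\beta_i, \alpha_i)$
with the mixture moments above; replaces explicit training regression by
its exact sampling distribution for independent standardized markers
(estimates are true effects plus $N(0, 1/n)$ noise, or $N(0, P(1-P)/n)$
on the observed scale with the $c$ transformation); and generates
evaluation cohorts under the mediation structure $X = \alpha'G + \eta$,
$Y = \beta'G + b\eta + \varepsilon$. The model prescribes only moments,
not a generative factorization, so the coefficient $b$ on the nongenetic
component of $X$ is chosen to make $\mathrm{cov}(X, Y) = R^2_{XY}$ hold
exactly (a unit marginal effect of $X$ without double-counting the shared
genetic part), and $\varepsilon$ tops the outcome variance up to 1;
moment combinations that would need negative residual variance raise an
error instead of renormalizing silently. Genotypes are independent
standardized Gaussians, matching the analytic abstraction.

Consequently, passing simulator-agreement tests shows that the formulas
are internally correct *under the model's assumptions*. It says nothing
about linkage disequilibrium, non-normal effect-size distributions (for
instance sharply peaked ones, under which selection behaves differently),
binary genotypes at low minor-allele frequency, case-control sampling of
the evaluation cohort, or heterogeneity between training and target
populations — all real-data features the model deliberately abstracts
away.

Agreement tests run at reduced scale — $m = 1000$ markers, $n = 2000$
training and evaluation subjects, 100–200 replicates under fixed seeds —
chosen so the whole suite completes in a few minutes while Monte-Carlo
standard errors remain small enough for 3-standard-error assertions to
have teeth. Every analytic operation (moments, AUC, both NRIs, IDI,
capture) has such a test.

## Worked-scenario presets and their provenance

`risk_scenario()` bundles three parameterizations drawn from the
published literature on coronary heart disease (63,746 cases, 2.05
controls per case, $R^2_{GY} = 0.3$, $\pi_0 = 0.8$, $K = 0.15$,
$R^2_{XY} = 0.052$), breast cancer (33,673 cases, 0.99 controls per case,
$R^2_{GY} = 0.3$, $\pi_0 = 0.95$, $K = 0.05$, $R^2_{XY} = 0.0375$), and
height ($m = 2.5$M, $R^2_{GY} = 0.48$, $\pi_0 = 0.995$, family-history
environmental score). Prevalence and null-proportion overrides expose the
standard sensitivity variants. The training sizes use the exact published
case/control counts; where the source material prints two slightly
different case counts for the same consortium, the presets use the count
stated with the consortium description (63,746).

```{r}
sc <- risk_scenario("breast_cancer", rho = 0.4, r2_gx = 0.8)
pr <- project_accuracy(sc$design, sc$trait, sc$env, "ols",
                       risk_thresholds = 0.08, quantiles = c(0.1, 0.2, 0.5))
glance(pr)
tidy(pr)
```

`scenario_table()` regenerates the full summary grids, and
`accuracy_curve()` + `autoplot()` trace accuracy against training size:

```{r, fig.width = 6, fig.height = 3.5}
cvd <- risk_scenario("cvd")
cur <- accuracy_curve(cvd$design, cvd$trait, cvd$env,
                      schemes = c("polygenic", "environment", "ols"),
                      n_grid = 10^seq(4, 6.5, length.out = 12))
autoplot(cur)
```

The curves illustrate the package's central qualitative message: combined
scores are barely better than the environmental score at genome-wide
selection thresholds and current sample sizes, improve substantially with
liberal selection, and are eventually dominated by the polygenic
component as training samples grow — while the environmental score
retains independent value whenever the chip heritability falls short of
what it captures (family history being the extreme case).

## Numerical choices, degenerate inputs, limitations

* Probability computations use double precision throughout; CDF/quantile
  calls are the standard library's. MVN CDF arguments are clamped at
  $\pm 37$ standard deviations, beyond which the probabilities underflow
  anyway.
* A selection window expected to pass no variance flags the moments as
  degenerate; the combiner then warns and returns the environment-only
  score rather than dividing by zero.
* Identical old and new scores (the environment-only reduction) return
  NRI and IDI of exactly zero by convention, short-circuiting a singular
  trivariate joint.
* The trivariate covariance is eigenvalue-checked (tolerance
  $-10^{-10}$) before integration; inconsistent parameter combinations
  fail loudly.
* `required_sample_size()` resolves $n$ to three significant figures;
  quoting finer precision would be false precision given that the inputs
  (heritabilities, $\pi_0$) are themselves estimates.
* The conditional case/control distributions are treated as normal with
  the stated moments — an approximation inherited from the model; the
  simulator quantifies it (at the scales tested the error is within
  Monte-Carlo noise) rather than replacing it.
* All results are projections under an idealized architecture
  (independent markers, normal-null effects); they set expectations and
  design targets, not guarantees for any particular cohort.
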