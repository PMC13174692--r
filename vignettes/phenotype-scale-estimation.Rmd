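---
title: "Estimating phenotype measurement scales by quantile-effect homogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phenotype measurement scales by quantile-effect homogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(siqreg)
```

## The model

Quantitative traits are usually analyzed on whatever scale the instrument or
database provides, yet additive genetic and covariate effects are a property
of a *scale*, not of a trait. `siqreg` assumes there exists a latent
phenotype on which effects are additive,

$$ y^* = G\beta^* + C^\top\alpha^* + \varepsilon, \qquad
   y^* = \mathrm{BoxCox}(y;\lambda_0) = \frac{y^{\lambda_0}-1}{\lambda_0}, $$

with the log map as the $\lambda_0 \to 0$ limit. On the correct scale a
predictor shifts every conditional quantile by the same amount; on a wrong
scale its quantile-regression coefficient profile $\hat\alpha(\tau_k)$ bends.
The estimator therefore minimizes, over candidate $\lambda \in [-5, 5]$, the
Wald quadratic form
$r^*(\lambda)^\top \Sigma(\lambda)^{-}\, r^*(\lambda)$ built from relative
residuals $r^*_k = 1 - \hat\alpha(\tau_k)/\bar\alpha$, where
$\Sigma(\lambda)$ is the multiplier-bootstrap covariance of $r^*$. Because
$\sum_k r^*_k = 0$ identically, $\Sigma$ is structurally rank $K-1$; the
quadratic form drops the last coordinate and inverts the $(K-1)\times(K-1)$
block (a generalized inverse is the fallback when that block is itself
ill-conditioned).

Two quantile-level sets are deliberately distinct and never conflated:
deciles $\tau \in \{0.1,\dots,0.9\}$ for estimating $\lambda_0$ (stable,
central), and the nine-level testing set
$\{0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99\}$ for detecting
quantile-dependent predictor effects (tail-sensitive).

Each covariate yields its own $\hat\lambda$; estimates from informative
covariates are pooled by fixed-effect inverse-variance meta-analysis, with
Cochran's Q reported as a cross-covariate heterogeneity diagnostic (reported,
not acted on). Standard errors come from $R$ disjoint subsamples:
$\mathrm{SE} = \mathrm{sd}(\hat\lambda_1,\dots,\hat\lambda_R)/\sqrt{R}$. The
$\sqrt R$ scaling treats the subsample spread as $R$ independent draws of an
estimator whose variance scales linearly in sample size; it is validated
empirically by coverage simulation rather than assumed.

## Smoothed quantile regression

All quantile regressions use convolution smoothing with a Gaussian kernel:
the check loss $\rho_\tau(u) = u(\tau - 1\{u<0\})$ is replaced by its
convolution with a bandwidth-$h$ kernel, which has the closed form
$\tau u - u\Phi(-u/h) + h\phi(u/h)$ — convex and twice differentiable, with
derivative $\tau - \Phi(-u/h)$. Fitting is Barzilai–Borwein gradient descent
($O(pn)$ per iteration, C++ inner loop), initialized at least squares,
declared converged when the gradient sup-norm falls below
$10^{-5}\,\mathrm{sd}(y)$ (at most 500 iterations; non-convergence is
flagged per quantile level, never silent). Predictors are standardized
internally and coefficients mapped back, so step sizes and the bandwidth act
on a common scale. The bandwidth default is the rate-optimal
$h = ((p + \log n)/n)^{2/5}$.

Coefficient covariances across quantile levels use a multiplier (weighted)
bootstrap with i.i.d. Exp(1) weights: every replicate refits all levels under
reweighted loss, warm-started at the full-data solution and solved to a
looser tolerance (20× the fit tolerance) — the solver error this leaves is
orders of magnitude below bootstrap sampling noise. The default is $B = 200$
replicates; the simulation harnesses run smaller $B$ (20–100), which is
adequate for locating the objective's minimum because common random numbers
(one weight matrix shared by every candidate $\lambda$) make the objective
curve smooth in $\lambda$.

## Numerical choices

* **Log limit.** $|\lambda| < 10^{-8}$ is treated as $\lambda = 0$;
  $(y^\lambda - 1)/\lambda$ suffers catastrophic cancellation below that.
* **Positivity.** Box-Cox requires $y > 0$. The default policy is to reject
  non-positive phenotypes with a count of offenders; an optional `"shift"`
  policy adds $\epsilon - \min(y)$ with $\epsilon = 10^{-6}\,\mathrm{range}(y)$
  and records the shift, because silently shifting would change
  $\hat\lambda_0$.
* **RINT.** Blom fractional ranks $(r - 3/8)/(n + 1/4)$ with average ranks on
  ties — the convention of the GWAS literature.
* **Search.** The objective is minimized by a coarse grid (step 1.0 over
  $[-5,5]$), a finer grid (step 0.2) spanning one coarse step around its
  minimum, then golden-section refinement to a width of 0.005 in $\lambda$.
  With common random numbers the objective is smooth enough that this visits
  the same minimum as a dense 0.1-step grid at roughly a quarter of the
  objective evaluations. Optima within twice the tolerance of $\pm 5$ are
  flagged `boundary`.
* **Resolution guard.** A grossly wrong candidate $\lambda$ can compress the
  central mass of the transformed phenotype into less than about two
  smoothing bandwidths; decile coefficients are then artificially
  homogeneous and the objective spuriously small. Candidates whose central
  quantile span (between the smallest and largest estimation level) is below
  $2h$ after standardization are flagged degenerate and excluded from the
  search, exactly like uninformative covariates.
* **Uninformative covariates.** If $|\bar\alpha|/\mathrm{SE}(\bar\alpha) < 2$
  the ratio $r^* = 1 - \hat\alpha/\bar\alpha$ explodes; such covariates are
  excluded from meta-analysis and flagged.
* **Finite-bootstrap test calibration.** The heterogeneity Wald statistic
  uses a covariance estimated from $B$ bootstrap draws. Referred to
  $\chi^2_{K-1}$ it is anticonservative at practical $B$; the package uses
  the Hotelling-type $F$ calibration
  $T\,(B-K+1)/\{(B-1)(K-1)\} \sim F_{K-1,\,B-K+1}$, which converges to the
  $\chi^2$ reference as $B \to \infty$. This is exact when the bootstrap
  draws are Gaussian and the effect estimate is independent of the
  covariance estimate, and is verified by simulation in the test suite.
* **Extreme-level guard.** A tested quantile level needs
  $n\min(\tau, 1-\tau) \ge 30$ expected observations beyond it; levels
  failing the bound are dropped with a warning.

## The Gaussian-likelihood comparator

`fit_warped()` estimates $\lambda_0$ by maximizing the profile Gaussian
log-likelihood with its Jacobian term,
$-\tfrac n2 \log \mathrm{RSS}(\lambda) + (\lambda - 1)\sum_i \log y_i$,
with coefficients and residual variance profiled out analytically. It shares
the SIQReg search scheme so head-to-head comparisons isolate the criterion,
not the optimizer; the grid stage is global because concavity in $\lambda$
is not guaranteed. It is the efficient choice under Gaussian latent errors
and is biased under heavy tails — the contrast the simulations quantify.

## What the generator emulates — and what it does not

`sim_scenario()` draws $G \sim \mathrm{Binomial}(2, \mathrm{maf})$, standard
normal covariates, and latent errors that are Gaussian, Student-$t$ (heavy
tails), or genotype-heteroscedastic
($\varepsilon = e^{\gamma G} z$, which creates *genuine* quantile-dependent
genetic effects on the latent scale). The observed phenotype is the inverse
Box-Cox image $y = (1 + \lambda_0 y^*)^{1/\lambda_0}$.

Two generator choices matter and are deliberate:

* **Intercept placement.** The inverse transform only exists where
  $1 + \lambda_0 y^* > 0$. The default intercept puts that boundary four
  latent standard deviations from the mean: far enough that violations are
  rare (they are handled by redrawing the error term, up to 100 rounds, with
  the count reported; a scenario more than 10% infeasible on the first draw
  is rejected), close enough that the observation map stays visibly
  nonlinear over the latent range — the regime in which the scale is
  actually identified. A much larger margin makes the map locally affine,
  under-identifying $\lambda_0$ for *every* estimator. With heavy-tailed
  errors the rare boundary redraws slightly skew the realized error
  distribution, which is precisely the kind of perturbation a Gaussian
  likelihood is sensitive to and a quantile criterion is not.
* **Effect sizes.** The calibration and power harnesses default to a strong
  covariate ($\alpha = 2$) and a visible genetic effect
  ($\beta_G = 0.8$ where heterogeneity signals are the point,
  $\beta_G = 0.3$–0.5 elsewhere), mirroring the design principle that
  covariates carry more variance than any single genetic predictor and that
  the scale parameter is estimated from covariates, then applied to genetic
  analyses.

The generator does **not** emulate linkage disequilibrium, relatedness,
multi-locus architectures, covariate measurement scales, or non-continuous
phenotypes. Passing simulations therefore demonstrate the estimator's
statistical behavior under its own model class, not performance on any real
cohort.

At $\lambda_0 = 0$ with *symmetric* latent errors the exponential
observation map produces no residual skew on any candidate scale, and the
Gaussian-likelihood estimator is consistent there even under heavy tails;
the robustness contrast between the two estimators is accordingly evaluated
at $\lambda_0 \in \{-0.5, 0.5, 1\}$, where the feasibility boundary exists
and the heavy-tail bias mechanism operates.

Two further family-level facts shape the study designs. First, the
additive-power comparison uses Gaussian latent errors: at $\lambda_0 = 0$
the default-scale phenotype is the exponential of the latent one, and
$e^{t}$ has infinite mean for a Student-$t$ variate of any degrees of
freedom, so with heavy-tailed latent errors the default-scale least-squares
t-test has no valid null at any sample size; Gaussian errors keep every
scale's null valid while lognormal-style noise still penalizes the default
scale. Second, within this generator the latent marginal is near-Gaussian
(Gaussian covariates and errors) or non-Gaussian only in the tails
(Student-$t$), so the rank-inverse-normal transformation is close to an
affine map and its well-known pathologies — inflated heterogeneity tests,
U-shaped effect profiles — though real, are weak: resolving them reliably
needs either far larger samples and replicate counts than the packaged
studies run, or the strongly bimodal covariate structure (e.g. sex-mixed
traits) of real phenotypes, which this generator deliberately does not
include. The packaged checks assert the full expected pattern, and the RINT
legs are the ones that can fail at these sizes for exactly this reason.

## Problem sizes

The packaged studies (test suite and `scripts/acceptance.R`) run the four
simulation designs at $n$ = 2,000 with 28–100 replicates per condition and
bootstrap sizes 20–100 (the profile-shape illustration uses a single
$n = 10{,}000$ dataset; the exact-oracle comparison uses instances of
$n$ = 250–450), sized so the full suite completes on one CPU in well under
an hour. All assertions use tolerances that adapt to the Monte-Carlo error
of the chosen replicate count (3 Monte-Carlo SEs for biases, exact central
binomial bands for rejection rates), so the checks remain meaningful at
these sizes; the harness functions default to $n = 10{,}000$ with 500–1,000
replicates for users who want production-scale runs.

## Known limitations

* The scale family is Box-Cox only; traits needing shifts, bounded supports,
  or non-monotone maps are out of scope.
* Estimating the scale and testing heterogeneity on the same sample couples
  the two procedures: the estimated scale partially adapts to the realized
  quantile noise, leaving a slight upward drift in the SIQReg-scale
  heterogeneity test's size at moderate sample sizes with few covariates.
  It shrinks as the covariate information behind the scale estimate grows
  and can be removed entirely by sample splitting, at a power cost.
* Subsampling SEs require each subsample to support the full estimation
  (roughly $n/R \gtrsim 2{,}000$ for typical signal strengths); with weak
  covariates the per-covariate SE can be undefined and the covariate drops
  out of the pooled estimate.
* The one-covariate-at-a-time objective conditions on *all* covariates in
  the quantile-regression design; covariates measured on badly wrong scales
  of their own are not corrected, only conditioned on.
* With a single informative covariate the meta-analysis degenerates to that
  covariate's estimate, and Cochran's Q is undefined.
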