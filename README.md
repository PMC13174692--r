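# siqreg

Scale-independent quantile regression: learn the measurement scale of a
quantitative phenotype from the data, instead of assuming it.

## The problem

Biobank analyses usually take the phenotype on whatever scale the database
provides, but additive genetic and covariate effects are a property of a
*scale*: a trait that is additive on the log scale shows spurious
quantile-dependent effects, variance QTL, and gene–environment interactions
when analyzed raw — and vice versa. `siqreg` assumes a latent phenotype on
which effects are additive,

    y* = G β* + Cᵀα* + ε,     y* = BoxCox(y; λ₀) = (y^λ₀ − 1) / λ₀,

and estimates λ₀ by exploiting the signature of a correct scale: a
predictor's quantile-regression coefficient profile α̂(τ₁), …, α̂(τ_K) is
flat. For each candidate λ in [−5, 5] it fits convolution-smoothed quantile
regression of BoxCox(y; λ) on the covariates at the deciles, forms relative
residuals r*_k = 1 − α̂(τ_k)/ᾱ, and minimizes the Wald objective

    λ̂₀ = argmin_λ  r*(λ)ᵀ Σ(λ)⁻ r*(λ),

with Σ(λ) a multiplier-bootstrap covariance. Per-covariate estimates are
pooled by inverse-variance meta-analysis, and standard errors come from R
disjoint subsamples. The package also provides the quantile-heterogeneity
Wald test on any scale (with the nine-level tail-reaching testing set), a
Gaussian-likelihood comparator estimator (profile log-likelihood plus
Box-Cox Jacobian), the rank-based inverse normal transformation (RINT) and
Anderson-Darling residual diagnostic, and a simulation toolkit that
generates phenotypes from the latent additive model via the inverse Box-Cox
map with Gaussian, Student-t, or genotype-heteroscedastic errors.

It is aimed at statistical geneticists and epidemiologists who analyze
continuous traits and want scale-dependence handled explicitly rather than
by habit (raw vs log vs RINT).

## Worked example

```r
library(siqreg)

# a synthetic trait: additive on the square-root-like scale (lambda0 = 0.5),
# one genotype, two covariates
sc <- sim_scenario(n = 6000, lambda0 = 0.5, beta_g = 0.5, alpha = c(1.5, 1))
d  <- simulate(sc, seed = 7)

est <- estimate_scale(d, "y", c("C1", "C2"), B = 32, R = 5, seed = 1, tol = 0.02)
est
#> SIQReg scale estimate
#>   lambda0 = 0.4967 (SE 0.0342, 95% CI [0.4296, 0.5637])
#>   H0: lambda0 = 1: z = -14.705, p = 5.96e-49
#>   Anderson-Darling residual A^2: default 10.09 -> siqreg 0.51
#>   2 covariate(s), 2 informative
```

The pooled estimate recovers the generating exponent (0.497, CI covering
0.5), decisively rejects the default scale (λ₀ = 1), and the residual
normality diagnostic collapses once the phenotype is re-expressed on the
estimated scale. `tidy(est)` gives the per-covariate estimates, `glance(est)`
the one-row summary, `autoplot(est)` the objective traces.

Testing a predictor for quantile-dependent effects on a chosen scale:

```r
het <- quantile_het_scan(d, "y", "G", covariates = c("C1", "C2"),
                         scale = "boxcox", lambda = est$lambda_hat,
                         B = 200, seed = 2)
glance(het)
#> # A tibble: 1 x 5
#>   statistic    df p_value scale         k_taus
#>       <dbl> <int>   <dbl> <chr>          <int>
#> 1      1.63     8   0.991 boxcox(0.497)      9
```

On the estimated scale the additive genotype shows no quantile-dependent
effect (p = 0.99); the same scan with `scale = "default"` rejects
(p = 0.013), illustrating a pure scale artifact.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/siqreg.R simulate --n 6000 --lambda0 0.5 --beta-g 0.5 \
    --alpha 1.5,1 --seed 7 --output trait.tsv
Rscript inst/cli/siqreg.R estimate-scale --input trait.tsv --phenotype y \
    --covariates C1,C2 --bootstrap 32 --subsamples 5 --seed 1 --output scale.tsv
Rscript inst/cli/siqreg.R het-test --input trait.tsv --phenotype y \
    --predictor G --covariates C1,C2 --scale boxcox --lambda 0.5 --output het.tsv
```

Every output TSV carries a `.json` sidecar with the full configuration,
seed, and package version.

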