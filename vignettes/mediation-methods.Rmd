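---
title: "Generalized mediation analysis for multivariate omics data: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized mediation analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipath)
```

## The causal model

medipath analyzes studies in which a treatment $T$ may influence outcomes
$Y \in \mathbb{R}^J$ both directly and through a set of mediators
$M \in \mathbb{R}^K$, with pretreatment covariates $X \in \mathbb{R}^P$
feeding both regressions.  The motivating settings are microbiome
experiments: IBD status acting on a metabolome through microbial community
composition, or a mindfulness intervention acting on gut community
composition through diet and sleep behavior.  Unlike classical mediation
tooling, both $M$ and $Y$ may be multivariate and high-dimensional, and the
two regressions are interchangeable "model families".

In counterfactual notation, $M(t)$ is the mediator vector under treatment
$t$ and $Y(t, M(t'))$ the outcome when the direct path receives $t$ while
the mediators are held at their potential values under $t'$.  Only
$t = t'$ is ever observed; the cross-world quantities are model-derived.
For a contrast between treatment levels $a$ and $b$ the package estimates:

* **overall indirect effect** per outcome:
  $\tfrac{1}{2}\sum_{t \in \{a,b\}}
  \mathrm{mean}_i\left[\hat Y_i(t, \hat M_i(a)) - \hat Y_i(t, \hat M_i(b))\right]$,
* **direct effect** per outcome:
  $\tfrac{1}{2}\sum_{t' \in \{a,b\}}
  \mathrm{mean}_i\left[\hat Y_i(a, \hat M_i(t')) - \hat Y_i(b, \hat M_i(t'))\right]$,
* **pathwise indirect effect** per mediator–outcome pair, which moves only
  mediator $k$ between its $a$- and $b$-counterfactuals while the remaining
  mediators stay at their $t'$-counterfactuals.

These are plug-in estimators: counterfactual expectations are replaced by
averages of fitted-model predictions under constructed treatment profiles.
The mediators passed into the outcome model are the *predicted* means
$\hat M(t)$, not resampled draws, so with linear families the estimators
reduce exactly to products and sums of fitted coefficients
(indirect $= \sum_k \hat\alpha_k \hat\beta_{kj}$, direct $= \hat\gamma_j$);
stochastic propagation is available separately through
`sample_counterfactual()`.  Two exact identities hold by construction and
are enforced in the test suite: total $=$ direct $+$ indirect for *any*
family, and pathwise effects summing to the overall indirect effect for
additive linear outcome models.

Identification rests on sequential ignorability: treatment and mediator
assignment must be as-if random given $X$, and no unmeasured variable may
confound the mediator–outcome relation.  These assumptions are untestable;
the sensitivity module quantifies how conclusions degrade as they fail.

## Model families

Every family implements `fit`, `predict`, `sample`, and `residual_scale`,
and any family can serve on either side of the graph:

| family | fit | noise model | notes |
|---|---|---|---|
| `family_linear()` | per-response OLS (QR; minimum-norm fallback) | Gaussian, $\hat\sigma$ from residuals ($n-\mathrm{rank}$) | reference implementation; exact closed forms |
| `family_regularized()` | glmnet lasso/ridge, one shared $\lambda$ | Gaussian | objective $\sum_i (y_{ij} - x_i'\beta_j)^2 + \lambda P(\beta_j)$, intercept unpenalized; `lambda = "auto"` = 5-fold CV on squared error pooled over responses with a fixed fold seed, selected value recorded; `penalty_mask` exempts chosen columns (e.g. shrink only participant intercepts) |
| `family_random_forest()` | one ranger forest per response | Gaussian at OOB residual scale | explicit seed required; detects nonlinear signal |
| `family_lnm()` | logistic-normal multinomial MAP | multinomial at supplied/training depths | see below |
| `family_hurdle()` | logistic presence $\times$ lognormal magnitude | two-part | for zero-inflated intensities |

The hierarchical-Bayesian families of the broader literature are realized
here as penalized-likelihood/MAP analogues (ridge $=$ Gaussian-prior MAP,
hurdle $=$ two-part maximum likelihood): point estimation is all the
plug-in effect estimators consume, and this keeps the package free of an
MCMC engine.

### The logistic-normal multinomial family

Taxonomic counts $Y_i \in \mathbb{N}^J$ with depth $N_i$ are modeled as
$Y_i \sim \mathrm{Mult}(N_i, \varphi^{-1}(B z_i))$ where
$z_i = (1, T_i, M_i, X_i)$, $B \in \mathbb{R}^{(J-1) \times D}$, and
$\varphi^{-1}$ is the inverse additive-logistic map (last taxon as
reference), computed with max-subtraction so extreme latent values saturate
without overflow and outputs are clamped strictly positive.  Every entry
of $B$ carries an independent $N(0, \sigma^2)$ prior; the MAP estimate
maximizes the penalized multinomial log-likelihood by BFGS with analytic
gradients.  Defaults that the problem does not pin down and that are
therefore exposed in the constructor: $\sigma^2 = 1$, gradient max-norm
tolerance $10^{-6}$ (scaled by the per-sample depth, and damped by
$\min(1, \sigma^2)$ so that prior-dominated fits are judged by the Newton
step rather than the raw gradient), up to six BFGS restarts before a
convergence error that reports the gradient norm.  With a diffuse prior
and intercept only, the fitted composition equals pooled empirical
proportions; with $J = 2$ the family reduces to penalized logistic
regression — both are exploited as independent oracles in the tests.

## Uncertainty

**Bootstrap.**  Rows (whole samples) are resampled with replacement,
both submodels refit, and user statistic functions re-evaluated; percentile
intervals plus the inner 66% interval are reported, and the full replicate
matrix is kept so the histogram can be inspected before the intervals are
trusted.  Resampling is unstratified by default (a `stratify` flag guards
tiny arms).  Replicates whose refit fails are dropped and counted; more
than 10% failures aborts.

**Synthetic-null FDR calibration.**  `nullify()` removes the edge
`T->M`, `T->Y`, or `M->Y`; re-estimating and ancestrally sampling from the
masked model at the observed $T, X$ yields negative-control data.  For
matched per-feature statistics $\hat\theta^1$ (real) and $\hat\theta^0$
(synthetic null), every pooled absolute value is a candidate threshold and

$$\widehat{\mathrm{FDR}}(t) =
\frac{\#\{d: |\hat\theta^0_d| > t\}}
     {\#\{d: |\hat\theta^0_d| > t\} + \#\{d: |\hat\theta^1_d| > t\}},$$

with $0/0 := 0$ and strict inequalities; the selection threshold is the
smallest $t$ with $\widehat{\mathrm{FDR}}(t) \le q$.  The per-feature
curve reported alongside applies a running minimum from the largest
threshold downward (a q-value-style monotonization); the raw values are
retained in the `thresholds` attribute.

*Known limitation.*  This estimator carries no finite-sample offset in its
numerator.  In the extreme tail the event "the largest pooled statistic is
real" occurs with probability about one half under an exchangeable global
null, and then $\widehat{\mathrm{FDR}} = 0/1$ licenses selecting that
single feature.  Consequently the realized false discovery proportion
under a *complete* null is near $1/2$ regardless of $q$; the rule is
informative about the bulk of the ranking, not about lone extreme
features.  Analysts should treat single-feature selections at the very
top of the ranking with caution, or harden the rule themselves by adding
1 to the numerator counts (the knockoff-plus correction) before
thresholding.

**Sensitivity analysis.**  Unmeasured mediator–outcome confounding is
emulated by correlated noise: draw
$(\epsilon_m, \epsilon_y) \sim N(0, \Sigma(\rho, G))$ where the diagonal
blocks are the fitted residual variances and the off-diagonal block is
$\rho\, \hat\sigma_M \hat\sigma_Y^{\top}$ masked to the mediator–outcome
pairs $G$ under scrutiny, form $M^* = \hat M(T_{\mathrm{obs}}) + \epsilon_m$
and $Y^* = \hat Y(T_{\mathrm{obs}}, M^*) + \epsilon_y$, refit both
submodels, and recompute indirect effects.  Refitting (rather than merely
re-evaluating plug-in contrasts) is the implemented interpretation: it is
the only one under which confounding actually biases the estimator, with
the classical omitted-variable drift
$\hat\beta \to \hat\beta + \rho \hat\sigma_Y / \hat\sigma_M$ in the
single-pair linear case serving as a closed-form oracle.  Every
$\Sigma$ is eigenvalue-checked before sampling; non-PSD grid points are
rejected with a diagnostic (dense $G$ patterns lose positive
semidefiniteness well below $|\rho| = 1$, one reason to keep $G$ small).
The generalized sweep `sensitivity_perturb()` uses
$\Sigma(\Delta, \nu) = \mathrm{diag}(\hat\sigma_M^2, \hat\sigma_Y^2) + \nu\Delta$
for arbitrary symmetric patterns, including cross-mediator correlation
(which leaves linear-additive indirect estimates unbiased in expectation —
also tested).  Defaults: 20 replicates per grid point, $\rho$ grid
$0, \pm 0.1, \dots, \pm 0.9$ intersected with the PSD-feasible region, and
the $\rho = 0$ anchor always present.  Families without additive Gaussian
residuals (LNM, hurdle) are refused with a capability error rather than
given a misleading latent-scale sweep.

## Preprocessing transforms

`clr()` is the centered log-ratio ($\log x_d - \overline{\log x}$ per
row; rows sum to zero to $10^{-10}$).  Zeros require an explicit
pseudocount (default 0.5, the conventional half-count for counts; for
already-relative data the default is an error, since an imputation scale
cannot be guessed).  `filter_by_mean()` keeps features whose mean
*transformed* value strictly exceeds a threshold — strictly, because the
rule it mirrors is phrased as "larger than" — on whatever transform the
caller applied, and `filter_by_prevalence()` keeps features present
(count $> 0$) in at least the given fraction of samples (the
core-microbiome rule; 0.4 in the motivating cohort), reporting the
per-sample fraction of reads the retained features preserve.

## The synthetic-data generator

`simulate_mediation()` draws $X \to T \to M \to Y$ ancestrally with known
coefficients, so every dataset ships with a closed-form truth table
(indirect $= d\sum_k\alpha_k\beta_{kj}$, direct $= d\gamma_j$ for a
treatment-score difference $d$).  Treatments may be binary (default
assignment probability 0.5, the randomized-trial setting), multilevel
with per-level scores, or continuous.  Mediators are Gaussian — mirroring
survey scores and CLR-transformed abundances, which are continuous —
while outcomes may be Gaussian, compositional (latent Gaussian predictor
through $\varphi^{-1}$, multinomial counts at Poisson depths, mean 5000,
the scale of a shallow shotgun or deep 16S library), or zero-inflated
(Bernoulli presence times lognormal magnitude).  Optional
`confounder_rho` injects true mediator–outcome noise correlation so that
the omitted-variable bias the sensitivity module probes can be produced
for real, linking the generator and the sensitivity oracle.  Default
noise scales are 1 (unit-variance errors against order-one coefficients,
i.e. moderate signal-to-noise).  What the generator does *not* emulate:
phylogenetic or co-abundance correlation between taxa, longitudinal
dependence, batch effects.  Passing tests therefore certify estimator
logic and calibration under the stated model, not robustness to those
real-data features.

The fixed fixtures (`make_toy_fixture()`) pin the configurations used
throughout the tests and scripts: the `chain` ($M = 2T + \epsilon$,
$Y = 3M + T + \epsilon$, truths $6$ and $1$), `two_path`
($\alpha = (2,-1)$, $\beta = (3,4)$, pathwise truths $6$ and $-4$),
`null`, and a five-taxon `compositional` fixture.

## Numerical and design notes

* Categorical treatments are stored as factors with an explicit,
  overridable reference level (default: lexicographically first observed);
  contrasts always name levels, and effects are reported per named
  contrast pair, by default every level against the reference.
* Effect tables retain the two per-regime components, which differ under
  nonlinear families; the `estimate` is their mean.
* Missing values in any role block are rejected at construction rather
  than imputed; each input row is one analysis unit, and aggregation of
  technical replicates belongs upstream.
* Rank-deficient linear designs warn and fall back to the minimum-norm
  (pseudoinverse) solution rather than erroring: constant covariates and
  collinear mediators occur routinely in practice.
* All samplers demand an explicit seed and restore the caller's RNG
  state; identical seeds give identical draws everywhere, which the
  pipeline relies on for byte-identical reruns.
* Problem sizes in the shipped checks were chosen to make Monte-Carlo
  tolerances meaningful on a single CPU: parameter recovery at
  $n = 2000$ over 100 repeats, bootstrap coverage at $n = 150$ with
  $B = 1000$ over 200 repeats, global-null FDR calibration with $D = 200$
  outcomes over 100 repeats, sensitivity sweeps with 40 replicates per
  grid point at $n = 400$.

## A worked sketch

```{r example, eval = FALSE}
fx <- make_toy_fixture("chain", n = 500, seed = 1)
model <- estimate(multimedia(fx$data), fx$data)
indirect_overall(model, fx$data)   # estimate near the truth 6
direct_effect(model, fx$data)      # estimate near the truth 1

boot <- bootstrap(model, fx$data,
                  list(indirect = function(m, d) indirect_overall(m, d)$estimate),
                  B = 1000, seed = 2)
boot$ci

null_fit <- estimate(nullify(model, "T->Y"), fx$data)
nd <- synthetic_null_data(null_fit, fx$data, seed = 3)
```
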