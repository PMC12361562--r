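---
title: "Pooling flourishing networks across countries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling flourishing networks across countries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flournet)
```

flournet studies how the twelve items of the Secure Flourish Measure (SFM)
hang together as a *network* — a Gaussian graphical model (GGM) whose edges
are partial correlations — and how that network varies across country
samples. This vignette explains the statistical machinery, the choices
behind its defaults, and what the synthetic-data experiments do and do not
establish.

## The data and the preprocessing contract

The unit of analysis is a per-country respondent table: one row per person
with a sample weight and the 12 items on 0–10 scales. Preprocessing is
deliberately minimal and mirrors common practice for these surveys:

* **Listwise deletion.** Any respondent missing any of the 12 items is
  dropped (`listwise_complete()`). Missingness in this instrument is
  typically well below 2%, so the completeness screen costs little; no
  imputation or pairwise option is offered.
* **Weighted correlations.** Each country's correlation matrix is the
  sample-weighted Pearson matrix (`weighted_correlation_matrix()`), with
  weights normalized to mean 1. Correlations are invariant to rescaling
  all weights, and equal weights reduce exactly to the unweighted matrix.
* **Effective sample size.** Likelihoods use the nominal complete-case
  count. Published analyses of this design report nominal Ns and
  chi-square magnitudes consistent with them. The Kish effective size
  $(\sum w)^2 / \sum w^2$ is available behind `kish = TRUE` for
  sensitivity analysis; it is always smaller, so it yields more
  conservative tests.

Items are treated as continuous. Eleven-point scales are commonly analysed
this way; an integer-rounding stress mode (`discretize = TRUE`) exists to
probe that assumption.

## Competing measurement models

Before interpreting a network it is worth asking whether a latent-variable
account explains the item covariance better.
`compare_measurement_models()` fits six models to one correlation matrix
by maximum likelihood and ranks them by AIC:

| model | structure | free parameters (12 items) |
|---|---|---|
| `cfa6` | six correlated factors, two indicators each | 39 (df 39) |
| `bifactor` | six specific factors + one orthogonal general factor | 36 (df 42) |
| `second_order_g` | a second-order factor over the six | 30 (df 48) |
| `latent_network` | six factors whose correlation matrix is a saturated latent GGM | 39 (df 39) |
| `residual_network` | one general factor + GGM over residuals | pruned to identification |
| `ggm` | saturated 12-node partial-correlation network | 78 (df 0) |

All models fix factor variances at 1 for identification. Fitting minimizes
the ML discrepancy $F = \log|\Sigma| - \log|S| +
\operatorname{tr}(S\Sigma^{-1}) - p$ by box-constrained quasi-Newton
optimization (`L-BFGS-B`, variances bounded below by $10^{-6}$,
correlations by $\pm 0.999$) from five deterministic starting points:
analytic starts derived from within-domain correlations, plus seeded
multiplicative jitter. Inadmissible parameter points (non-PD implied
matrices) receive a finite penalty rather than an error, so the optimizer
can retreat from them. Convergence is flagged when the projected gradient
norm exceeds $10^{-3}$ or starts disagree by more than $10^{-4}$ in $F$.

Two structural facts the code exploits and the tests verify:

* The **saturated latent network is a reparameterization of the correlated
  six-factor CFA** (the latent partial correlations are a bijection of the
  factor correlations), so both must attain the same minimum. The latent
  network is therefore seeded with the transformed CFA solution; the suite
  checks agreement within $10^{-2}$ chi-square units.
* A **saturated residual network under a single factor is not
  identified** (90 parameters against 78 moments). `flournet` prunes
  residual edges stepwise — first to the strongest edges that leave
  spare degrees of freedom, then removing edges failing a partial-
  correlation test at $\alpha = 0.05$ — and reports the pruning trail in
  the convergence messages instead of pretending the model converged
  cleanly. This model family is known to be fragile here, and the report
  says so.

AIC and BIC use the full Gaussian log-likelihood (with the
$p\log 2\pi$ constant), so magnitudes are comparable across models.
Incremental indices (NFI, RFI, TLI, CFI) use the independence model
(diagonal covariance, df 66) as the shared baseline; RMSEA's 90% CI
inverts the noncentral chi-square distribution.

## The network model and its primitives

For multivariate-normal data the GGM's edge weights are partial
correlations: with $K = R^{-1}$,
$\omega_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}$ (`pcor_from_corr()`). The
inverse map (`corr_from_pcor()`) standardizes $(I - \Omega)^{-1}$; the
pair round-trips to $10^{-10}$, which the suite checks on random matrices.

Per-country edges are screened with the classical partial-correlation
t-test ($t = \omega\sqrt{(n - 2 - k)/(1 - \omega^2)}$, $k = 10$
conditioned variables). This closed form is asymptotically equivalent to
information-matrix standard errors at survey-scale $n$ and keeps
single-country thresholding deterministic; model-based SEs are used where
the pooled analysis genuinely needs them (below). Thresholding at
$\alpha = 0.05$ zeroes non-retained edges **without refitting** the
survivors — the retained weights are the original estimates. A
prune-and-refit variant exists but is off by default.

Centrality uses two complementary indices:

* **Expected influence**: the signed sum of a node's edge weights.
* **Predictability**: the variance of a node explained by all others,
  $R^2_i = 1 - 1/K_{ii}$, identical to the $R^2$ of regressing node $i$
  on the rest.

Predictability is always computed from the *unthresholded* estimated
structure. It is a property of the estimated joint distribution, and a
thresholded weight matrix need not correspond to any admissible
distribution (zeroing edges can push $I - \Omega$ outside the positive-
definite cone); expected influence, by contrast, respects the thresholded
display by default.

## Random-effects pooling (MAGNA)

To pool $C$ country networks, each country contributes its vector
$y_c$ of 66 sample correlations with analytic sampling covariance
$V_c = V(\rho)/n_c$, where $V(\rho)$ is the Isserlis/Pearson–Filon
covariance of Pearson correlations evaluated at the pooled estimate. The
random-effects model is

$$y_c \sim N\!\big(\rho,\; V_c + T\big), \qquad T = \mathrm{diag}(\tau^2),$$

with $\rho$ the pooled fixed-effect correlations and $\tau_j$ the
between-country SD of edge $j$'s marginal correlation over and above
sampling noise. Implementation choices, in order of consequence:

* **Two-stage marginal formulation.** Working from per-country
  correlation matrices and their analytic sampling covariances (rather
  than a one-stage full-information fit over raw data) is deterministic,
  fast at desk scale, and asymptotically equivalent; small numeric
  differences from a full-information fit are expected and documented,
  not reconciled.
* **Diagonal $T$.** Only the per-edge random-effect SDs are
  interpreted; a full 66×66 between-country covariance is hopelessly
  unidentified at $C \approx 22$.
* **Raw correlation scale.** Pooling averages sample correlations
  directly; `fisher_z = TRUE` offers the variance-stabilized alternative.
* **Profiled estimation.** For fixed $\tau$, the optimal $\rho$ is the
  closed-form GLS average, so the likelihood is profiled and maximized
  over $\tau$ alone (L-BFGS-B, $\tau \ge 0$) with the analytic gradient
  $\partial \ell / \partial \tau_j = \tau_j \sum_c [(W_c r_c)_j^2 -
  (W_c)_{jj}]$. Zero estimates are reported as boundary notes, not
  errors. The moment start ($\tau_0^2$ = between-country variance minus
  mean sampling variance, truncated at zero) is already close to the
  optimum in practice.
* **Outer iteration.** $V(\rho)$ is re-evaluated at the current pooled
  estimate and the fit repeated until $\rho$ moves less than $10^{-7}$
  (at most 3 rounds; 2 suffice in every test).
* **PD safeguard.** The GLS average occasionally needs projection to the
  positive-definite cone (eigenvalue floor $10^{-6}$, rescale to unit
  diagonal); when that happens it is recorded in the convergence report.

The pooled network is $\Omega(\hat\rho)$; its edge covariance comes from
the delta method through the correlation-to-partial-correlation map
(numeric Jacobian, central differences at $10^{-6}$), giving per-edge SEs,
Wald 95% CIs, normal p-values, and thresholding at $\alpha = 0.05$.

Heterogeneity is screened first by `fit_saturated_models()`: every
country keeps its own saturated structure versus one common structure
(whose ML estimate is the $n$-weighted average matrix), compared by AIC
and BIC. Preferring the single-country model licenses the random-effects
step.

## The parametric bootstrap for centrality differences

`bootstrap_centrality_difference()` draws $B$ edge-weight vectors from
$N(\hat\omega, \hat\Sigma_\omega)$, recomputes both centrality indices per
draw (predictability through the implied correlation matrix of each drawn
network; inadmissible draws are skipped), and for each node pair reports
$p = 2\min(\Pr(\Delta < 0), \Pr(\Delta > 0))$, capped at 1. Zero
proportions are reported as $2/B$ — the resolution limit — rather than 0.
The default significance level divides 0.05 by the 66 node pairs and
rounds to 4 decimals (0.0008). The reference setting is $B = 10^6$; the
test suite runs at $B = 10^4$–$10^5$, where the Monte-Carlo SE of a
p-value near the threshold is below $10^{-3}$. Draws default to centering
on the unthresholded pooled edges (`use_thresholded = FALSE`), since the
sampling distribution belongs to the estimator, not to the display rule.

## What the synthetic generator emulates

`simulate_study()` is the package's ground-truth instrument, not a
fixture. Its defaults are the study conditions of the cross-national
flourishing analysis it is designed to emulate:

* 22 countries at the published sample sizes (1,473 to 38,312; 202,898
  in total);
* a pooled 12-node network defaulting to the published pooled edge
  weights (`pooled_truth("reported")`);
* per-edge random effects applied **on the marginal-correlation scale**
  — heterogeneity is reported for unconditional associations, so that is
  the scale on which the generator perturbs — with default SD
  $\tau = 0.12$ (the average reported heterogeneity; the reported range
  is 0.08–0.19);
* MCAR missingness drawn per country from the observed 0.1–1.7% range;
* log-normal weights with log-SD 0.5, normalized to mean 1 — a typical
  dispersion for post-stratification weights; the real weighting scheme
  is not public, so this is a declared stand-in.

Perturbed matrices are projected to the nearest positive-definite
correlation matrix (eigenvalue clipping at $10^{-6}$, rescale to unit
diagonal; idempotent on admissible input, distance logged). Around the
reported network — which contains marginal correlations up to 0.73 — a
$\tau = 0.12$ perturbation of all 66 edges usually leaves the PD cone, so
projection engages routinely there and shrinks realized heterogeneity
mildly: at the default conditions the realized per-edge SD is about
0.113 rather than 0.120, and recovery experiments measure estimates of
the *realized* spread. On sparser, weaker networks projection engages for
under 1% of draws and the realized SD matches $\tau$ to Monte-Carlo
accuracy, which the suite verifies.

What passing recovery tests shows: the estimator chain (weighted
correlation → GLS/ML pooling → delta-method CIs) is consistent and
approximately calibrated under multivariate-normal data with MCAR
missingness and ignorable weights. What it does not show: robustness to
ordinal measurement, informative weighting, non-MCAR missingness, or
response styles — none of which the generator emulates.

## Problem sizes and seeds in the shipped experiments

The test suite fits full-scale studies (22 countries, published Ns) in
about a second per replication; the recovery experiment uses 100
replications at $\tau = 0.12$, checking that the mean estimated
random-effect SD lands in [0.10, 0.14] and that 95% CI coverage of the
true pooled edges lies in [0.90, 0.99]. Cross-checks include a univariate
random-effects meta-analysis per edge (metafor) and a nonparametric
bootstrap over countries at $C = 50$ for the delta-method SEs. Monte-Carlo
oracles use 2,000–10,000 draws with tolerances set from their standard
errors. All randomness flows from explicit integer seeds; identical seeds
give bitwise-identical studies.

## Known limitations

* The residual-network model is identified only after pruning; its fit
  depends mildly on the pruning path, which is why its convergence report
  is part of the result rather than a hidden detail.
* Random-effect SDs are ML estimates; with 22 countries they carry a
  small downward bias (order $1/C$), visible but immaterial in the
  recovery experiments.
* The sampling covariance $V(\rho)$ is first-order asymptotic; at country
  sizes in the thousands its error is negligible, but for groups below a
  few hundred respondents a z-scale fit (`fisher_z = TRUE`) is the safer
  choice.
* Printed reference matrices are rounded to 3 decimals; quantities
  recomputed from them (for example a chi-square of a factor model at
  $N \approx 2 \times 10^5$) inherit that rounding, which is why
  comparisons against published fit statistics are made at the precision
  the source prints.
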