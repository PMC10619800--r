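---
title: "Censored QUAIDS estimation: model, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored QUAIDS estimation: model, corrections, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censquaids)
```

## The problem

Household budget surveys record, for each household, the expenditure and
quantity of each food category acquired during a short diary window.
Demand-system estimation turns these records into price and expenditure
elasticities. Two features of diary data dominate the econometrics:

* **Zero purchases.** A household that buys soda every month may still
  record none in its diary week. Treating observed zeros as zero latent
  demand biases every equation of the system.
* **Endogenous total expenditure.** The shares are modelled conditional
  on total food expenditure `m`, but `m` is chosen jointly with the
  shares; unobserved taste shocks move both.

`censquaids` implements a Quadratic Almost Ideal Demand System (QUAIDS)
with the standard two-step probit correction for zero purchases
(Shonkwiler–Yen) and the residual-inclusion control for expenditure
endogeneity (Blundell–Robin).

## Model

The latent budget share of category $i$ for household $h$ is

$$\tilde w_{ih} = \alpha_i + \sum_j \gamma_{ij}\ln p_{jh}
  + \beta_i x_h + \frac{\lambda_i}{b(p_h)}\, x_h^2,
  \qquad x_h = \ln\!\frac{m_h}{a(p_h)},$$

and the estimated equation for the observed share is

$$w_{ih} = \Phi_i(z_h)\,\tilde w_{ih} + \theta_i \hat v_h
  + \rho_i\,\phi_i(z_h) + \xi_{ih},$$

where $\Phi_i$, $\phi_i$ are the cdf and pdf of a per-category probit of
the purchase decision on the household price index and sociodemographic
covariates, and $\hat v_h$ is the residual of an OLS regression of
$\ln m_h$ on household characteristics. The quadratic term lets a
category shift between luxury and necessity across the expenditure
distribution; $\lambda_i = 0$ for all $i$ collapses the model to the
almost ideal demand system (AIDS).

### Price indices

* $a(p)$ is a **Törnqvist index**:
  $\ln a(p_h) = \sum_i \tfrac12 (w_{ih} + \bar w_i)(\ln p_{ih} - \ln \bar p_i)$,
  with base prices $\bar p$ the cross-household geometric mean of
  post-imputation unit values. The geometric-mean base is a choice the
  data do not dictate; it is the standard normalization for
  translog-type indices and makes log-price deviations mean-centred, so
  the index is exactly 1 for a household facing average prices.
* $b(p)$ has two modes. The **exact** mode is the Cobb–Douglas QUAIDS
  aggregator $\ln b = \sum_i \beta_i \ln p_{ih}$, recomputed from the
  current $\beta$ during estimation; this is the default inside
  `nlsur_fit()` because it is the aggregator under which the quadratic
  term has its structural interpretation. The **approximate** mode is
  the parameter-free deviation-weighted companion of the Törnqvist
  index, $\ln b = \sum_i \tfrac12 (w_{ih} - \bar w_i)(\ln p_{ih} - \ln \bar p_i)$,
  computable before any estimation. Both are exposed (`b_mode`), and all
  reports record which was used.

### Unit values and price imputation

Prices are household-level unit values: within a household–category, the
expenditure-share-weighted mean of per-record unit prices (a single
record reduces to expenditure over quantity). Cells without purchases
are imputed from the mean observed unit value in the household's state,
falling back to the region and then the national mean (the fallback
chain guarantees completeness on small samples; the level used is
recorded per cell). Imputation never alters an observed unit value. An
alternative construction (`state_prices = TRUE`) replaces *all*
household prices with state averages, which is how some studies define
the price variable; the default keeps observed household unit values.

## Estimation

Given the indices, the system is linear in
$(\alpha, \gamma, \beta, \lambda, \theta, \rho)$, so NLSUR reduces to
iterated feasible GLS:

1. solve the restricted linear GLS problem exactly at the current
   residual-covariance weighting (restrictions — homogeneity, symmetry,
   latent adding-up — are imposed by null-space reparameterization);
2. update the cross-equation residual covariance $\hat\Sigma$ from the
   residuals and, in exact mode, refresh $b(p)$ from the current
   $\beta$; repeat until the largest parameter change is below `tol`
   (default `1e-6`, `max_iter = 500`).

Initialization is immaterial for the linear solves; $b$ starts at
$\beta = 0$, i.e. $b \equiv 1$.

Two numerical safeguards matter in practice:

* **Spectrum floor.** Residuals of a full share system sum to (nearly)
  zero across equations, so $\hat\Sigma$ is singular or nearly so. Its
  eigenvalues are floored at $10^{-6}$ of the largest before inversion.
  Unbounded weights would otherwise let the iteration chase collapsing
  variance directions — iterated FGLS is asymptotically a Gaussian MLE,
  which legitimately rewards shrinking $|\hat\Sigma|$.
* **Capped weight refinement.** In large systems the probit cdf and pdf
  of high-prevalence categories are nearly constant columns, making
  $\alpha_i$ and $\rho_i$ weakly identified; along such flat directions
  the FGLS map need not contract, and the iteration can wander
  indefinitely at a small amplitude. The covariance (and exact-mode
  $b$) refinements are therefore capped at `weight_updates` (default
  50); once the weighting has stabilized — or the cap is reached — it is
  held fixed and the restricted GLS solve closes exactly at it. The
  resulting multi-step feasible GLS estimator is asymptotically
  equivalent to the fully iterated one; well-conditioned systems
  stabilize long before the cap and are unaffected (the 4-category
  scenarios below converge in under 20 iterations).

With no censoring correction, no residual term and $\lambda \equiv 0$,
each step is textbook linear SUR, and the test-suite checks the solution
against an independently coded restricted GLS.

### Which equations are estimated

The censoring correction breaks adding-up of observed shares, so the
coherent default estimates **all** $n$ equations jointly. A
`drop_reference` option instead drops the residual ("other foods")
equation and recovers its latent parameters from the adding-up
identities (and its $\gamma$ row from homogeneity plus symmetry). The
recovery experiment uses the drop-reference path deliberately: the
residual category absorbs the budget not spent on censored goods, so its
equation does not have the cdf-scaled form the other equations have, and
keeping it in a joint GLS with symmetry ties would leak that
misspecification into the correctly specified equations. The default
no-drop fit remains available and exercised, but parameter recovery
should be judged on the drop-reference configuration.

### Restrictions

Homogeneity and symmetry are imposed by default; latent adding-up
($\sum_i \alpha_i = 1$, $\sum_i \beta_i = \sum_i \lambda_i = 0$, zero
column sums of $\gamma$) is imposed by default only for uncensored
systems, where it is the exact sample identity. All three are switchable,
and the restriction record travels with the fitted object.

### Covariance

The parameter covariance is the GLS expression at the final weighting.
It ignores the sampling error of the first-step probits and of the
expenditure regression (the usual two-step plug-in); delta-method
standard errors for elasticities inherit this limitation. The recovery
experiment checks that nominal 95% intervals cover at close to nominal
rates under the default scenario, so the omission is immaterial there,
but it is a known caveat for heavily censored categories.

## Elasticities

Price elasticities are obtained by differentiating the estimated share
system at a representative point:

$$e_{ij} = \frac{\Phi_i \,\partial \tilde w_i / \partial \ln p_j}{w_i}
  - \delta_{ij},
  \qquad
  \frac{\partial \tilde w_i}{\partial \ln p_j} =
  \gamma_{ij} - \Big(\beta_i + \frac{2\lambda_i x}{b}\Big)
  \frac{\partial \ln a}{\partial \ln p_j}
  - \frac{\lambda_i x^2}{b}\,\frac{\partial \ln b}{\partial \ln p_j},$$

with $\partial \ln a/\partial \ln p_j = \tfrac12 (w_j + \bar w_j)$ for
the Törnqvist index and $\partial \ln b/\partial \ln p_j = \beta_j$
(exact mode) or $\tfrac12 (w_j - \bar w_j)$ (approximate mode). The
expenditure elasticity is
$e_i = \Phi_i (\beta_i + 2\lambda_i x / b)/w_i + 1$. Published
closed-form displays of the price-elasticity formula vary (in
particular, printed versions sometimes carry the $2\lambda_i$ term
unscaled by $b$ and mix the index of the translog term); this package
treats the derivative of its own estimated system as definitive — a
property test checks it against central-difference numeric
differentiation to $10^{-6}$ over random draws — and offers
`derivation = "verbatim"` to evaluate the commonly printed display for
comparison.

The **evaluation point** is the vector of (sub)sample means of shares,
log prices, log expenditure and probit cdf, with $\ln a$ and $b$
recomputed *at* those means rather than averaged across households, so
the point is internally consistent with the index definitions and the
analytic/numeric derivative equivalence holds exactly at it. Reported
elasticity matrices are point evaluations, not per-household averages —
one matrix per (sub)sample.

Income-quintile elasticities rank households by reported income (ties
to the lower quintile) and re-evaluate the full-sample parameters at
quintile means; no subgroup re-estimation is performed, matching the
convention of reporting subgroup elasticities from one fitted system.
Significance stars use two-sided normal z-ratios at the 1/5/10% levels.
Tax counterfactuals are first-order:
$\Delta q_i(\%) = \sum_j e_{ij} \Delta p_j(\%)$.

## The synthetic-data generator

`make_default_truth()` + `simulate_purchases()` generate purchase-diary
microdata with the exact statistical structure the estimator assumes:

* 27 synthetic states in 5 regions; log prices vary at the state level
  (household-level price noise is available but defaults to zero, the
  situation in which prices are effectively state-average unit values —
  this also makes geographic imputation exact, so recovery error is
  attributable to the estimator alone);
* a dominant residual category (latent share 0.65, ~99.5% purchase
  prevalence) and censored categories with prevalence targets spanning
  roughly 15–75%, mirroring the shape of real food-category tables where
  the residual group holds ~80% of the budget;
* total food expenditure driven by covariates plus a shock `v`; the
  share-equation error loads on the component of `v` orthogonal to the
  covariates — exactly what a residual-inclusion first stage recovers —
  making the $\theta_i \hat v_h$ term correctly specified in sample;
* per-category purchase censoring from probit latents whose shocks are
  correlated with the share errors with loading $\rho_i$, which yields
  $E[w_i \mid z] = \Phi_i \tilde w_i + \rho_i \phi_i$ *exactly* (the
  structural hurdle model behind the two-step correction); the
  expenditure-shock loading enters on the purchase-conditional scale so
  the $\theta_i \hat v$ term sits outside the $\Phi_i$ bracket exactly
  as estimated;
* the residual category absorbs the budget not spent on censored goods,
  so total observed expenditure equals the drawn total for every
  household that buys it; the rare (~0.5%) households that skip the
  staple category spread their budget proportionally over purchased
  goods — their censoring is covariate-independent by design, so they
  add noise, not confounding;
* the latent-share price index is the same Törnqvist index the pipeline
  will compute from the emitted (censored) data, resolved by fixed-point
  iteration inside the generator, and quantities equal expenditure over
  price so unit values reproduce the generated prices bit for bit.

These choices make the recovery experiment a test of the
*implementation* under the estimator's own assumptions. What the
generator deliberately does **not** emulate: survey sampling weights and
design effects, diary-week mechanics (multi-record items, recall
error), real price levels or inflation adjustment, and
renormalization-induced misspecification beyond the rare
staple-skipping households. Passing recovery therefore says the
estimator and formulas are implemented correctly — not that the model is
correctly specified for any particular real survey.

Default magnitudes: share-equation noise SD 0.012 (scaled down with the
smallest latent share for larger systems, keeping categories off the
zero boundary); expenditure-shock SD 0.45 on log expenditure;
state-level log-price SD 0.12; loadings $\theta_i, \rho_i$ proportional
to category shares (≈0.008 for a 9% category). These are fixed once as
realistic diary-data magnitudes and are not tuned.

## Problem sizes

The test-suite and the acceptance script run the default recovery
scenario at 4 goods × 10,000 households × 20 replicates (about fifteen
seconds), a 14-category pipeline at 4,000 households, and assorted
smaller property checks; these sizes give Monte-Carlo error comfortably
below the tolerances being asserted while keeping the suite quick to
run.

## Degenerate inputs and edge cases

* Probit cdf values are clipped to $[10^{-9}, 1-10^{-9}]$ before use;
  the clip count is recorded. Perfect separation triggers a tiny-L2
  refit, flagged on the result. A category purchased by all (or no)
  households is an error naming the category.
* Households with missing covariates, and households with non-positive
  total food expenditure, are dropped with counts.
* A category with no observed unit value anywhere stops the pipeline
  (no price signal exists for it).
* Rank-deficient probit or expenditure-regression designs error,
  listing the collinear columns.
* Quintiles with fewer than 30 households warn; empty subgroups error.

## Known limitations

* Two-step covariance: first-stage uncertainty is not propagated.
* The $\alpha_i$/$\rho_i$ pair is weakly identified when a category's
  purchase probability varies little across households; their standard
  errors are honest (large), but their point estimates should not be
  over-read — elasticities, which depend on $\gamma$, $\beta$,
  $\lambda$, are well identified in all tested scenarios.
* No compensated (Hicksian) elasticities or welfare measures; the
  first-order tax counterfactual holds expenditure fixed.
* No survey weights: all sample statistics are unweighted.
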