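---
title: "Population pharmacokinetics of high-dose tigecycline: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of high-dose tigecycline: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigepk)
```

## The problem

Tigecycline is used off-label at high dose (a 200-mg loading infusion, then
100 mg every 12 h, each given over 30 min) in intensive-care patients with
sepsis or septic shock, a population whose pathophysiology — capillary leak,
altered protein binding, extracorporeal circuits — can shift both clearance
and distribution volumes away from the values seen in healthier cohorts.
`tigepk` implements the population pharmacokinetic analysis of such a study:
arterial plasma concentrations sampled at 0.5, 2, 4, 8 and 12 h after each
dose in 37 adult ICU patients receiving 2–8 doses each, analysed with a
nonlinear mixed-effects model, and evaluated with the standard pharmacometric
toolkit (conditional weighted residuals, shrinkage, visual predictive checks,
nonparametric bootstrap, empirical-Bayes covariate screening).

Because no patient-level dataset is publicly deposited, the package ships a
synthetic-study generator that reproduces the design and the published
population summaries, so that every stage of the analysis is exercised and
tested end to end on data with known ground truth.

## Structural model

Disposition is two-compartment with zero-order (infusion) input,
parameterized in clearances and volumes: elimination clearance $CL$,
central volume $V_1$, intercompartmental clearance $Q$, peripheral volume
$V_2$. With amounts in mg and volumes in litres, central concentration is
mg/L ≡ µg/ml without conversion factors. Writing $k_{10} = CL/V_1$,
$k_{12} = Q/V_1$, $k_{21} = Q/V_2$, the hybrid rate constants
$\lambda_{1,2}$ are the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$, with
$\lambda_2 = \lambda_z$ the terminal rate constant.

The concentration function is evaluated analytically: over any interval with
constant parameters and constant infusion rate the two-state linear system
is advanced with its exact matrix exponential (written via Lagrange
interpolation on the two eigenvalues), between breakpoints formed by dose
starts, infusion ends and observation times. Doses superpose by linearity.
Numerical choices:

* when the eigenvalues nearly coincide
  ($|\lambda_1-\lambda_2| < 10^{-9}\lambda_1$) the propagator switches to
  the repeated-eigenvalue limit $e^{\mu t}(I + (M-\mu I)t)$, avoiding the
  catastrophic cancellation of the Lagrange form;
* $Q = 0$ is treated as the exact one-compartment limit rather than a
  degenerate 2×2 solve;
* evaluation exactly at an infusion end belongs to the during-infusion
  branch; the state is continuous there, so the concentration is too.

The closed form agrees with adaptive ODE integration (`deSolve::lsoda` at
`rtol = 1e-12`) to ~1e-12 relative error in the tests, far inside the 1e-6
contract.

Secondary quantities derive from the fitted typical values:
$V_{ss} = V_1 + V_2$, terminal half-life $\ln 2/\lambda_z$, steady-state
interval AUC $= \mathrm{dose}/CL$, and the terminal-phase accumulation
ratio $1/(1-e^{-\lambda_z\tau})$. The accumulation-ratio definition is the
standard $\lambda_z$-based one; with the reference typical values it gives
1.57 at $\tau = 12$ h, matching the published derivation.

## Statistical model

Individual-occasion parameters follow a log-normal hierarchy,
$$P_{i,k} = \theta_P\, e^{\eta_{P,i}}\, e^{\kappa_{P,i,k}},$$
with subject-level effects $\eta \sim N(0, \omega^2)$ (on CL, V1, V2) and
occasion-level effects $\kappa \sim N(0, \pi^2)$ (on CL and V2); $Q$ carries
no random effect ($\omega^2_Q$ fixed at 0, as in the final published model;
any variance can be fixed to 0 through the interface, which removes that
effect dimension rather than special-casing a reason). An **occasion** is a
dosing interval: occasion $k$ runs from the $k$-th dose time (inclusive) to
the $(k+1)$-th (exclusive), giving up to 8 occasions for 2–8 doses. When
parameters change at an occasion boundary the compartment *amounts* are
carried continuously across the switch — state continuity is the contract,
and the piecewise closed form is verified against time-varying-parameter ODE
integration.

Residual error is combined additive plus proportional,
$y = f\,(1+\varepsilon_{prop}) + \varepsilon_{add}$, with variances
$\sigma^2_{prop}$ and $\sigma^2_{add}$. Percent CVs for the log-normal
variances use the exact convention $\omega^2 = \ln(1 + (CV/100)^2)$; the
proportional-error CV is $100\sqrt{\sigma^2_{prop}}$ (it is a normal, not a
log-normal, perturbation). Simulated concentrations below the assay
quantification limit (0.078 µg/ml) are flagged and excluded from fitting by
default; negative simulated values (possible under the additive term) are
retained unless explicitly truncated for display.

## Estimation

The marginal likelihood is approximated FOCE-with-interaction style: for
each subject the penalized deviance
$$h(b) = \sum_j\left[\ln(2\pi v_j) + \frac{(y_j-f_j(b))^2}{v_j}\right]
 + b^\top \tilde\Omega^{-1} b, \qquad
 v_j = f_j(b)^2\sigma^2_{prop} + \sigma^2_{add},$$
is minimized over the subject's active effects
$b = (\eta, \kappa_{1..K})$ — residual variance at the *conditional*
prediction is the η–ε interaction — and the subject's contribution to the
objective (−2 log marginal likelihood) is the Laplace value at the mode,
$$\mathrm{OFV}_i = h(b^*) + \ln\det\tilde\Omega
 + \ln\det\!\left(J^\top V^{-1} J + \tilde\Omega^{-1}\right),$$
with $J$ the prediction Jacobian at the mode. On a one-effect toy problem
this agrees with adaptive quadrature of the exact marginal likelihood well
within 0.5 OFV units (the tests include that oracle); duplicating subjects
exactly doubles the OFV, and with all variances zero it collapses to the
extended-least-squares deviance.

*Inner problem.* The mode search is a damped Gauss–Newton iteration
(compiled): exact gradient including the $\partial v/\partial b$ interaction
terms, Gauss–Newton curvature with Levenberg damping and step halving,
warm-started from the previous outer iteration. Non-positive-definite
curvature is eigenvalue-floored at 1e-8 and the subject flagged. A subject
with no usable observations has its mode exactly at zero and contributes
nothing to the OFV.

*Outer problem.* `nlminb` quasi-Newton over log-transformed parameters
(positivity by construction; box bounds at $e^{\pm 8\ln 10}$ in natural
units). Two details matter and are deliberate:

* the objective carries noise at the inner-mode tolerance, far above machine
  precision, so the outer gradient is supplied explicitly as a forward
  difference with step 1e-5 on the log scale — an optimizer left to its own
  machine-epsilon differences sees pure noise near the optimum and can stall
  more than 10 OFV units short;
* convergence is declared only at a *fixed point*: the optimizer is
  restarted from its own solution (with a fresh curvature model and cold
  inner modes) until a restart moves the OFV by less than 1e-3.

Multi-start is available (`n_starts`, jittered on the log scale with a fixed
seed) but defaults to 1: with the gradient and fixed-point polishing above,
jittered starts never changed the optimum on this problem class and triple
the cost. Relative standard errors come from the inverse Hessian of the
outer objective (`optimHess`), reported on the natural scale via the delta
method ($SE(\ln\hat P)$ is the relative SE of $\hat P$); the nonparametric
bootstrap is the confirmatory uncertainty method, as in the source analysis.

## Evaluation toolkit

**CWRES.** FOCE-linearized residuals: with $J$ and $f$ at the conditional
mode, $E = f(b^*) - J b^*$ and
$V = J\tilde\Omega J^\top + \mathrm{diag}(v)$, the residuals are
$V^{-1/2}(y - E)$ using the symmetric matrix square root; approximately
$N(0,1)$ under a correct model (mean and variance calibration are tested on
simulated data). Observations with $|CWRES| > 5$ are flagged, and
`drop_observations()` supports the flag-and-refit step used during model
building.

**Shrinkage.** $100(1 - SD(\mathrm{EBE})/\sqrt{\mathrm{variance}})$;
occasion-level effects are summarized per occasion over the subjects
contributing to it. Note a design-dependent subtlety: the published pattern
of near-total late-occasion shrinkage reflects sparse late-occasion
*sampling* in the clinical data; the synthetic design samples every dosed
occasion fully, so the package tests the underlying property directly —
thinning an occasion's observations pulls its EBEs toward zero and raises
shrinkage.

**VPC.** Observations are binned by nominal time-after-most-recent-dose
(0.5, 2, 4, 8, 12 h), pooling occasions as the sampling design intends; a
sample drawn exactly at a dose time is the previous interval's 12-h trough.
`nsim` replicate datasets are simulated under the fitted model on the
original design; the observed 5th/50th/95th percentiles per bin are compared
with the central 90% interval of the same percentile across replicates.

**Bootstrap.** Whole subjects are resampled with replacement (the subject is
the exchangeable unit; all occasions travel together), refit from the point
estimates under the same fixed-point convergence standard, and summarized by
percentile medians and 90% intervals; non-converged resamples are counted
and excluded (typically a few percent here — a stricter convergence
criterion than the reference software's, so more resamples are discarded).

**Covariate screen.** Subject-level effects are paired with
time-independent covariates, body surface area (DuBois) and BMI, and
per-subject medians of the time-dependent covariates; occasion-level effects
with the time-dependent covariate value at the occasion start
(last-observation-carried-forward from daily records). Each pair gets a
rank correlation, a lowess trend, and a monotone variance-explained
statistic; a pair is a candidate only if that statistic reaches 20% — the
level below which a covariate cannot usefully cut the unexplained
variability. The statistic is estimated by leave-one-out cross-validated
isotonic regression (both directions, step-function prediction so it is
invariant to monotone covariate rescaling; grouped means for categorical
covariates). The cross-validation is essential: raw isotonic $R^2$ on 37
subjects exceeds 0.20 about a fifth of the time on pure noise, so an
uncorrected screen would flag spurious candidates in nearly every null
study, while the LOO estimate stays near zero under the null and still
recovers a deliberately planted weight-on-clearance effect.

## The synthetic study generator

The generator reproduces the study conditions: 37 subjects; 200 mg loading
then 100 mg q12h as 0.5-h infusions; per-subject dose counts uniform on
{2..8} (the per-subject histogram is unpublished); samples at 0.5, 2, 4, 8,
12 h after every dose; occasions assigned by dosing interval. With these
defaults the expected observation total is $37 \times 5 \times 5 = 925$,
already within 2% of the 942 analysed concentrations, so the optional
missingness fraction defaults to 0 (no missingness value could raise the
uniform-design expectation to exactly 942).

Covariates are drawn to match the published population table: continuous
variables from Beta distributions rescaled to the published (min, median,
max) — the Beta respects the observed bounds, and its shapes are chosen so
the median matches — with categorical counts (26/11 male/female, 35/2
ECMO, 6/30/1 CRRT) as multinomial probabilities. Time-dependent covariates
evolve across days by a bounded random walk on the logit of the
range-scaled value (SD 0.25/day). Covariates are independent of the PK
parameters by default — the null design matching the published finding of
no covariate relationships — with an optional planted effect
(`plant = list(param, covariate, power)`) for screen power testing. The
generating truth defaults to the published final estimates, and truth, seed
and drawn effects are attached to the dataset.

What the generator does *not* emulate: correlated covariates (margins are
independent; weight and height in real patients are not), informative
missingness, dose delays or interruptions, assay heteroscedasticity beyond
the combined error model, and time-varying clearance within an occasion.
Passing tests therefore demonstrate correct recovery of the model's own
data-generating process under the study design — not robustness to the
model misspecifications real ICU data would carry.

## Problem sizes and reproducibility

The test suite and the acceptance script choose sizes that make the
stochastic checks informative while remaining desk-scale: 5 replicate
studies for parameter recovery, 200 VPC replicates, 100 bootstrap
resamples, ~900-observation datasets for residual calibration. All
randomness flows from explicit integer seeds; identical seeds give
bit-identical datasets, fits and evaluation tables.

## Known limitations

* The estimator is Laplace-at-the-mode with Gauss–Newton curvature — the
  FOCE-I flavor, not bit-compatible with any specific NONMEM option string;
  agreement is demonstrated against quadrature, not against NONMEM output.
* Only diagonal random-effect covariances are supported (the final published
  model is diagonal); no SAEM/importance-sampling estimators; no automatic
  covariate model building (the source analysis found no covariate effects
  and used visual screening only).
* Below-quantification observations are excluded rather than likelihood-
  censored; at these dose levels fewer than ~1% of simulated samples fall
  below the limit, so the information loss is negligible.
* The bootstrap convergence standard is stricter than classical practice,
  so its failure count is not comparable to published NONMEM failure rates.
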