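# tigepk

Population pharmacokinetics of high-dose tigecycline (200 mg loading dose,
then 100 mg every 12 h as 30-min infusions) in adult ICU patients with
sepsis or septic shock.

Tigecycline is often the antibiotic of last resort against multidrug-
resistant pathogens in critically ill patients, whose pathophysiology can
shift drug clearance and distribution volumes far from the values seen in
healthier cohorts. `tigepk` implements the full population analysis for
this setting, for pharmacometricians and clinical-pharmacology researchers:
a structural model, a hierarchical statistical model, an approximate
maximum-likelihood estimator, the standard evaluation toolkit, and a
synthetic study generator so the whole pipeline runs and is tested without
access to patient data.

## The model

Disposition is two-compartment with zero-order infusion input,
parameterized as clearances and volumes (CL, V1, Q, V2; mg and litres give
µg/ml directly). Individual-occasion parameters follow a log-normal
hierarchy

P<sub>i,k</sub> = θ<sub>P</sub> · e^{η<sub>P,i</sub>} · e^{κ<sub>P,i,k</sub>},

with interindividual effects η ~ N(0, ω²) on CL, V1, V2 and interoccasion
effects κ ~ N(0, π²) on CL and V2, an occasion being one dosing interval
(up to 8). Residual error is combined additive + proportional,
y = f·(1+ε<sub>prop</sub>) + ε<sub>add</sub>. Estimation maximizes a
FOCE-with-interaction (Laplace-at-the-mode) approximation to the marginal
likelihood: each subject's penalized deviance is minimized over (η, κ) by a
compiled damped Gauss–Newton search, and −2 log L is assembled from the
mode value plus the log-determinant of the linearized curvature. Model
evaluation: conditional weighted residuals (CWRES), shrinkage, visual
predictive checks, nonparametric subject-level bootstrap, and an
empirical-Bayes covariate screen with a monotone variance-explained
criterion.

## Worked example

```r
library(tigepk)

# a complete synthetic study under the published design and estimates:
# 37 subjects, 200/100 mg q12h, 2-8 doses, samples 0.5/2/4/8/12 h post dose
x <- generate_study(seed = 101)
x
#> <pk_dataset> 37 subjects, 905 observations, 181 doses
#>   covariates: age, weight, height, dialysis_volume, uf_speed, elwi,
#>   cardiac_output, sofa, pct, albumin, sex, ecmo, crrt

fit <- fit_pk(x, options = list(seed = 1))
fit
#> <pk_fit> converged, OFV = -2106.654
#>              estimate  RSE%
#> theta_CL     21.67000  2.99
#> theta_V1    182.90000  3.87
#> theta_Q      53.96000 13.00
#> theta_V2     85.41000  9.59
#> omega2_CL     0.02371 33.50
#> omega2_V1     0.04034 28.30
#> omega2_V2     0.17880 46.90
#> pi2_CL        0.02802 20.70
#> pi2_V2        0.02277 70.90
#> sigma_add     0.01189 53.50
#> sigma2_prop   0.01883  7.96
```

The typical values land near the generating truth (CL 22.1 L/h, V1 162 L,
Q 69.4 L/h, V2 87.9 L): clearance — the parameter that drives exposure and
is best determined by this sampling design — is recovered within a few
percent with ~3% RSE, while Q and the variance components carry the larger
uncertainty the design implies.

Derived clinical quantities from the typical parameters:

```r
p <- pk_params(CL = 22.1, V1 = 162, Q = 69.4, V2 = 87.9)
str(secondary_metrics(p, tau = 12, maintenance_dose = 100))
#> List of 5
#>  $ Vss               : num 250     # steady-state volume, litres (249.9)
#>  $ lambda_z          : num 0.0848  # terminal rate constant, 1/h
#>  $ terminal_half_life: num 8.17    # hours
#>  $ accumulation_ratio: num 1.57    # 12-hourly dosing (1.566)
#>  $ auc_tau_ss        : num 4.52    # mg h/L per interval at steady state
```

Evaluation:

```r
res <- flag_outliers(cwres(fit))          # CWRES, |value| > 5 flagged
shrinkage(fit)                            # eta and per-occasion kappa
v <- vpc(fit, nsim = 1000, seed = 1)      # percentile bands vs observed
plot(v)
b <- bootstrap_pk(x, init = fit$estimates, n = 1000, seed = 1)
sc <- covariate_screen(fit)               # EBE-vs-covariate screen
```

A YAML-configured driver runs the stages end to end and writes delimited
artifacts (`run_pipeline("all", config = "config.yaml")`); a thin CLI
wrapper lives at `inst/cli/tigepk.R`.

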