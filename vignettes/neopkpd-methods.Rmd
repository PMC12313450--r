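---
title: "Methods: neonatal beta-lactam PK simulation, target attainment and model evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal beta-lactam PK simulation, target attainment and model evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and rationale

`neopkpd` implements a simulation workflow for evaluating intravenous
amoxicillin and benzylpenicillin dosing regimens in (pre)term neonates treated
for suspected early-onset sepsis during the first 48 hours of life, together
with the external-evaluation battery used to qualify a population PK model for
such simulations. The unit of analysis is a virtual neonate characterised by
gestational age (GA) and a GA-matched birth weight; dosing regimens are
resolved per subject into explicit infusion events, true (residual-error free)
concentration profiles are simulated under between-subject variability (BSV),
and efficacy is summarised as the probability of target attainment (PTA) over
a grid of `%fT>MIC` targets, with toxicity summarised as the percentage of the
first 48 h spent above total-concentration thresholds.

## The population PK model

Both shipped drug models follow the standard neonatal covariate
parameterisation. For individual $i$ and parameter $P \in \{CL, V, Q, V_2\}$:

$$P_i = \theta_P \cdot \prod_k f_k(\mathrm{cov}_i) \cdot e^{\eta_{P,i}},
\qquad \eta_{P,i} \sim N(0, \omega_P^2)$$

with covariate effects composed from:

* **allometric scaling** to birth weight, $(BW/BW_{ref})^{0.75}$ for
  clearances and exponent 1 for volumes;
* **sigmoidal (Hill) maturation** of clearance in postmenstrual age,
  $PMA^\gamma / (PMA_{50}^\gamma + PMA^\gamma)$, bounded in $(0,1)$, equal to
  0.5 at $PMA_{50}$, and monotone increasing in PMA;
* an optional **linear postnatal-age effect** on clearance,
  $1 + \beta \cdot PNA$, capturing the rapid postnatal rise in renal drug
  elimination.

The time origin is birth: $PNA(t) = t/24$ days and
$PMA(t) = GA + PNA(t)/7$ weeks. Because clearance therefore changes within
the 48-h window, time-varying covariates are refreshed *at each dose event*:
every dose's contribution to the superposed profile uses the parameters
evaluated at that dose's start time. This piecewise treatment is the standard
approximation used when a linear superposition engine meets a slowly varying
covariate; over 48 h the within-interval change in clearance is a few percent
and the approximation error is far below the BSV magnitude. Covariate values
beyond a model's declared development range are used as-is (matching the
deliberate extrapolation of published neonatal models down to GA 24 weeks),
with a warning.

Residual (proportional + additive) error is part of the model specification
but is used *only* where observed concentrations are involved: dataset
generation, pcVPC/NPDE simulation and MAP estimation. PTA and toxicity
simulations sample BSV only, because target attainment is a statement about a
subject's true concentration, not about an assay measurement of it.

## Simulation engine and its oracle

Profiles are computed by analytic superposition of the closed-form one- or
two-compartment constant-rate infusion solutions, one term per dose event
(bolus doses are represented as 5-minute infusions throughout). The closed
form is exact, linear in dose and fast enough for $10^4$ subjects; the
two-compartment washout uses `expm1`-based terms so the $Q \to 0$ limit
degenerates smoothly to the one-compartment solution. An independent
numeric oracle (`ode_oracle()`, stiff-capable `lsoda` integrated piecewise
between infusion on/off switches at tolerances $10^{-10}$) implements the same
contract and is used in the test suite, which requires agreement within 0.1%
in scaled sup-norm on randomized parameter/schedule instances.

`%fT>MIC` is computed on unbound concentrations (total multiplied by a fixed
unbound fraction; defaults 11.7% bound for amoxicillin and 49.2% for
benzylpenicillin) with a strict `>` comparison. Grid intervals that bracket a
threshold crossing are refined with `uniroot` on the continuous-time profile
evaluator, so the result does not depend on the grid step; the tests hold it
to within 0.1 percentage points of a 0.001-h dense grid.

**Attainment window.** Therapy starts at birth, so the concentration is zero
at $t = 0$ and below any MIC for the first seconds of the first infusion. A
literal `[0, 48]` h denominator therefore makes every `100%fT` target
unattainable by construction, for every regimen — contradicting the way such
targets are used and reported in this field. The package evaluates attainment
from the end of the first infusion (the first attainable peak) to 48 h;
`100%fT>MIC` thus reads "above MIC continuously from the first peak onwards".
Toxicity durations, by contrast, genuinely concern the fraction of the first
48 h of life above a threshold and keep the full `[0, 48]` denominator, on
total concentrations (the available neurotoxicity thresholds — 110 mg/L for
amoxicillin, 75 and 50 mg/L for benzylpenicillin — derive from adult reports
of total concentrations).

## Virtual population

The default population holds 500 subjects for each whole GA week from 24 to
42 (N = 9500); the per-week count is exact, not multinomial. GA within a
stratum is the whole-week value. Birth weight is drawn from a per-GA-week
log-normal whose median and spread are fitted to 3rd/50th/97th percentile
columns of a growth-reference table; draws are truncated to the
0.1st–99.9th percentile envelope by inverse-CDF sampling. The shipped table
(`growth_reference_synthetic.csv`) is a synthetic reference approximating the
shape of published neonatal birth-weight charts — it is deliberately a
config file, meant to be replaced by an institutional chart. Postnatal weight
dynamics are not modelled: over a 48-h window current weight is taken equal
to birth weight, for dosing and for allometry alike, so only the birth-weight
distribution matters.

## Dosing regimens

The catalog encodes, per regimen, a set of mutually exclusive stratification
rules on birth weight and GA:

* **DPF amoxicillin** — 25 mg/kg, q12h below 2 kg, q8h at/above 2 kg;
* **DPF benzylpenicillin** — 25,000 IU/kg with the same weight strata;
* **GA-based benzylpenicillin** — 30,000 IU/kg q12h (GA < 28 w), q8h
  (28 to < 36 w), q6h (>= 36 w). GA exactly 36 weeks is assigned to the more
  mature, more frequent stratum (the published description leaves 36
  unassigned);
* **continuous benzylpenicillin** — the weight-stratified total daily dose as
  a constant-rate infusion plus a 16.7% loading dose over 5 minutes,
  concurrent with the start of the continuous rate.

All intermittent doses start at birth ($t = 0$) and repeat every interval
while $t < 48$ h. Benzylpenicillin IU convert at 1 IU = 0.6 ug (the
international convention for benzylpenicillin sodium; configurable). The DPF
postnatal-age frequency switch at one week is not encoded because the
analysis window ends at 48 h of life. Seven further international formularies
are present as explicit, untranscribed stubs that error on use, keeping the
catalog honest about what it contains.

## Shipped parameter sets are synthetic

The published neonatal models this workflow is designed around are defined in
supplementary material not available to this package, so the shipped
amoxicillin (one-compartment, PMA+PNA clearance maturation, allometric birth
weight) and benzylpenicillin (two-compartment, PMA maturation, allometric
birth weight) parameter sets are *synthetic stand-ins*: the correct published
structure with literature-plausible values (volumes around 0.6 L/kg;
half-lives falling from roughly 10 h to 4 h [amoxicillin] and 5 h to 3 h
[benzylpenicillin] across GA 24–42; renal-type Hill maturation constants;
30–36% CV BSV), fixed once and labelled `_synthetic` in their file names and
headers. Quantitative conclusions about a specific published model require
replacing these files with transcribed values; the structural code needs no
change. The fully synthetic `demo` model backs every test whose validity must
not depend on any real drug's values.

Under these frozen stand-ins, the simulated pattern matches the qualitative
published picture: amoxicillin DPF attains >90% PTA across the entire
40–100%fT>MIC range with zero median time above 110 mg/L in every GA
category; benzylpenicillin DPF is adequate at MICs of 0.125–0.25 mg/L but
fails 100%fT>MIC at 1 mg/L (~82% PTA), while the GA-based and continuous
regimens restore >=90% and 100% attainment respectively. One cell —
amoxicillin 100%fT>4xMIC at MIC 1 mg/L — computes ~88–89%, just below the
90% adequacy bound; this cell is sensitive to the stand-in BSV magnitude and
to the amoxicillin MIC cut-off set, and is reported as computed rather than
adjusted for.

## Model evaluation battery

* **PRED / IPRED** — population predictions at $\eta = 0$; individual
  predictions at MAP $\hat\eta$ minimising
  $-2[\log p(DV \mid \eta) + \log p(\eta)]$ under the combined error model,
  with multi-start BFGS (prior mode plus four prior draws under a fixed
  internal seed) and a Nelder–Mead fallback. Subjects without observations
  return the prior mode exactly.
* **Prediction errors** — $PPE = 100 (PRED - DV)/DV$, APPE its magnitude,
  $NRMSE = 100\,RMSE/\overline{DV}$ (mean normalization by default,
  range-normalization selectable since published definitions vary), and
  P10/P20/P30 as the percentage of predictions within 10/20/30% of the
  observations.
* **pcVPC** — observations and each simulated replicate are rescaled by
  bin-median population prediction; bins are quantile-based on time after the
  most recent dose (default 4), because sparse TDM-style sampling under mixed
  q8/q12 regimens makes absolute-time bins misleading. Simulation bands are
  95% intervals of each percentile across replicates (default N = 1000).
* **NPDE** — per subject, the observed vector is decorrelated with the
  empirical mean and lower Cholesky factor of the simulation covariance
  (default N = 1000); $pde$ is the rank-based fraction of decorrelated
  simulations below the decorrelated observation, clamped to
  $[1/2N, 1 - 1/2N]$, and $npde = \Phi^{-1}(pde)$. Global mean/variance are
  tested against 0/1 (t and chi-squared) with Shapiro–Wilk normality and a
  Bonferroni-combined p-value. A singular simulation covariance raises an
  error suggesting a larger N.

On data simulated from the model itself the suite requires NPDE mean within
3 SE of 0 and variance within 3 SE of 1 (pooled over 20 replicate studies),
pc-median band coverage of at least 90% of bins, and MAP $\eta$ recovery
correlation above 0.9 at 8 samples/subject.

## Synthetic study generator

`generate_study()` emulates the sparse TDM-leftover design of a neonatal EOS
PK study: GA strata in the observed cohort proportions (20/30.5/17.9/31.6%
for extremely/very/moderate-late preterm and full-term — deterministic
largest-remainder allocation by default, so a 95-subject study reproduces the
19/29/17/30 split exactly), GA uniform on the whole weeks within each
stratum, growth-reference birth weights, DPF dosing, 1–4 samples per subject
(probabilities 0.20/0.45/0.25/0.10, median 2) drawn uniformly over 1–48 h
(avoiding the first hour of life, when sampling is clinically unrealistic),
and observations under the model's full BSV + residual error. Values below
the limit of quantification (default 0.1 mg/L) are set to the limit and
flagged, not dropped. True random effects are returned for recovery
experiments. The generator does **not** emulate TDM-driven (concentration
dependent) sampling times, gentamicin co-therapy records, or assay batch
effects — passing diagnostics on these data show internal consistency of the
evaluation machinery, not field performance on real TDM data.

## Numerical choices and problem sizes

Default simulation grid 0.05 h augmented with every infusion on/off time;
crossing refinement tolerance $10^{-10}$ h; MAP objective tolerance
$10^{-10}$ (relative); ODE oracle tolerances $10^{-10}$/$10^{-12}$. The
packaged analyses use 100 subjects per GA week (1900 total) for PTA/toxicity
tables and N = 1000 simulation replicates for pcVPC/NPDE — sizes at which a
full run completes in about a minute on one core while Monte-Carlo error on a
PTA percentage is below one point; the population generator itself defaults
to the full 500/week. Regimen comparisons reuse one BSV draw across regimens
(paired design), so regimen contrasts are not diluted by between-subject
Monte-Carlo noise; the published analyses do not state whether they paired
virtual subjects, making this a package design choice.

## Known limitations

* Parameter values for the two drug models are synthetic stand-ins (above);
  all drug-specific numbers should be read as "under these conditions".
* Clearance maturation within a dosing interval is frozen at the dose time.
* Protein binding is a fixed constant per drug; the binding sensitivity sweep
  varies the constant but not between-subject binding variability.
* No renal-function covariates, no nonlinear elimination, no oral absorption,
  no CSF compartment; estimation (FOCEI/SAEM) is out of scope — the package
  evaluates models, it does not fit them.
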