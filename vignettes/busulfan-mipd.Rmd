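---
title: "Methods: Bayesian precision dosing of intravenous busulfan in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian precision dosing of intravenous busulfan in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busmipd)
```

## The clinical problem

Busulfan is an alkylating agent given intravenously over four days as part
of conditioning before hematopoietic stem cell transplantation (HSCT) in
children, conventionally as a 2-h infusion every 6 h (16 doses). It has a
narrow therapeutic margin: underexposure risks graft rejection, overexposure
risks transplant-related mortality and veno-occlusive disease. Exposure is
summarized by the area under the concentration-time curve (AUC), with a
conventional per-dose target of 3.7–6.1 mg·h/L (900–1500 µM·min) and a
cumulative target of roughly 60–100 mg·h/L; dose individualization
typically aims at a cumulative AUC of 80 mg·h/L. Because rich sampling is
impractical in small children, therapeutic drug monitoring (TDM) relies on
sparse sampling — here two blood samples, 0.5 and 2 h after the end of the
first infusion — combined with Bayesian estimation of individual
pharmacokinetic (PK) parameters under a population model.

`busmipd` implements this workflow end to end for two published
one-compartment models and provides the machinery to cross-validate them
against each other: per-patient fits, AUC estimation, dose recommendation,
and cohort-level agreement analysis.

## The two population models

Both models are one-compartment with zero-order (constant-rate) infusion
input and first-order elimination. For an infusion of rate $R_0 = D/T_{inf}$
the concentration contribution is

$$C(t) = \frac{R_0}{CL}\left(1 - e^{-k t}\right), \quad 0 \le t \le T_{inf};
\qquad
C(t) = C(T_{inf})\, e^{-k (t - T_{inf})}, \quad t > T_{inf},$$

with $k = CL/V$; multiple doses superpose. AUC over any window is the exact
closed-form integral of this curve, and the cumulative AUC of a whole course
is total dose divided by clearance.

**Parametric (test) model.** Allometric covariate equations on body weight
(BW, kg):

$$CL\ (\mathrm{L/h}) = 2.18 \times (BW/9)^{\theta}, \qquad
\theta = \begin{cases}1.25 & BW < 9\ \mathrm{kg}\\ 0.76 & BW \ge 9\ \mathrm{kg}\end{cases}
\qquad V\ (\mathrm{L}) = BW^{0.86}.$$

Between-subject variability is log-normal with CVs of 23% (CL) and 22% (V);
residual error combines an 11% proportional term with a 57 ng/mL
(0.057 mg/L) additive SD. The CL exponent changes at 9 kg but the function
is continuous there.

**Nonparametric (reference) model.** Parameterized by slope parameters
$Ke_S$ and $V_S$:

$$Ke\ (\mathrm{h}^{-1}) = Ke_S \times \mathrm{size}^{-0.25}, \qquad
V\ (\mathrm{L}) = V_S \times \mathrm{size},$$

where size is the lower of BW and the Traub–Johnson ideal body weight
(IBW = height² × 1.65/1000, height in cm). The published summaries are
$Ke_S$ median 0.71 (range 0.42–0.98, CV 18%) and $V_S$ median 0.72
(0.53–1.40, CV 21%), with residual SD (mg/L) = 0.02 + 0.1·C~obs~. We store
the model internally as $(CL, V)$ with $CL = Ke\,V$.

## Estimation

**MAP (parametric).** The individual parameters maximize the posterior
under the log-normal prior, i.e. minimize

$$\sum_i\left[\frac{(C_{obs,i}-C_{pred,i})^2}{\sigma_i^2} + \ln \sigma_i^2\right]
+ \sum_k \frac{\eta_k^2}{\omega_k^2},
\qquad \omega_k^2 = \ln(1 + CV_k^2),$$

with $\sigma_i$ the combined residual SD evaluated at the model prediction.
The $\ln\sigma^2$ term is retained because $\sigma$ depends on $\eta$
through the prediction; dropping it would change the estimator (we measured
the difference to be about one percentage point of clearance bias in
simulation — see the recovery discussion below). Optimization is
derivative-free Nelder–Mead from $\eta = 0$ with a restart from the best
point of a coarse 5×5 grid on $[-1,1]^2$, relative objective tolerance
1e-12; the better solution is kept. The problem is smooth in two
dimensions, so robustness was preferred over speed, and the unit tests
verify the optimum against an exhaustive 0.005-resolution grid over
$[-1.5, 1.5]^2$.

**Discrete-prior (nonparametric).** The reference model's true support
points are unpublished; only the median, range and CV of each slope are.
`build_np_prior()` therefore reconstructs an *approximate* prior: an
$m\times m$ log-spaced grid spanning the published ranges (default
$m = 20$, 400 points), weighted by the product of independent truncated
log-normal densities with meanlog = log(median) and
sdlog² = ln(1 + CV²), times the log-grid cell widths. This matches the
published medians within 2% by construction and is flagged as approximate
in every provenance record. Given observations, posterior weights are
prior × normal likelihood (SD from the 0.02 + 0.1·C~obs~ rule, evaluated at
the observed value exactly as the published formula is written), normalized
in log space for stability. The support points never move; only their
probabilities update. Exposure and dose summaries use posterior-weighted
means (the full weight vector is retained); a single-support posterior
degenerates exactly to the parametric evaluation at that point.

If even the best support point's likelihood underflows to zero in linear
double precision — no candidate parameter set remotely fits, the signature
of a measurement or data-entry error — the posterior falls back to uniform
weights with an explicit warning rather than failing or silently returning
noise.

## Dosing and agreement analysis

The dose per administration to attain a target cumulative AUC is
target × CL / n~doses~ (for the nonparametric model, the posterior-mean CL).
The recommendation record always carries the re-simulated cumulative AUC,
which must and does equal the target to numerical precision — the check is
an algebraic identity, but it exercises the whole PK engine. Doses are not
rounded by default because model comparison uses raw predicted doses;
practical rounding is an option.

`cross_validate()` fits every patient with both models on first-occasion
data, then reports for each model the mean percent error (MPE, bias, with a
Student-*t* 95% CI on per-point percent errors) and root-mean-squared
percent error (RMSE, imprecision) of predicted vs observed concentrations,
and between-model agreement on three quantities: pooled predicted
concentrations, the AUC over the first 6 h (AUC₀₋₆, computed as the true
integral of the fitted curve over [0, 6] h — the per-interval dose/CL value
is available separately), and the predicted dose for the 80 mg·h/L target.
Agreement uses ordinary least squares (slope, intercept, R²) and
Bland–Altman percent differences with 95% limits of agreement
(mean ± 1.96 SD). The percent-difference denominator is the pairwise mean
(symmetric convention); a reference-denominated variant is available. Pairs
outside the limits are flagged with patient identifiers. Inter-occasion
variability is deliberately not modeled: parameters estimated after the
first dose are assumed to persist over the 16-dose course, and neither
implemented model carries occasion-level random effects.

## The virtual cohort generator

No patient-level dataset is public, so `simulate_cohort()` emulates the
study design for testing and calibration experiments:

* **Body weight**: log-normal, median 16.7 kg, truncated to [3.2, 90.9] kg.
  The log-scale SD is not published; we use 0.67, which places the
  truncation bounds near ±2.5 SD and reproduces a realistic pediatric HSCT
  spread. Chosen once, not revisited.
* **Height**: the published covariate summaries pin height only through its
  median and range, so height is generated by inverting the ideal-body-weight
  relation, $ht = \sqrt{BW/0.00165}$ cm, capped at 180 cm (weight keeps
  rising after longitudinal growth stops), with 5% log-normal noise and
  redrawing outside the cohort's 46–190 cm range. Height only matters
  through IBW in the reference model.
* **Regimen**: 2-h infusions every 6 h, 16 doses. Starting doses follow the
  conventional weight-banded label nomogram for q6h intravenous busulfan
  (1.0 / 1.2 / 1.1 / 0.95 / 0.8 mg/kg for <9 / 9–16 / 16–23 / 23–34 /
  >34 kg) — a standard clinical rule supplied in config, not taken from the
  cross-validation study; dose level mostly scales concentrations linearly,
  though it does set where the additive error floor bites.
* **Individual parameters**: $CL_i = TVCL\,e^{\eta}$,
  $\eta \sim N(0, \ln(1+0.23^2))$, likewise V at 22% CV.
* **Observations**: exactly at infusion end + 0.5 h and + 2 h (2.5 and
  4.0 h absolute), with additive-normal combined residual noise; negative
  draws are redrawn (up to 100 times) rather than truncated, avoiding a
  point mass at zero.

What the generator does *not* emulate: the real age–weight–height joint
distribution (only marginals are matched; age is a crude weight-based
proxy carried for reporting), repeat TDM occasions and inter-occasion
variability, assay quantification limits, and model misspecification — the
data are generated from the parametric model itself. Passing tests
therefore demonstrate the engine's internal correctness and the models'
agreement behavior under idealized conditions, not clinical performance on
real patients.

## What recovery simulations show — and an intrinsic bias

With the study design (two samples, full residual noise), MAP clearance
estimates on simulated cohorts of 200 patients have a relative RMSE of
about 15–18% against truth and a mean percent error of about +4–5%
(computed by the test suite and the acceptance script; the exact value is
seed-dependent). The spread reflects correct Bayesian shrinkage from the
23% prior CV given two early samples — both drawn less than one elimination
half-life after the infusion ends, so they separate CL from V only weakly.
The small positive bias is intrinsic rather than an implementation defect:
symmetric additive-normal noise on concentrations maps through the convex
concentration-to-clearance inversion ($E[1/(1+\varepsilon)] > 1$), and the
$\ln\sigma^2$ term adds about one further point by favoring slightly lower
predictions. We verified the optimizer itself is exact against grid search,
and that variants without the $\ln\sigma^2$ term or with $\sigma$ evaluated
at the observation do not reduce the error. In the noise-free,
dense-sampling limit (8 samples, residual noise off, fitted with a
correspondingly small residual assumption) clearance is recovered to well
under 1%, confirming near-identifiability.

## Numerical choices and degenerate inputs

* Internal units are mg, L, h and mg/L everywhere; ng/mL is accepted and
  produced only at the I/O boundary (factor 1000), the unit the assay
  reports in.
* Time zero is the start of the first infusion; "0.5 and 2 h after the end
  of infusion" are stored as absolute times 2.5 and 4.0 h.
* Bolus-like events (duration < 1e-6 h) are rejected: intravenous busulfan
  is always infused, and the closed forms assume a genuine infusion.
* AUC windows require t₀ < t₁; t₁ = ∞ is supported and equals dose/CL per
  event.
* Posterior weights are renormalized after every update and checked to sum
  to 1 within 1e-12 in the test suite.
* Zero observations are legal everywhere: MAP returns the prior mode, the
  discrete posterior returns the prior.
* Problem sizes in the shipped tests and acceptance script — 200-patient
  recovery, 61-patient cross-validation, 20-patient oracle comparisons —
  match the study's cohort scale while keeping a full run in the order of a
  minute.

## Known limitations

The discrete prior is a moment-matched reconstruction, not the true
(unpublished) support set, so nonparametric results approximate the
reference implementation's behavior rather than reproduce it. The published
Traub–Johnson variant used by the reference software is not printed in the
sources we implement from; the default here (height² × 1.65/1000) is
configurable and echoed in every provenance record. Only one-compartment
intravenous kinetics are supported — no oral absorption, no multi-compartment
disposition, no nonlinear elimination — and within-course re-estimation
after later TDM occasions is out of scope.
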