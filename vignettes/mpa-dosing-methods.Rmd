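---
title: "Methods: the MPA population model, virtual dosing trials and MAP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MPA population model, virtual dosing trials and MAP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`mpadose` implements a population pharmacokinetic (PK) model of
mycophenolic acid (MPA) in pediatric kidney-transplant recipients and the
analyses that such a model supports: virtual-population comparison of
starting-dose strategies, derivation of weight-band dosing charts, MAP
(maximum a posteriori) estimation of individual parameters from sparse
concentration data, and simulation-based model diagnostics.  This
vignette is the package's account of the underlying science and of the
design decisions we made where more than one reasonable choice existed.

## The structural model

Oral mycophenolate mofetil (MMF) is absorbed, hydrolysed to MPA, and
eliminated predominantly by glucuronidation.  The model describes MPA
plasma concentration with:

* **Erlang-type absorption**: the dose enters a chain of `n_abs`
  identical first-order compartments, each emptying at rate $k_{tr}$.
  With the default `n_abs = 2` (a depot plus one transition compartment)
  the absorption-time density is an Erlang distribution of shape 2,
  which produces the short lag and rounded peak typical of MMF without a
  discrete lag time.
* **Two-compartment disposition** with apparent central volume $V_c/F$,
  peripheral volume $V_p/F$, intercompartmental clearance $Q/F$ and
  elimination clearance $CL/F$ from the central compartment.

All parameters are *apparent* (divided by the unobserved oral
bioavailability $F$) because only oral data inform them.  Units are fixed
package-wide: hours, mg of MMF for doses, mg/L of MPA for
concentrations, litres and L/h.  The factor `mmf_to_mpa()` (0.739, the
molecular-weight ratio of MPA to MMF) is provided purely for comparing
estimates with models parameterized in MPA doses; it never enters any
computation here.

The covariate model scales clearances with allometric weight exponent
0.75, volumes with exponent 1, and rate constants with $-0.25$, all
relative to 70 kg, and adds a power function of serum albumin on
clearance:

$$CL/F = \theta_{CL}\,(WT/70)^{0.75}\,(ALB/35)^{\theta_{ALB}},$$

with $\theta_{CL} = 16.0$ L/h and $\theta_{ALB} = -2.49$ at a 35 g/L
albumin normalization.  Low albumin increases the unbound MPA fraction
and hence apparent total clearance, which the negative exponent
captures.  The remaining typical values are $V_c/F = 24.9$ L,
$V_p/F = 1590$ L, $Q/F = 36.2$ L/h and $k_{tr} = 1.48$ h$^{-1}$ at
70 kg.  Source tables of this model are printed inconsistently in the
literature stream it comes from (an albumin normalization of 34 appears
alongside 35, and an exponent of $-2.5$ alongside $-2.49$); we default
to 35 and $-2.49$ and keep both configurable in `mpa_params()` rather
than silently reconciling them.

Random effects are log-normal: inter-individual variability (IIV) on
$CL/F$ (38.6% CV), $V_c/F$ (320% CV) and $Q/F$ (63.6% CV), and
inter-occasion variability (IOV) on relative bioavailability $F$
(46.1% CV), one multiplier per dosing occasion.  $V_p/F$ and $k_{tr}$
carry no IIV.  CV and log-scale variance are related by
$CV(\%) = \sqrt{e^{\omega^2}-1}\times 100$ (`cv_percent()` /
`omega2_from_cv()`).  Residual error is proportional,
$y = f(1+\varepsilon)$; we interpret the reported 47.3% CV with the
standard proportional-error convention $\sigma = 0.473$ (the log-normal
CV formula above is defined for $\omega^2$ random effects; applying it
to $\sigma^2$ would change $\sigma$ only from 0.473 to 0.449, and the
choice never affects exposure simulation, only observation noise).

Deliberately **not** modelled: enterohepatic recirculation of MPA (its
secondary peaks are absent from the structural model), nonlinear protein
binding, and unbound-MPA kinetics.

## Solving the system

The model is a linear constant-coefficient ODE system, so between dose
events the state propagates exactly by the matrix exponential.
`solve_profile()` builds the rate matrix (absorption chain, central,
peripheral, plus a cumulative-elimination state used for mass-balance
checks) and steps through the merged timeline of dose and observation
times with `arma::expmat()` in compiled code.  This choice is deliberate:
the absorption chain has the eigenvalue $-k_{tr}$ with multiplicity
`n_abs`, so closed-form solutions that assume distinct eigenvalues are
fragile exactly where this model lives; the matrix exponential is
uniformly robust, including when a disposition eigenvalue collides with
$k_{tr}$.  The test suite verifies agreement with an independent
stiff-safe ODE integration (`deSolve::lsoda`) to better than $10^{-6}$
relative over random parameter sets spanning both $V_p \gg V_c$ and
$V_p \ll V_c$ regimes, plus dose-linearity, superposition and
mass-balance identities.

Two conventions matter for users:

* an observation coinciding with a dose time is read *before* the dose
  (a pre-dose sample), so concentrations at times with no earlier dose
  are exactly zero;
* steady-state exposure is computed analytically,
  $AUC_{0-\tau} = F_{occ} \cdot \text{dose} / CL$, which is exact for
  linear PK and independent of absorption parameters.  The tests verify
  this against trapezoidal integration of a superposed multiple-dose
  profile; because $V_p/F = 1590$ L implies a terminal half-life of
  roughly three days, that check superposes 120 twice-daily doses —
  after 50 doses the system is still about 1% short of steady state,
  which is worth remembering when interpreting early-phase simulations.

## The virtual pediatric population

The dose-comparison analysis needs virtual subjects, generated by
`generate_population()`:

| quantity | distribution | default |
|---|---|---|
| age | uniform | 3–18 y |
| sex | Bernoulli | 0.5 male |
| height | normal around a sex-specific median-by-age growth reference | 4% CV |
| weight | weight-for-age median $\times (h/h_{med})^2$, log-normal spread | 17% CV |
| albumin | truncated normal on [20, 55] g/L | mean 33 g/L, 21% CV |

The growth reference is a table of rounded median heights and weights by
whole year of age and sex (values typical of European/North-American
references), linearly interpolated; the $(h/h_{med})^2$ factor keeps
weight consistent with the subject's own height (a BMI-like coupling).
Heights are truncated to 90–200 cm and weights to 10–100 kg.  Body
surface area uses the Dubois formula
$BSA = 0.007184\, WT^{0.425}\, HT^{0.725}$.

This generator emulates the *marginal* structure the analysis needs
(realistic weight/height/BSA ranges for ages 3–18, the stated albumin
moments).  It does not emulate a registry-based population simulator:
there is no secular trend, no obesity tail, no age–albumin correlation,
and no post-transplant physiology.  Tests that pass on these subjects
therefore validate the *computational pipeline* under plausible
covariates, not the demographic fidelity of any particular cohort — and
the attainment percentages below inherit a few points of uncertainty
from this surrogate.

## Dosing rules and the virtual trial

Two starting-dose policies are built in:

* **licensed**: 1200 mg/m²/day divided over two doses, i.e.
  $600 \cdot BSA$ mg twice daily;
* **chart**: the optimized weight-band chart shipped as
  `published_chart()` — under 20 kg: 250 mg; 20 to under 40 kg: 500 mg;
  40 to under 60 kg: 750 mg; 60–90 kg: 1000 mg, twice daily.

All computed doses are rounded to the 250-mg tablet size; the default
rule rounds to the nearest multiple with ties upward, encoding a
preference for slightly elevated over slightly reduced exposure
(`round_dose()` also offers strict up/down).  `derive_chart()`
regenerates a chart from first principles via
$\text{dose} = CL/F(\text{representative weight}, \text{albumin}) \times
AUC_{target}$; the representative weight (band midpoint by default), the
albumin (33 g/L) and the target (45 mg·h/L, the centre of the 30–60
window) are explicit arguments because no single published choice
reproduces the shipped chart exactly — with mid-window targets the
40–59 kg band lands near the 500/750 boundary.  The shipped chart is
therefore used verbatim for all comparisons, and weights above 90 kg
raise an error (or are skipped with a warning in trial runs) rather than
extrapolating.

`simulate_trial()` evaluates a policy on a population: per subject one
IIV draw on clearance and one IOV draw on bioavailability — the only
random effects that change steady-state AUC — and
$AUC = e^{\kappa}\,\text{dose}/CL_i$.  Residual (assay) error is
deliberately excluded from exposure: it describes measurement, not
pharmacology.  The therapeutic window 30–60 mg·h/L is closed on both
ends.  Runs are paired: the same seed produces identical subjects and
identical random effects under every policy, so policy contrasts are
within-subject.  The default analysis size is 1000 subjects, and the
acceptance checks repeat it over ten seeds; at this size the Monte-Carlo
standard error of an attainment percentage is about 1.5 points.

A consequence of the full variance stack deserves emphasis: combining
IIV on clearance (38.6% CV), IOV on bioavailability (46.1% CV) and the
albumin covariate spread (21% CV through the exponent $-2.49$) gives a
log-scale exposure SD near 0.8, which caps the achievable probability
mass inside a window of ratio 2 (30–60) at roughly 35% *regardless of
dosing policy*.  Simulated attainment is ~29% for the licensed regimen
and ~34% for the chart, with the chart also pulling the median AUC from
above 60 back inside the window.  Reported optimized-attainment figures
in the 40% range are reachable only under a narrower variance stack
(for example, without IOV in the predicted exposure, or with albumin
fixed at its mean); we keep the full stack because each component is
part of the model being evaluated.

## MAP estimation for precision dosing

`map_fit()` computes the posterior mode of a subject's random effects
given the population prior and observed concentrations, minimizing

$$-2\log p = \sum_j\left[\frac{(y_j-f_j)^2}{\sigma^2 f_j^2}
 + \ln(\sigma^2 f_j^2)\right]
 + \sum_k \frac{\eta_k^2}{\omega_k^2}
 + \sum_m \frac{\kappa_m^2}{\omega_{IOV}^2}$$

over the effects with non-zero prior variance ($\eta$ on $CL$, $V_c$,
$Q$; one $\kappa$ per observed occasion; future occasions are taken at
their mode, $F = 1$).  Numerically this landscape is unpleasant — the
proportional weights $1/f_j^2$ make it stiff, and $F$ trades off against
a joint rescaling of $CL$, $V_c$ and $Q$ along a shallow valley that
only the fixed $V_p$ and $k_{tr}$ tilt.  The optimizer is therefore
multi-start (prior mode, a start with $\eta_{CL}$ set from the
trapezoidal AUC of the raw observations, and prior-scale jittered
starts, five in total) and two-stage: a Levenberg–Marquardt pass on the
penalized-least-squares core (data residuals plus prior residuals),
followed by a quasi-Newton polish of the full objective including the
$\ln(\sigma^2 f^2)$ term.  The best candidate is kept, and the returned
mode never scores worse than the prior mode.

Numerical conventions:

* observations at or before the first dose are dropped (under a
  proportional error a structurally-zero prediction carries no
  information), and a subject whose remaining observations are all zero
  is flagged ill-posed and returned at the prior mode;
* when fitting *noise-free* simulated data (recovery studies), the
  fitting $\sigma^2$ should match the generative error: we use
  $10^{-10}$, which makes the data term sharp enough to pin the
  $F$-scaling valley and recover clearance to well under 2%.  With the
  published $\sigma$ the same data legitimately yield a shrunk mode —
  that is Bayesian shrinkage, not an optimizer failure;
* shrinkage is tested by tightening the prior: scaling all $\omega^2$
  down drives $\|\hat\eta\|$ to zero monotonically.  (The textbook
  statement "growing $\sigma^2$ shrinks $\hat\eta$ to zero" is *false*
  for this objective: as $\sigma^2 \to \infty$ the
  $\ln(\sigma^2 f_j^2)$ term keeps pulling predictions downward, and
  the mode converges to the minimizer of $\sum_j \ln f_j^2$ plus the
  prior, not to the prior mode.)

`recommend_dose()` closes the precision-dosing loop:
$\text{dose} = \hat{CL}_i \times AUC_{target}$, future bioavailability
at its mode, rounded to tablets.  In simulation with the published
residual error and the 3-sample limited design (0, 0.5, 2 h), the MAP
AUC estimate has a mean bias within a few percent of truth over 200
replicates — individual estimates scatter considerably (median absolute
relative error ~30%), which is the expected price of three samples under
a 47% assay CV and is why the acceptance bound is on bias, not spread.

## Diagnostics

`gof()` tabulates, per observation, the population prediction (all
effects zero), the MAP individual prediction, and the individual
weighted residual $IWRES = (y - \hat f)/(\hat f \sigma)$.
Linearization-based conditional residuals (CWRES) require the
first-order machinery of a population estimator, which this package
intentionally does not contain; IWRES preserves the diagnostic contract
used in testing — on self-simulated data it is centred with unit-order
spread and vanishes as noise vanishes.

`pcvpc()` implements the prediction-corrected visual predictive check:
each observed and simulated concentration is scaled by
$\text{median}(PRED_{bin})/PRED_{ij}$, removing variability explained by
dose and covariates, then observed 5th/50th/95th percentiles per
time-after-dose bin are compared with confidence bands formed from
`n_sim` full-variability replicate datasets.  Binning is quantile-based
on time after dose (8 bins by default, explicit edges accepted), and
bins with fewer than two observations merge with a neighbour.  Time
after dose, not time after first dose, is the axis, so steady-state
troughs fold onto the absorption profile correctly.  The self-coverage
test simulates 50-subject datasets from the model itself (200
replicates, 20 seeds) and requires the observed median to fall inside
its 95% band in at least 90% of bin-level comparisons; measured coverage
is ~97%.

## Known limitations

* The demographic generator is a parametric stand-in, not a registry
  sample; attainment percentages carry its imprint (see above).
* Total-MPA kinetics only; no enterohepatic recirculation, so secondary
  peaks in real curves will appear as misfit.
* The MAP machinery is a standard empirical-Bayes engine built on the
  published population values; it is not a reproduction of any specific
  clinical TDM software, and population *re*-estimation (FOCE-type) is
  out of scope.
* Confidence intervals of the population parameters are not implemented;
  the published interval for $V_c/F$ is internally inconsistent across
  sources and is deliberately not encoded.
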