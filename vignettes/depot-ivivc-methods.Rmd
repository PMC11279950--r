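---
title: "Mechanistic depot PK modelling and IVIVC: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic depot PK modelling and IVIVC: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-acting injectable (LAI) depot formulations release drug over weeks to
months after subcutaneous injection. Their plasma kinetics are dominated by
the release process rather than by the compound's own elimination
(flip-flop kinetics), so a useful model must separate the
*formulation-driven* part (the release function) from the
*compound-driven* part (clearance and tissue distribution). `depotpk`
implements that separation for a risperidone depot translated from dog to
human, together with the in vitro-in vivo correlation (IVIVC) machinery
used to predict plasma profiles from an accelerated in vitro release
assay.

# Model

## Release

Cumulative release (or in vivo absorption) is a multi-phase Weibull
function

$$F(t) = \mathrm{Max}\,\Big(1 - \sum_{i=1}^{n} f_i
  \exp\big[-(t - T_{lag})^{b_i} / A_i\big]\Big), \qquad n \le 3,$$

with $F(t) = 0$ for $t < T_{lag}$. The phase fractions $f_i$ lie on the
simplex ($f_i \ge 0$, $\sum f_i = 1$, enforced to $10^{-6}$ at
construction), the time-scale factors $A_i > 0$ divide the *powered* time
and therefore carry units $h^{b_i}$, and the shapes $b_i > 0$ are
dimensionless. The divisor convention matters: with the dog parameter set
(phase-2 scale 6370.7, shape 1.285) it yields a half-release time of about
24 days, consistent with a one-month depot, whereas the alternative
$((t-T_{lag})/A')^b$ convention would imply multi-year release. The two
conventions are related by $A' = A^{1/b}$; `print.weibull_release` shows
the per-phase half-release times $(A \ln 2)^{1/b}$ to make fitted scales
interpretable. Phase order does not affect the curve; `sort_phases()`
canonicalises by characteristic time for comparisons.

## Disposition and the depot

Plasma kinetics use a central compartment (volume `Vc` in L/kg times body
weight, clearance `CL` in L/h) with an optional peripheral compartment
(`K12`, `K21`). The depot model adds two states upstream of plasma:

* a *formulation* depot that drains at the analytic release rate
  $\mathrm{dose} \cdot F'(t)/100$;
* an *injection-site* tissue (volume `V_site`, blood flow `Q_site`) that
  exchanges with plasma perfusion-limited,
  $\mathrm{flux} = Q_{site}\,(C_p \cdot B\!/\!P - C_{site} \cdot B\!/\!P / K_p)$,
  where `Kp` is the site tissue:plasma partition coefficient.

`Kp` is the compound-driven distribution parameter: it is identified from
immediate-release sc data independently of any formulation property, which
is what makes the staged calibration meaningful. The full whole-body
physiology of commercial PBPK platforms is deliberately reduced to this
minimal mechanistic system; the reduction preserves the separation of
compound- and formulation-driven kinetics that the approach relies on,
at the cost of not resolving individual organs.

Internal canonical units are hours, litres, milligrams and ng/mL.

## Metabolite tracking and IVIVE clearance

The active 9-hydroxy metabolite is fed by a fraction `fraction_formed` of
parent hepatic elimination with the molar-mass correction
(410.49 to 426.48 g/mol) and eliminated with its own clearance
(literature value 80 mL/min). `fraction_formed` defaults to 1 —
hydroxylation is the dominant pathway and no split is reported — and the
metabolite volume must be supplied explicitly rather than defaulted.

Human clearance is scaled from recombinant-CYP Michaelis-Menten constants:
$CL_{int,u} = \sum_e (V_m/K_m)_e \cdot \mathrm{abundance}_e \cdot
\mathrm{MPPGL} \cdot \mathrm{liver\ mass}$, converted to L/h, then the
well-stirred model $CL_h = Q_h f_{u,b} CL_{int,u} / (Q_h + f_{u,b}
CL_{int,u})$ with $f_{u,b} = f_u / (B\!/\!P)$. The scaling constants
(abundance CYP3A4 137 and CYP2D6 8 pmol/mg microsomal protein, MPPGL 40
mg/g, liver 1800 g, $Q_h$ 90 L/h) are literature-typical defaults and
fully configurable; both CYP2D6 assay entries and CYP3A4 are summed by
default, with an `enzymes` argument to restrict the set.

## Staged calibration

1. `fit_iv()` — closed-form 1- or 2-compartment fit of iv data; clearance
   must come from an immediate-release route because flip-flop kinetics
   make it unidentifiable from depot data.
2. `fit_kp()` — single-parameter search for `Kp` in [0.01, 100]
   (log-scaled) against immediate-release sc data with clearance frozen.
3. `fit_release_in_vivo()` — the Weibull release fitted through the full
   depot simulator with disposition and `Kp` frozen.

All stages minimise unweighted SSR on untransformed concentrations (a log
objective is available by flag since profiles span decades), consume one
geometric-mean profile rather than per-subject data, and are deterministic
given `(seed, n_starts)`. Parameter bounds: `CL` [0.1, 100] L/h, `Vc`
[0.05, 20] L/kg, Weibull scales $10^{[-3, 8]}$, shapes [0.2, 5]; boundary
hits are flagged, not silently accepted.

## IVIVC

`deconvolve()` performs mechanistic deconvolution: a triple-Weibull
absorption function is fitted through the depot simulator to the observed
human profile of each strength, and the fitted Weibull evaluated at the
observation times is the in vivo absorbed-fraction series. The series is
evaluated literally (the asymptote `Max` multiplies the bracket), so a
strength whose fitted `Max` is below 100 plateaus below 100%; a
`normalize` flag rescales to the asymptote for users who prefer 0-100
fractions.

`levy_time_scaling()` pairs in vitro and in vivo times at matched
fractions (default grid 5-80% in 5% steps — fine enough to use the
curves' information without extrapolating beyond either end) by linear
interpolation of the raw series (a flag switches to inversion of fitted
Weibull curves), pools all strengths, and regresses through the origin.
One pooled slope is the default because a per-strength factor is not
common practice with two strengths; the per-strength alternative is
available by calling the function per strength.

`fit_correlation()` fits linear, quadratic, cubic, square-root (Higuchi
form), logistic and Gompertz families and selects by $R^2$, breaking
exact ties (within $10^{-9}$) toward fewer coefficients. The full
leaderboard is returned so model selection is auditable.

`convolve_predict()` scales the in vitro clock by the Levy slope, maps
percent released through the correlation model, and uses the resulting
monotone piecewise-linear absorbed schedule (flat beyond the last point)
as the depot drain. Correlation outputs below zero are clamped to zero
with a warning count; outputs above 100% are *not* capped by default —
terminal overprediction is a real failure mode that capping would hide —
with an optional `cap`.

`internal_validation()` computes per-strength percent prediction errors
$100\,|obs - pred|/obs$ for Cmax and AUC and their arithmetic means. The
Level-A verdict uses the extended-release guidance bound: mean PE at most
10% for both metrics, with each strength also reported against 15%. The
AUC metric is AUC to the last shared time point (`auc_last`), matching
how depot validation tables are reported, rather than the extrapolated
AUC used for single-profile summaries.

## Noncompartmental analysis

`exposure_summary()` reports Cmax/Tmax (earliest time on ties), AUC by
the pure linear trapezoid (no log-down rule; switchable behaviour was
considered and rejected to keep the single documented method), and
$\lambda_z$ from the terminal log-linear regression. The terminal window
is the set of at least three positive points strictly after Tmax ending
at the last positive point that maximises adjusted $R^2$ (ties toward
fewer points); if the best window has adjusted $R^2 < 0.80$ the
extrapolated AUC is reported absent with a reason code instead of a
number. Leading zeros are kept in the trapezoid; embedded zeros are
excluded from the regression.

# Synthetic data

No raw study data are public, so `gen_pk_dataset()` and
`gen_invitro_dataset()` generate every input from the printed truth
parameter sets (`dog_release_truth()`, `human_release_truth()`,
`dog_disposition_truth()`, `risperidone_mm_truth()`) on the studies'
sampling schedules (`design_dog_iv()` and friends).

* PK noise is multiplicative lognormal with geometric CV 15% (typical of
  combined bioanalytical and inter-animal variability; the true CVs are
  unpublished) and median-unbiased centring, so geometric-mean summaries
  recover the truth curve. LLOQ 0.05 ng/mL; values below it are zero.
* In vitro replicate noise is applied to the *increments* of the
  cumulative curve with mean-unbiased centring, so replicates are
  non-decreasing by construction and the arithmetic replicate mean is
  centred on the truth — matching how dissolution data are averaged.
* The human disposition truth uses the IVIVE clearance and assumes the
  central volume (1.13 L/kg) carries over from dog, the same preservation
  assumption made for `Kp` and the release function.
* The in vitro truth for the demo pipeline is the in vivo absorption
  run on an 11-fold accelerated clock (scales divided by $11^{b_i}$),
  so the Levy step has a well-defined quantity to recover.

What the generator does **not** emulate: between-subject variability in
disposition (noise is purely multiplicative on one truth curve), dropout
and missingness, assay interference, or any species difference in the
release mechanism — the synthetic dog-to-human translation is exact by
construction. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and well-conditioned under the stated
noise, not that the biological preservation assumptions hold in real
data; the original study in fact found the release profile to be
species-dependent.

# Numerical choices

* **Reference simulator.** `simulate_depot()` integrates with `lsoda`
  (relative tolerance $10^{-10}$, absolute tolerance scaled by dose so
  that linearity is preserved to machine precision) and asserts mass
  balance — released = site + central + peripheral + eliminated — at
  every output time, reported as an attribute (typically $10^{-12}$
  relative).
* **Fitting path.** The depot system is linear and time-invariant, so
  fitting objectives use an exact exponential integrator: the system
  matrix is eigendecomposed once and the release input, taken
  piecewise-linear on a dense log-spaced node grid (500 nodes) and
  rescaled per interval to deliver the exact cumulative-release
  increment, is propagated analytically. The rescaling handles the
  integrable rate singularity of shapes below 1 at the lag. Agreement
  with `lsoda` is about $10^{-5}$ relative at a fraction of the cost.
* **Variable projection.** Given the nonlinear parameters (lag, shapes,
  characteristic times $A^{1/b}$), both the closed-form curve and the
  depot response are linear in the products $\mathrm{Max} \cdot f_i$.
  All Weibull fitters therefore search only the nonlinear space, solving
  the linear coefficients in closed form (clipped at zero, capped at
  100%), multi-started from a deterministic coarse grid — characteristic
  times as multiset combinations, since phases may share a time scale
  and differ only in shape — plus seeded random draws, and finish with a
  bounded Levenberg-Marquardt polish in the full parameter space that
  enforces the simplex exactly. This is what makes 11-parameter
  triple-Weibull deconvolution reliably recover its generating
  parameters from noise-free data.
* **Degenerate input.** Constant series, all-zero profiles and
  fewer-points-than-parameters designs are errors, not warnings;
  slightly non-monotone cumulative series (violations under 2 percentage
  points) are repaired by isotonic projection, larger violations are
  errors; optimiser non-convergence is flagged on the result.
* **Determinism.** Every stochastic component (noise generation,
  multi-start draws) derives from an explicit seed; the pipeline stamps
  each artifact with the seed and an MD5 hash of the resolved
  configuration, and reruns are bit-identical.

# Problem sizes

The test-suite simulations use the studies' own designs: 15-19 point dog
schedules, the 7-point repeat-dose LAI schedule, the 36-point human
single-dose schedule, the 16-point in vitro grid with 12 replicates, and
10 synthetic dogs at 15% CV for the noisy-recovery checks. Monte-Carlo
calibration checks use 400-10,000 draws. The end-to-end pipeline demo
runs both strengths (50 and 225 mg) with 6-16 optimiser starts per fit.

# Known limitations

* The reduced site model has two free physiological constants
  (`V_site` 0.1 L, `Q_site` 1.2 L/h per 10 kg body weight, scaled
  linearly) that are plausible defaults, not measurements; they are
  exposed in every constructor and in the pipeline configuration.
* Single-dose only; repeated-dose superposition and steady-state metrics
  are out of scope.
* Linear elimination throughout; saturable metabolism is not modelled at
  depot-relevant concentrations.
* The iv infusion duration of the original dog study is unstated (its
  observed Cmax exceeds the theoretical bolus C0); simulations default
  to a bolus.
* External validation requires additional strengths and is not part of
  the package's claims.
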