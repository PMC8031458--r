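---
title: "Solubility correlation and apparent dissolution thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solubility correlation and apparent dissolution thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(soluthermo)
```

## The measurement and its containers

A saturation shake-flask study equilibrates excess solid drug with a
solvent system at controlled temperature, assays the supernatant, and
reports the mole-fraction solubility

$$x_e = \frac{m_1/M_1}{m_1/M_1 + m_2/M_2},$$

with $m_1, M_1$ the solute mass and molar mass and $m_2, M_2$ those of
the solvent system.  `soluthermo` stores one sample's $(T, x_e)$ series
as a `solubility_curve` — the unit all downstream analyses operate on.
Temperatures are kelvin only; values below 200 K are rejected as probable
Celsius entries, because every expression below involves absolute
temperature and a silent unit error would corrupt every derived quantity.
Replicate measurements at one temperature are reduced to their arithmetic
mean (with the count retained): the simplest defensible reduction when,
as is typical, only per-temperature point values are published for
triplicate experiments.

For micellar media the single solvent term of the mole-fraction formula
is ambiguous.  `mole_fraction_from_masses()` therefore supports two
explicit conventions: `"aqueous"` (default) folds the surfactant mass
into the water term, `"two_component"` counts the surfactant's own moles.
At millimolar surfactant loadings the two differ by well under 2%, but
the choice is an argument, never an assumption.

Assay concentrations (µg/mL) convert to mole fraction under the
dilute-solution approximation that solution density equals solvent
density; this is exact enough below $x \approx 10^{-4}$ (relative error
of the linearized form under 0.1%) and is the convention under which
1.74 µg/mL of simvastatin in water corresponds to $7.49\times10^{-8}$
mole fraction.

## Correlation models

Both standard correlations are linear in their parameters once written
in $\ln x$:

- van't Hoff: $\ln x = a + b/T$ — fitted for any curve with $\ge 2$
  points;
- modified Apelblat: $\ln x = A + B/T + C\ln T$ — fitted for $\ge 3$
  points.

Fitting is ordinary unweighted least squares in $\ln x$ space, solved by
QR factorization.  Although the Apelblat model is often fitted by
nonlinear optimizers, the log-space formulation makes the solution exact
and deterministic; the fitted solubilities are identical.  Two
goodness-of-fit numbers are reported per fit, on the two scales users
care about:

- $R^2$ in $\ln x$ space (the space of the regression), and
- RMSD% $= 100\sqrt{\tfrac1N\sum\big((x^{fit}-x_e)/x_e\big)^2}$ on the
  back-transformed solubilities.

This combination is the one that reproduces published correlation tables
for this kind of study; fitting in $x$ space does not.

Over a typical 20 K span, $1/T$ and $\ln T$ are nearly collinear.  The
exact condition number of the Apelblat design is computed at every fit;
beyond $10^{10}$ a warning is raised and recorded on the object.  The
fitted curve remains reliable in that regime — only the individual
parameters lose meaning, which is also why three-point Apelblat
parameter tables should never be interpreted, merely evaluated.  A
three-point Apelblat fit is interpolatory (RMSD exactly 0), so nonzero
published three-point Apelblat RMSDs imply additional unpublished data;
such parameter tables are treated as non-reproducible and excluded from
validation targets here.

`predict()` evaluates a fit at new temperatures and flags any point
outside the fitted range — extrapolation, typically to 298.2 K, is the
standard way ambient solubility is estimated from elevated-temperature
measurements, and deserves an explicit flag rather than silence.

## Apparent thermodynamics at the mean harmonic temperature

Regressing $\ln x_e$ on the centred regressor $u = 1/T - 1/T_{hm}$, with
$T_{hm} = n/\sum_i 1/T_i$ the mean harmonic temperature, decorrelates
slope and intercept estimates (Krug's argument), and gives

$$\Delta_{sol}H^0 = -R\,\frac{\partial \ln x_e}{\partial u}, \qquad
  \Delta_{sol}G^0 = -R\,T_{hm}\cdot\text{intercept}, \qquad
  \Delta_{sol}S^0 = \frac{\Delta_{sol}H^0 - \Delta_{sol}G^0}{T_{hm}}.$$

Design choices worth stating:

- $T_{hm}$ defaults to the harmonic mean of the data's own temperatures
  (309.985 K for a 300.2/310.2/320.2 K design) but accepts an override
  for replaying published tables computed at a stated reference.
- $\Delta_{sol}S^0$ uses the difference form, so the Gibbs identity
  $\Delta G = \Delta H - T_{hm}\Delta S$ holds to machine precision by
  construction.  The algebraically equivalent route $R\,a$ is kept as a
  cross-check property in the tests, not as the implementation.
- The centred regression and the closed-form identities on van't Hoff
  parameters ($\Delta H = -Rb$, $\Delta G = -R(T_{hm}a+b)$) are affine
  reparameterizations of the same least-squares problem; the package
  exposes both (`apparent_thermodynamics()`, `thermo_from_vant_hoff()`)
  and tests their agreement to $10^{-9}$ relative.
- $R = 8.314$ J/(mol K), the four-significant-figure value conventional
  in this literature; using more digits shifts third-decimal places in
  kJ/mol quantities and worsens agreement with published tables.

Units follow field convention: kJ/mol for enthalpy and Gibbs energy,
J/(mol K) for entropy, converted once at result construction.

A caution on sign classification near zero: when the true entropy is
small (a few tenths of J/(mol K)), refitting from solubilities printed
to 3 significant figures can flip its sign — the intercept of the
centred regression is then smaller than the rounding noise.  The
packaged simvastatin study contains exactly one such sample (5 mM
Tween-20, published $\Delta_{sol}S^0 = 0.39$ J/(mol K)), whose refit
from the printed data gives $-0.03$ J/(mol K).  Classifications that
close to zero should be read as "approximately isentropic".

## Ideal solubility

From fusion calorimetry,

$$\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
 + \frac{\Delta C_p}{R}\Big[\frac{T_{fus}-T}{T} + \ln\frac{T}{T_{fus}}\Big],$$

valid for $0 < T \le T_{fus}$ (the melt regime is rejected).  When
$\Delta C_p$ has not been measured it defaults to the fusion entropy
$\Delta S_{fus} = \Delta H_{fus}/T_{fus}$ — the classical substitution,
and the one under which the packaged simvastatin profile reproduces its
published ideal-solubility values (68.72 J/(mol K) for simvastatin).
Configs may state the enthalpy in kJ/mol or J/mol; it is converted once
on read.  Both terms of the expression are returned separately so their
relative size can be inspected; with $\Delta C_p = 0$ the second term
vanishes and the classical ideal-solubility expression remains.

## Hansen parameters and solubilization capacity

`hansen_total()` combines components as
$\delta = \sqrt{\delta_d^2+\delta_p^2+\delta_h^2}$.
`hansen_table_check()` recomputes each total of a published table and
flags relative deviations above a tolerance; with `digits = 1` the
recomputed total is first rounded to the table's printed precision, so
the check asks "is the printed total the correctly rounded combination
of the printed components?".  In the packaged table exactly one row
fails (the drug itself: $\delta_d = 46.60$ is inconsistent with
$\delta = 18.70$ — evidently a transcription error in the source table,
which the checker exists to catch).

Micellar solubilization capacity is
$S_c = (S_t - S_w)/(C_s - \mathrm{CMC})\times1000$ (mmol drug per mol of
micellized surfactant).  CMC values are required inputs: they are
surfactant- and temperature-specific and no defensible default exists.
`CMC = 0` is accepted for the common "all surfactant micellized"
approximation but always announced with a warning.  Solubilities given
as mole fractions are converted to molarity with the dilute aqueous
factor 55.49 mol/L when requested.

## The synthetic-data generator

`synthetic_spec()` + `generate_curve()` emulate the shake-flask design:
3 temperature levels in 300–320 K, triplicate flasks per level, and
multiplicative lognormal measurement noise — Gaussian on $\ln x$ with
`noise_sd_ln = 0.014` by default, matching the ~1.4% relative standard
uncertainty typical of these assays.  Replicates are averaged exactly as
real replicates are.  A single integer seed controls all randomness;
`recovery_study()` seeds once and lets each Monte Carlo replicate consume
the stream, so a study of any size is reproducible from one integer.

What the generator does *not* emulate: equilibration kinetics (the 72 h
approach to saturation), assay calibration error structure, temperature
control error, or error in the surfactant concentration.  Passing
recovery tests therefore validates the estimation chain — generator,
fitter, thermodynamic identities — under the stated noise model, not the
chemistry of any particular real system.

Recovery studies report bias, RMSE and empirical standard deviation for
$a, b, \Delta H, \Delta G, \Delta S$.  Under the linear noise model the
OLS slope is unbiased and its sampling standard deviation has the closed
form $\sigma/\sqrt{\sum_i(z_i-\bar z)^2}$ ($z = 1/T$); the test suite
checks the empirical value against this at 2000 replicates within 5%, a
margin set by the Monte Carlo error of a standard-deviation estimate at
that size ($\approx 1.6\%$).

## Orchestration and reporting

`run_full_analysis()` runs every stage over a curve list: both
correlations per curve, overall RMSD (the arithmetic mean of per-sample
RMSDs, which is how "average RMSD" is used in this literature — not a
pooled deviation), apparent thermodynamics at a common $T_{hm}$, and the
ideal-solubility profile.  Outputs are CSV (15 significant digits, so
numeric round trips are exact to more than 12) plus an aligned-text
summary (solubilities in 3-significant-digit scientific notation,
energies to 2 decimals, matching how such tables are printed).  Every
warning raised during the run — conditioning, CMC defaults,
extrapolation — is captured into the report's provenance section.  A
failing stage aborts with a stage-named error and removes partial
outputs, so an output directory never holds a half-written analysis.

## Problem sizes and runtime

Everything here is desk scale: the packaged study is 25 curves × 3
temperatures, each fit a 2–3 parameter least-squares solve.  The test
suite's largest computation is the 2000-replicate recovery study
(seconds); the full suite runs in a few seconds on one CPU.

## Known limitations

- No activity-coefficient models: the analysis is "apparent"
  thermodynamics of the saturated solution as measured, not transfer
  thermodynamics.
- No alternative correlations (Buchowski–Ksiazczak, NRTL, Wilson) and no
  weighted or robust regression.
- Uncertainty is not propagated from reported relative uncertainties of
  solubility measurements; goodness of fit is the only error summary.
- Hansen components are inputs; the package only combines and checks
  them, it does not estimate them from structure.
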