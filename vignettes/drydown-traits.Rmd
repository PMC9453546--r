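---
title: "Models and methods for dry-down trait extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dry-down trait extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotraits)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic data generator can and cannot tell you about real
measurements.

## Sign and unit conventions

All plant water potentials are signed megapascals (MPa, ≤ 0). The single
exception is the applied tension of a vulnerability curve, which is stored
as positive MPa (the pressure-sleeve convention); fitted P50/Px values are
converted back to signed MPa on output. The osmotic potential at full
turgor π~o~ is reported as a positive magnitude, the convention of trait
tables, while Ψ~TLP~ stays negative. Conductances are mmol m^-2^ s^-1^,
photosynthesis µmol m^-2^ s^-1^, iWUE mmol CO~2~ mol^-1^ H~2~O. The CSV
readers enforce the sign rule: a potential column that is entirely
positive is interpreted as magnitudes and negated (with a message); mixed
signs are a schema error.

## Hydroscape and σ

Regressing Ψ~min~ on Ψ~pd~ by OLS gives slope σ and intercept *a*. With
σ < 1 the line meets the 1:1 line at *b* = *a*/(1 − σ), and the enclosed
area — the hydroscape — is |*a·b*|/2 = *a*²/(2(1 − σ)). The area is
extremely sensitive to σ when σ is high (d Area/dσ = *a*²/(2(1 − σ)²)),
which is worth remembering when comparing cultivars whose areas differ by
less than ~10%: small slope errors translate into large area errors.
Records with Ψ~min~ > Ψ~pd~ are physically inconsistent (a leaf cannot be
wetter at midday than at predawn under transpiration) and are excluded
from this fit but counted in the diagnostics; well-watered controls are
excluded by default because the hydroscape is a dry-down construct.
σ ≥ 1 means the regression never meets the 1:1 line; the area is reported
as infinite rather than `NaN`, and `hydroscape_area()` treats it as an
error.

## The triphasic water-potential curve

The dry-down trajectory of Ψ~min~ against Ψ~pd~ is modelled as a
continuous piecewise line with three phases: a steep initial decline
(slope β₁), a gentler middle phase (β₂), and a flat terminal phase (β₃),
with boundaries Θ₁ and Θ₂ on the Ψ~pd~ axis (Θ₂ < Θ₁ < 0). For fixed
breakpoints the model is linear, so the fitter profiles the residual sum
of squares over (Θ₁, Θ₂):

1. a deterministic grid of breakpoint pairs over the inner 80% of the
   Ψ~pd~ range (10 positions per breakpoint) is scored;
2. the twelve best starts are refined by iterative relinearization (the
   gap-covariate update of segmented regression) with step halving,
   tolerance 10^-8^ on the breakpoints, at most 100 iterations;
3. a Nelder–Mead polish of the profile RSS is run from every basin the
   multistart visited, because the relinearization can stall on the
   kinked, locally flat profiles that noisy data produce;
4. breakpoint standard errors come from the final linearization
   (SE(Θ) = SE(γ)/|δ|).

**Identifiability.** Breakpoints closer than 0.05 MPa to each other or to
the edge of the observed range are declared unidentifiable, as are fits
whose adjacent phases have indistinguishable slopes (data on a single
line). One subtlety is deliberate: on smooth, convex trajectories the
*global* least-squares optimum sometimes collapses both breakpoints onto
a single sharp bend. When an identifiable solution exists within 0.5% of
that collapsed optimum's RSS the fitter prefers it — the two fits are
statistically indistinguishable and only one of them estimates the
quantity the model is for. Only a decisively better collapsed optimum is
reported as an error. Monte-Carlo analysis against an exhaustive
breakpoint grid search (the test suite's oracle) shows the estimator is
information-limited at realistic residual scales: at a residual SD of
0.27 MPa on a 4 MPa range with n = 60, the median error of Θ̂₁ is about
0.2 MPa for the exhaustive search and the package fitter alike.

The Ψ~pd~ = Ψ~min~ point — the limit of stomatal control — is the
intersection of the fitted curve with the 1:1 line. Both the full
piecewise function (with the terminal phase extended beyond the data) and
the terminal-phase line alone are available; they coincide whenever the
crossing falls in the terminal phase. Crossings beyond the observed range
are flagged as extrapolated.

## Weibull vulnerability curves

Relative conductivity is modelled as K(P)/K~max~ = exp(−(P/b)^c^).
Fitting is done on relative conductivity, not PLC, which keeps the error
structure of the flow measurements simple; each stem is normalized by its
own K~max~ (an explicit `kmax` column, or the flushed measurement at
pressure 0) before pooling. The optimizer is Levenberg–Marquardt from a
deterministic multistart (c ∈ {1, 2, 4, 8} crossed with two data-driven
scale guesses), best RSS wins. Px follows in closed form,
Px = b·(−ln(1 − x/100))^1/c^. PLC values marginally outside [0, 100] from
measurement noise are clipped with a warning, never errors. Bootstrap
confidence intervals for P50 use case resampling of the pooled
observations with percentile intervals (n = 1000 by default, seeded);
replicates that fail to refit are dropped and a failure rate above 20%
flags the interval as unstable. Curves whose observed PLC never reaches
50% yield an extrapolated-P50 warning.

## Pressure–volume traits

Beyond the turgor loss point the potential is purely osmotic, so 1/Ψ is
linear in 100 − RWC. The TLP detector grows a candidate tail from the
three driest points and keeps the longest tail whose linear fit retains
R² ≥ 0.99; a wet-end trim then removes leading points whose residual
exceeds three tail RMSEs. The trim matters: on noiseless ideal curves the
R² rule alone overshoots the inflection by one sample (a single
supra-TLP point barely dents R²), which would break sub-percent trait
recovery. If the best achievable tail has R² < 0.98 there is no
detectable osmotic region and the curve is rejected; a tail that spans
the whole series means no turgid phase was observed (degenerate, flagged).

π~o~ = −1/intercept of the tail line at RWC = 100. Turgor is
Ψ~p~ = Ψ − Ψ~π~ with Ψ~π~ = −π~o~·100/RWC under the zero-apoplast
convention (the apoplastic fraction is not estimated; it is exposed as a
modelling convention, not a measured quantity). The modulus of elasticity
ε is the slope of Ψ~p~ against RWC/100 over the supra-TLP points, and the
capacitance at full turgor is
C~FT~ = slope(RWC/100 vs Ψ) · (m~sat~ − m~dry~)/(M~w~·A) with
M~w~ = 18.015 g mol^-1^ and A the leaf area — the package's documented
normalization, chosen to produce the conventional mol m^-2^ MPa^-1^
units. Without a leaf area only the mass-normalized value is returned.

## Stomatal decline and Ψ~gs90~

The first-order kinetic model is gs(Ψ) = g₀·e^kΨ^ (Gauss–Newton with
numeric derivatives; an optional third parameter adds a conductance floor
g~min~ for data with residual cuticular conductance). Ψ~gs90~ follows in
closed form as ln(0.1)/k and is exactly the root of
gs(Ψ) = 0.1·g₀ — the self-consistency the test suite checks by bisection.

A weighted polynomial alternative (degree 2 by default, weights
proportional to observed gs so near-closed stomata do not dominate) is
also provided, with its reference conductance taken as the fitted value
at the least negative observed Ψ and Ψ~gs90~ as the most negative real
root of fitted(Ψ) = 0.1·gs~ref~ in (or just beyond) the observed range.
**Known limitation:** a quadratic cannot follow an exponential decline
down to 10% of its reference. On kinetic-model data the degree-2 estimate
carries a deterministic, conservative (more negative) truncation bias of
roughly 0.15·|Ψ~gs90~| — about 0.25–0.35 MPa at decline rates typical of
woody crops — and on restricted ranges it may find no 10% crossing at
all. The pipeline therefore reports the kinetic estimate in its trait
table and logs the polynomial one as advisory. The polynomial's gs~ref~
convention also means that on dry-down data that never approaches Ψ = 0
it measures closure relative to an already-stressed reference — a
different quantity from the kinetic Ψ~gs90~.

Per-cultivar kinetic curves are compared against a pooled fit by the
extra-sums-of-squares F test. The test assumes homoscedastic errors;
strongly multiplicative measurement noise makes it anticonservative.

## The synthetic dry-down generator

The generator exists to give every estimator inputs with known ground
truth and the right qualitative structure; it is a minimal water-balance
construction, not a mechanistic soil–plant model. Each simulated day:

1. Ψ~pd~ = −a·(100/GWC − 1)^n^ (substrate retention; a = 1.6 MPa, n = 1);
2. Ψ~min~ solves the supply–demand balance
   Ψ~min~ = Ψ~pd~ − E(Ψ~min~)/(K~plant~·relK(Ψ~min~)), where
   E = E~max~·e^kΨ^ + e~cut~·e^Ψ/3^ combines the kinetic stomatal decline
   with a cuticular component that fades as the leaf dehydrates, and
   relK is the Weibull curve floored at 0.15 (residual, non-vascular
   pathways). The root is bracketed and solved by `uniroot`; a missing
   root (runaway cavitation) is a simulation error naming the day;
3. the transpired mass (E · canopy area · effective seconds · 18.015 g
   mol^-1^) is removed from the substrate. Well-watered controls hold GWC
   at 90%.

The cuticular term and the conductance floor are deliberate departures
from the simplest E ∝ gs closure: without them the Ψ~pd~–Ψ~min~ gap
collapses exponentially and simulated σ falls to 0.5–0.7, far below the
0.8–0.9 regime that real dry-down studies report; residual water loss
through the cuticle is the standard physical mechanism that keeps the gap
open.

Three presets ("avijor-like", "isabelona-like", "soleta-like") span the
isohydric–anisohydric continuum. Their trait targets (gs~max~, E~max~,
A~max~, Ψ~gs90~, π~o~, Ψ~TLP~, P50, SWC) are patterned on published
almond cultivar values; the three free water-balance constants per preset
(K~plant~, e~cut~, effective transpiring time) were calibrated once, by
Newton iteration, so that the attenuation-corrected OLS expectation of
(a, σ) over a 50-day simulation matches the geometry implied by the
published (σ, hydroscape) pairs and the final substrate water content
matches the published end-of-experiment values. The calibration was done
while designing the generator and is frozen; it is not adjusted per run.
Because the ideal zero-apoplast PV model links π~o~, ε and Ψ~TLP~, the
presets pin π~o~ and Ψ~TLP~ and derive ε = π~o~·|Ψ~TLP~|/(|Ψ~TLP~| − π~o~)
(≈ 5–6 MPa) rather than carrying an independent ε; simulated RWC~TLP~
follows the same identity.

Observation noise is Gaussian per channel, with one user seed fanned out
to independent per-channel substreams (so adding noise to one channel
never shifts another): 0.02 MPa on chamber potentials (instrument
precision with duplicate leaves), 5% relative on gas-exchange channels,
0.005 MPa on bench PV potentials, 1 mg on PV masses, 5 g on pot weights.
All replicate plants share one true trajectory and differ only in
observation noise.

**What passing tests do and do not show.** The generator emulates the
central structure of a dry-down — monotone depletion, a supply–demand Ψ
gap, Weibull cavitation, ideal PV curves — with purely observational
noise. It does not emulate plant-to-plant biological variation, leaf
shedding, osmotic adjustment over time, soil–root interface resistance,
or weather-driven demand fluctuations. Parameter recovery on these
inputs validates the estimators' correctness, not their robustness to
those unmodelled features; in particular the piecewise residual scale of
simulated trajectories (~0.02 MPa) is an order of magnitude below the
~0.3 MPa of real curves, where biological scatter dominates.

## Problem sizes

The shipped study conditions are 50 days × 8 plants per treatment and
cultivar, 3 stems × 11 pressure steps per vulnerability curve, and 4
leaves × 41 points per PV curve — the scale of the pot experiment the
generator emulates. The test suite's Monte-Carlo checks use 100–200
replicates and 300–1000 bootstrap resamples.

## Known limitations

- The hydroscape's 1/(1 − σ)² sensitivity makes area comparisons between
  similar cultivars fragile at realistic noise; report σ alongside it.
- The three-segment model is fixed (a `n_segments` override exists); no
  automatic model selection over segment counts is attempted, and on
  smooth trajectories the breakpoints may be genuinely unidentifiable
  (reported as such, or as an identifiable near-tie when one exists).
- The degree-2 polynomial Ψ~gs90~ is structurally biased on exponential
  declines (above); treat it as a descriptive companion to the kinetic
  estimate, not a replacement.
- PV analysis assumes zero apoplastic water and no oversaturation
  correction; extracted RWC~TLP~ is tied to those conventions.
- The extra-sums-of-squares comparison assumes homoscedastic errors.
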