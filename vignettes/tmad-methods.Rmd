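---
title: "Modelling exhaled carbon monoxide with a trumpet model with axial diffusion"
author: "tmad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exhaled carbon monoxide with a trumpet model with axial diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmad)
```

## The problem

Exhaled carbon monoxide (eCO) is a candidate biomarker of oxidative stress
and respiratory disease, but a single end-tidal number cannot distinguish
whether an unusual value reflects blood carboxyhemoglobin, lung diffusion
properties, an airway contribution, or exposure.  Real-time expirograms —
CO concentration sampled continuously over a single exhalation — carry much
more information, provided a physiological gas-exchange model connects
their shape to interpretable parameters.  This package implements such a
model: a one-dimensional *trumpet* representation of the symmetric airway
tree with gas-phase axial diffusion (TMAD), the associated parameter
estimation from tissue/blood data, breathing-maneuver simulation,
expirogram analysis, and parameter fitting.

## The model

The airway tree (Weibel generations 0–23) is collapsed onto an axial
coordinate $z$ from the mouth ($z=0$) to the distal end of the alveolar
region ($z=L=27.2$ cm).  The conducting airways occupy $[0, L-z_1]$ with
cross-section

$$A_{c,aw}(z) = A_{c,1}\left(\frac{L-z}{z_1}\right)^{-m},\qquad
A_{c,1}=217\ \mathrm{cm^2},\ z_1=0.6\ \mathrm{cm},\ m=2 ,$$

and the final $z_1$ centimetres hold the alveolated generations 17–23,
with rescaled per-generation areas taken directly from the bundled
morphometric table.  The mole-fraction concentration $C(z,t)$ (ppb) obeys
the mass balance

$$\Bigl[A_{c,aw}(z) + \tfrac{N_{alv}(z)}{N_t}A_{c,A}\Bigr]\,
\frac{\partial C}{\partial t} =
-\dot V \frac{\partial C}{\partial z}
+ D_{gas}\frac{\partial}{\partial z}\Bigl[A_{c,aw}(z)\frac{\partial C}{\partial z}\Bigr]
+ (J'_{aw} - D'_{aw} C)\Bigl[1-\tfrac{N_{alv}(z)}{N_{max}}\Bigr]
+ (J'_{A} - D'_{A} C)\tfrac{N_{alv}(z)}{N_t},$$

with constant volumetric flow $\dot V$ (positive during inhalation,
negative during exhalation), gas-phase diffusivity $D_{gas}$ (0.21 cm²/s
for CO, 0.23 for NO), and four exchange parameters: the total maximum
fluxes $J_{aw}, J_A$ (pl/s) and diffusing capacities $D_{aw}, D_A$
(pl s⁻¹ ppb⁻¹) of the airway and alveolar compartments.  The ratios
$J_{aw}/D_{aw}$ and $J_A/D_A$ are the airway-tissue and alveolar
equilibrium concentrations.  Working in ppb, cm and seconds, the identity
1 pl/s ≡ 1 ppb·cm³/s makes all terms consistent without conversion
factors.

### Axial weights and the alveolar storage term

Two readings of the printed equation needed to be fixed by behaviour
rather than by dimensional analysis, and both choices are deliberate:

* **Airway source weight.**  The total airway flux is distributed
  uniformly *per unit axial length*, attenuated by $1-N_{alv}/N_{max}$
  where alveoli displace airway tissue:
  $w_{aw}(z) \propto 1-N_{alv}(z)/N_{max}$, normalized so
  $\int w_{aw}\,dz = 1$.  Because the conducting airways are narrow, the
  per-volume exchange rate $D_{aw} w_{aw}/A_{c,aw}$ is then large near the
  mouth (~0.5 s⁻¹) and small distally.  This reproduces the observed
  breath-hold behaviour — conducting-airway gas is enriched toward the
  tissue level within tens of seconds — and gives the early exhalation
  window its sensitivity to $J_{aw}$.  The alternative (per unit gas
  volume, $w_{aw}\propto A_{c,aw}$) gives an exchange rate of ~2·10⁻³ s⁻¹
  everywhere, under which a breath-hold would leave airway gas essentially
  unchanged, contradicting the phenomenology the model exists to capture.

* **Alveolar storage.**  The storage coefficient uses the total alveolar
  cross-section $A_{c,A}=39\,444$ cm² times the normalized alveolar
  density $N_{alv}(z)/N_t$ (per cm).  Its axial integral,
  $A_{c,A}\times 1$ cm ≈ 39 l, acts as the *effective* alveolar reservoir
  and sets the alveolar equilibration time constant
  $\tau = A_{c,A}/D_A \approx 5$ s.  This timescale — slow compared with a
  single breath — is what makes end-tidal CO flow-rate dependent and
  strictly below alveolar CO, as observed.  Rescaling the alveolar area so
  that the grid holds a physical airspace volume of 3,700 ml (available
  via `trumpet_grid(total_capacity_ml = 3700)`) collapses $\tau$ to
  ~0.3 s, pinning end-tidal at the alveolar level for every maneuver; it
  is provided for comparison only.  The physical airway-tree volume (about
  1.9 l, dead space 127 ml) is reported separately by the grid object.

The bundled per-generation alveoli fractions rise monotonically to a
generation-23 fraction of $N_{max}/N_t \approx 0.549$; the exact rescaled
values are not tabulated in the primary sources, so the table ships as an
editable CSV and the simulated end-tidal values are insensitive (<0.5%) to
plausible reshaping of the distribution.

## Parameter estimation

Membrane diffusing capacities follow the morphometric relation
$D = A_M K_{CO}/\Delta x$ with $K_{CO}=2.15\times10^{-5}$
cm² min⁻¹ atm⁻¹, converted to pl s⁻¹ ppb⁻¹ with the derived constant
(1 cm³ min⁻¹ atm⁻¹ → 1/60 pl s⁻¹ ppb⁻¹ in the model's bookkeeping, with
thickness in cm).  The mean capillary CO tension comes from the Haldane
relation
$P_{CO} = \frac{10^9}{760}\,\frac{[COHb]\,P_{O_2}}{[O_2Hb]\,M}$ (ppb), and
the maximum fluxes are $J = f\,D\,P_{CO}$ with $f=1$ for the alveolar
membrane and $f=0.1$ for the airway wall (the bronchial circulation is
roughly a tenth of the pulmonary one).  With the bundled healthy
non-smoker values this chain gives $P_{CO}\approx3.1$ ppm,
$D_A\approx7.8\times10^3$, $J_A\approx2.4\times10^7$,
$D_{aw}\approx1.6$ and $J_{aw}\approx5\times10^2$ — the package's default
parameter set.

```{r estimate}
estimate_exchange()
```

## Numerics

The PDE is discretized by the method of lines on a uniform grid
(`dz = 0.1` cm, 273 nodes) and integrated with backward Euler
(`dt = 0.01` s), which is unconditionally stable and handles the stiff
sink terms implicitly.  Space is discretized in finite-volume form:
storage $A_{tot}(z)\,dz$ per node, first-order upwind advection selecting
the upstream neighbour by the sign of the flow, and conservative-flux
axial diffusion through arithmetically face-averaged airway areas.  Each
step solves one tridiagonal system (Thomas algorithm, strictly diagonally
dominant by construction) in compiled code; a full breath costs a few
milliseconds.

Boundary conditions: during inhalation the mouth node is pinned to the
ambient concentration; during breath-hold and exhalation the mouth is a
no-outer-flux finite-volume row with advective outflow, equivalent to the
zero-gradient condition up to O(dz) (the two differ by 0.2% in end-tidal
CO); the distal end is always closed to diffusion, with upwind advection
handling in/outflow there.  The finite-volume form has column-sum-zero
transport operators, so with sources off and boundaries closed the total
content $\sum A_{tot} C\,dz$ is conserved to solver roundoff — one of the
test-suite invariants.  Tiny negative concentrations (below 10⁻⁹ ppb in
magnitude) are clipped; anything larger raises an error, since the
implicit upwind scheme is positivity-preserving and a real violation
indicates a defect.

Numerical error was quantified rather than assumed: halving `dt` or `dz`
moves simulated end-tidal CO by <0.5%, a 10-node configuration agrees with
a fine-step (10⁻⁵ s) explicit reference integration to <0.5% after 1 s,
and time steps up to 1 s remain stable.  First-order upwinding does smear
the phase I–II front (numerical diffusion ≈ u·dz/2), which mainly affects
the transition region, not the plateau; this mirrors the published
discretization choice.

## Maneuvers, analysis and defaults

A maneuver is inhalation at `ifr` until `v_in` ml, an optional hold, and
exhalation at `efr` until `v_ex` ml, starting from a gas-free tract
(`initial = "zero"`; a steady-cycling mode repeats the breath until the
end-tidal value settles to 0.5%, and measured flow traces can replace the
constant flows).  The expirogram records the mouth node at every
exhalation step.

Analysis conventions, chosen here and recorded in outputs because the
field uses them loosely:

* **End-tidal** = mean over the final 5% of exhaled volume
  (`end_tidal(x, window = 0.05)`); `window = 0` gives the single final
  sample, i.e. the mouth concentration at end of exhalation.
* **Phases**: phase I ends at the model's conducting-airway (dead-space)
  volume, 127 ml; phase II ends where the profile reaches 95% of its
  plateau trend (least-squares line over the final third of volume, which
  also defines the phase III slope).  Boundaries are reported, not used in
  fitting defaults.
* **Elimination rate** = end-tidal × EFR (ppb·ml/s ≡ pl/s).
* **Flow sweeps** default to IFR 127 ml/s, inhaled/exhaled volume 800 ml
  and ambient 125 ppb — the breathing conditions of the subject whose
  measured end-tidal values the sweep is compared against (volumes
  726–770 ml, ambient 119–130 ppb); single cycle from a gas-free start.
  The exhaled volume for this curve is not fixed by the sources, so it is
  a documented, configurable default.

## Fitting

`tmad_fit()` mirrors the staged procedure used with breath-hold data:
stage 1 adjusts $J_{aw}$ (optionally $D_{aw}$, default held at 1.6) to the
first 0.2 s of a breath-hold exhalation — the gas that resided in the
conducting airways — and stage 2 refines $J_A, D_A$ against the phase III
plateau, within ±50% bounds around the initial estimates.  Because axial
diffusion couples the early window to the alveolar level, the two stages
are alternated twice.  A joint bounded least-squares mode
(`method = "joint"`, `least_squares_refine()`) handles any parameter
subset across several maneuvers, with derivative-free Nelder–Mead search,
optional seeded multi-start, and identifiability diagnostics (a flag when
airway parameters are requested without breath-hold data, and the
condition number of the residual Jacobian at the solution).  Residual
weighting is uniform in time over the fit window.

Identifiability, measured on synthetic data with 2 ppb sensor noise:
the three-flow joint fit pins $J_A$ and $D_A$ to well under 2% (median),
while stage 1 recovers $J_{aw}$ to roughly 10% (median) — the early window
holds only one or two sensor samples, so airway parameters are inherently
an order of magnitude less certain than alveolar ones.

## Synthetic data

`synthetic_expirogram()` emulates the real-time laser spectrometer that
motivates the package: sampling every 0.14 s, additive Gaussian noise of
2 ppb (the instrument precision), optional exhalation-flow jitter and
start/end flow ramps, all seeded and reproducible.  What it does *not*
emulate — true intra-breath flow variability, inter-generation anatomical
differences, cardiogenic oscillations, sensor drift — bounds what passing
recovery tests show: they demonstrate that the estimation machinery is
correct and well-conditioned under the model's own assumptions, not that
the model is anatomically exact for any individual.

## Problem sizes used in the test suite

Unit and property tests run on the default 273-node grid with breaths of
6–40 s simulated at `dt = 0.01` s; the flow-rate sweep uses 20 flow values
between 20 and 250 ml/s; parameter-recovery studies use 20 seeds for each
of the stage-1 and three-flow joint experiments.  These sizes keep the
full suite around a minute while leaving every statistical margin
(noise SD bounds, recovery medians) comfortably resolved.

## Known limitations

* Rigid geometry: cross-sections do not change during the breath, and a
  single constant flow is assumed along the trumpet.
* One dimension: no inter-regional ventilation inhomogeneity, no radial
  gradients, no oral/nasal cavity volume.
* CO₂/O₂ dynamics are out of scope; end-tidal CO₂ is pass-through
  metadata.
* The per-generation alveoli fractions are approximations (see above).
* The airway window of a no-hold expirogram identifies airway parameters
  poorly; the package flags this rather than hiding it.
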