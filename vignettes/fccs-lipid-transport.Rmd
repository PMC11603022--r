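---
title: "Modelling dual-color FCCS assays of transporter-mediated lipid exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual-color FCCS assays of transporter-mediated lipid exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccstransport)
```

## The assay this package models

The yeast lipid transfer protein Osh6 shuttles phosphatidylserine (PS)
from the endoplasmic reticulum to the plasma membrane and returns with
phosphatidylinositol 4-phosphate (PI4P); the PI4P gradient pays for the
counter-gradient PS flux. In vitro, the cycle is reconstituted between
two populations of 50-nm large unilamellar vesicles (LUVs): donor LUVs A
carry the cargo lipid and a red lipid tracer (DiD, one dye per 10,000
lipids), acceptor/competitor LUVs B are unlabeled. A fluorescent lipid
biosensor (the C2 domain of lactadherin for PS, SidC for PI4P) binds the
accessible cargo on the donor surface, so donor vesicles are doubly
labeled. Dual-color fluorescence cross-correlation spectroscopy (FCCS)
counts co-diffusing green/red particles; the readout used throughout is
the ratio of the fitted zero-lag amplitudes

$$R = G_{cc}(0) / G_R(0),$$

which, for uniformly labeled vesicles in the dilute limit, equals the
fraction of biosensor bound to the labeled vesicles. As the transporter
extracts cargo, the sensor detaches and $R$ decays; the decay encodes
extraction and, when acceptor vesicles are present, delivery.

Two concentration regimes make the assay interpretable. In the
*extraction* regime the accessible cargo roughly equals the transporter
concentration, so uptake alone empties the sensed pool. In the *release*
regime the cargo saturates the sensor; the initial uptake barely
registers, and the subsequent decay reports delivery to the acceptor
membrane. `scenario_preset()` reproduces the published compositions of
both regimes for both cargoes, completing caption compositions with POPC
and deriving vesicle counts from sphere-shell geometry (0.65 nm² per
lipid, 4-nm bilayer; ~20,600 lipids and ~2.06 DiD per 50-nm vesicle).

## The kinetic model

`build_network()` + `simulate_kinetics()` integrate a closed mass-action
system over the accessible (outer-leaflet) cargo pools of each membrane
and the transporter states $E_{\ell,x}$ with load
$\ell \in \{\varnothing, \mathrm{PS}, \mathrm{PI4P}\}$ and location
$x \in \{\text{solution}, A, B\}$:

* **Adsorption/desorption** — $E_{\ell,\mathrm{sol}} \rightleftharpoons
  E_{\ell,x}$ with rate $k_{on} L_x m_{ads}(x,\ell)$ and $k_{off}$,
  where $L_x$ is the accessible lipid concentration. The defaults put
  the transporter in a weak-binding, fast-exchange regime
  ($k_{on} L \ll k_{off}$): it visits membranes frequently but spends
  most time in solution, which is why adding plain competitor vesicles
  barely changes extraction kinetics, as observed.
* **Extraction** — $E_{\varnothing,x} + c_x \to E_{c,x}$ with flux
  $k_{ext}[c]\, \phi_{c,x}\, [E_{\varnothing,x}]$, where
  $\phi_{c,x} = c_x / L_x$ is the cargo's mole fraction in the
  accessible leaflet. The mole-fraction (surface-density) form is
  essential: an adsorbed protein meets cargo at a rate set by how
  crowded the surface is, not by the bulk concentration, and it is what
  lets a four-fold larger acceptor surface act as a sink.
* **Release** — $E_{c,x} \to E_{\varnothing,x} + c_x$ at
  $k_{rel}[c] \cdot M(x, c)$ with the charge/fluidity multiplier below.
* **Exchange** — at any membrane carrying PI4P,
  $E_{\mathrm{PS},x} + \mathrm{PI4P}_x \rightleftharpoons
  E_{\mathrm{PI4P},x} + \mathrm{PS}_x$, forward coefficient $k_{exch}$
  (per PI4P mole fraction) and reverse $k_{exch}/K_{comp}$. $K_{comp}$
  is the PI4P:PS pocket affinity ratio; it must be large (default 50)
  for a PI4P-blocked transporter to actually stall: at small $K_{comp}$
  the reverse swap at the donor keeps draining PS, which contradicts the
  blocked-transport phenotype.

Each cargo headgroup and the total transporter are conserved exactly in
the reaction scheme; `deSolve::lsoda` at `rtol = atol = 1e-10` keeps the
numerical drift below $10^{-8}$ relative over 20 simulated minutes
(`conservation_error()` checks this on every trajectory). A Gillespie
realization of the identical reaction table (`simulate_gillespie()`)
serves as a small-copy-number cross-check of the ODE mean in the tests;
the deterministic path is the production engine because the assay
observables are ensemble fractions.

### Charge and fluidity modulation

`charge_fluidity_multiplier()` encodes the membrane dependence of the
cycle. With charge density $Q = \sum_i |z_i| x_i$ (headgroup valence
times mol fraction; PS/PG/PA/PI count $-1$, PIP2 $-4$) and a fluidity
score $F$ from an ordinal tail-class map (di-unsaturated/DAG 1.5,
palmitoyl-oleoyl 1.0, cholesterol 0.3; pure POPC scores 1):

* PS-loaded release: $M = (1 + 8Q) \cdot F$ — charged *and* fluid
  acceptors unload PS faster;
* PI4P-loaded release: $M = F$ — the tightened lid ignores non-cargo
  charge; only fluidity (and exchange against membrane PS) helps;
* empty-transporter adsorption: $1 + 10Q + 6P$ with $P$ the mol
  fraction of diphytanoyl (packing-defect) lipids, which expose charge;
* loaded-transporter adsorption: damped (0.5 for PS, 0.25 for PI4P) and
  charge-blind, matching the reduced adhesion of the loaded protein;
* PS (re-)extraction from a charged membrane is damped by
  $1/(1 + 6Q)$: charged lipids stabilise PS in the bilayer and inhibit
  its non-productive re-export. This extraction-side term is a model
  extension beyond the release/adsorption multipliers; without it the
  thermodynamic preference of PS for charged membranes has no kinetic
  counterpart.

The linear charge dependence is the simplest form consistent with the
orderings the data establish; only orderings, not functional forms, are
constrained.

### Biosensor

`bound_sensor_fraction()` solves the 1:1 equilibrium
$S + L \rightleftharpoons SL$ exactly (quadratic root), so sensor
depletion is handled; one sensor occupies one accessible cargo lipid.
The affinities are calibration choices (no measured values exist):
$K_d = 50$ nM for the PS reader at 50 nM, $K_d = 40$ nM for the PI4P
reader at 100 nM. They place 3-4 mol% cargo at 50 µM lipid on the
saturated plateau (within ~5% of the asymptote, local slope below 10% of
the maximum) while 1 mol% still responds — the split that creates the
two assay regimes. One caveat is worth stating plainly: for *any* 1:1
isotherm, a composition only 3-4 times the extraction composition
cannot be fully saturated while the extraction composition sits on the
steepest part of the curve (a hyperbola needs an ~81-fold span to go
from 10% to 90%). The extraction regime works not because its
composition is on the steepest point but because extraction sweeps the
pool *through* the steep region down to zero; the tests check the
plateau side quantitatively and the steepness side as an ordering.

By default the sensor-bound share of the pool is *not* withheld from the
transporter (`sensor_shielding = FALSE`): extraction removes the lipid
and the sensor re-equilibrates by mass action. The alternative
(shielding on) makes complete extraction of a stoichiometric pool far
slower than the ~10 minutes the PI4P assay shows, because the protected
tail never empties. The control experiment with non-extractable
diphytanoyl-PS is honored either way: a species that cannot be extracted
produces no readout change, so sensor displacement alone is silent.

### Calibrated defaults

Three printed kinetic anchors pin the default rate constants
(`scripts/calibrate-defaults.R` reproduces the procedure):

1. PS extraction is stoichiometric and complete within the first minute
   (bound fraction 0.93 at 1 min at the extraction preset; readout falls
   to ~0.1 of baseline);
2. emptying the accessible PI4P pool takes about ten minutes — the
   readout completes 90% of its asymptotic drop at 9 min
   (`pi4p_extraction_time90()`);
3. competition equivalence: 1 mol% PI4P in competitor vesicles
   suppresses the initial PS extraction rate by the same factor (~0.47)
   as 20 mol% PS suppresses the initial PI4P extraction rate
   (`competition_equivalence()`); $k_{exch}$ is bisected so the integer
   scan matches at exactly 20 mol%.

These are calibration constraints, not predictions: the package's
defaults are *defined* to reproduce them, and the corresponding tests
verify that the shipped numbers still do. Everything downstream of the
anchors — the orderings across acceptor compositions, the
competition-scan shape, the preincubation behavior — is a genuine model
output.

## The synthetic microscope

`ensemble_from_state()` realizes a kinetic state as discrete particles:
donor LUVs (Poisson-distributed DiD copies, mean 2.06), bound sensors
distributed multinomially over vesicles, free sensors, and — when cargo
has been delivered — green-only acceptor vesicles.
`simulate_photon_trace()` then runs Brownian dynamics through a 3D
Gaussian observation volume: steps of variance $2D\Delta t$ per axis
with periodic wrapping in a cubic box, expected counts per bin
$\sum_i q_i \exp(-2(x_i^2+y_i^2)/w_0^2 - 2z_i^2/(\kappa w_0)^2)\,
\Delta t$, Poisson-realized, bit-reproducible per seed (a dedicated
xoshiro generator, independent of R's RNG state). Defaults: $w_0$ =
0.25 µm, $\kappa$ = 5, 10-µs bins, 3-µm box, Stokes–Einstein diffusion
(9.8 µm²/s for a 25-nm-radius vesicle, 80 µm²/s for the free sensor).
All optics values are synthetic: the published experiments report the
hardware, not the calibrated volume. Channels are perfectly separated
(pulsed interleaved excitation is idealized as zero bleed-through);
triplet kinetics, afterpulsing and detector dead time are not modeled.

What the generator deliberately emulates — and what it does not — bounds
what passing tests mean for real data: it reproduces the *statistical
structure* the analysis assumes (diffusive number fluctuations, Poisson
shot noise, Poisson dye loading, co-diffusion of bound sensors), not
instrument artifacts. A pipeline validated here can still be misled by
bleed-through, photobleaching or aggregation in a real measurement.

## Correlation analysis

`correlate_direct()` evaluates the auto- and cross-correlation
functions $G(\tau) = \langle\delta I_a(t)\,\delta I_b(t+\tau)\rangle /
(\langle I_a\rangle\langle I_b\rangle)$ literally at chosen lags
(means taken over the overlapping windows); it is the oracle.
`correlate_multitau()` is the production estimator: 16 lags per cascade,
pairwise averaging between cascades, symmetric normalization. The two
agree exactly on the base cascade (they are the same estimator there)
and within 5% over the resolved part of the decay; at lags where the
correlogram falls below its own sampling noise no estimator comparison
is informative, and the deepest cascades low-pass any feature faster
than the cascade bin — both behaviors are characterized in the tests.
Splitting the trace into segments gives per-lag standard errors that the
fits use as weights.

`fit_diffusion()` fits $G(\tau) = G_0\,(1+\tau/\tau_D)^{-1}
(1+\tau/(\kappa^2\tau_D))^{-1/2}$ (one component for the red and
cross-correlation channels; two components for the green channel, whose
fast term is the free sensor) by weighted least squares. $G_0$ is
always the fitted extrapolation, never the shot-noise-dominated first
lag point. `readout_ratio()` forms $R$; the forward and reverse
cross-correlations estimate the same quantity and are averaged to halve
the estimator variance.

Two amplitude subtleties are handled explicitly rather than hidden:

* **Dye-number dispersion.** With Poisson-distributed DiD copies (mean
  $\mu$), brightness weighting inflates $G_R(0)$ by $1 + 1/\mu$, so the
  raw ratio reads $f_{bound}\,\mu/(1+\mu)$, about 0.67 $f_{bound}$ at
  $\mu = 2.06$. The optical pipeline multiplies by the analytic
  $(1+1/\mu)$ so the readout matches the ideal bound fraction. The rate
  estimators use only ratios of readouts, so they are invariant to this
  correction — which is precisely why the amplitude *ratio* is a robust
  assay readout in the first place.
* **Small-amplitude rectification.** Near $R \approx 0$ the
  nonnegative amplitude fit cannot fluctuate downward, so very low bound
  fractions carry a small positive bias (~0.04 at $R = 0.15$ with 20-s
  traces). The ideal-vs-optical agreement is therefore checked at
  saturated and mid-range states; rate estimates in the release regime
  operate at $R \gtrsim 0.8$ where the bias is negligible.

Multiple sensors per vesicle do *not* bias the ratio (the
cross-amplitude is linear in the green brightness per particle), which
the readout-meaning test exercises with exact constructed ensembles.

## The two analysis paths, and problem sizes

`run_assay()` runs scenario → kinetics → readout → rates either on the
*ideal* path (isotherm only; deterministic; optional multiplicative
measurement noise for replicate studies) or the *optical* path (each
time point spawns ensemble → trace → correlation → ratio). Optical
replicates are new seeds at fixed kinetics, matching repeated FCCS
measurements on one vesicle stock; `compare_conditions()` applies the
published replicate pipeline — single-pass exclusion of points deviating
more than 1.5 SD from the mean, then a pooled-variance two-sample
t-test.

The package's own test suite chooses desk-scale problem sizes: 60-s
traces at 20-µs bins for amplitude checks, 40-s traces for the
readout-meaning check, and 8-20-s traces at 50-100-µs bins with a
20-fold sensor-pool dilution (the readout is dilution-invariant, and
the vesicle pool can be diluted independently) for the ten-replicate
ordering studies. The published measurements are 200 s; longer traces
only tighten every comparison.

## Known limitations

* Rate constants are calibrated to three anchors, not fitted to data;
  absolute rates are therefore in model units, and only orderings and
  the anchored quantities should be compared across studies.
* The charge/fluidity response is linear in charge density; saturation
  at high charge is not modeled.
* No spatial encounter physics, no membrane tethering, no phosphatase
  step, no transbilayer flip; acceleration of PI4P extraction by
  non-ligand charged donor lipids is not modeled (only the PS-side
  damping is).
* The extraction regime's second-order endgame (transporter and cargo
  both depleted) makes the final approach to the floor slower than
  exponential; the 90%-drop time is the robust summary.
* The synthesizer omits triplet dynamics, bleed-through and detector
  artifacts; see above for what that implies about real data.
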