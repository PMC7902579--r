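---
title: "Methods: environmental dose rate coefficients for the pregnant female and fetus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental dose rate coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envdose)
```

## The problem

After an atmospheric release of radioactivity, the dominant long-term
exposure pathway for the public is external irradiation by photons from
radionuclides deposited on the ground or suspended in air.  Dose assessment
for these situations works with *dose rate coefficients*: organ equivalent
dose rates per unit environmental activity concentration.  This package
computes such coefficients for the fetus (24th week of gestation) and
supports the normalisation, weighting and surrogate-ratio reports used with
them.

Two idealised exposure scenarios are covered:

* **Ground contamination** — an infinite plane source buried at an
  areal-mass depth of 0.5 g cm⁻² in soil (representative of surface
  roughness during the first year after deposition).  Coefficients are in
  Sv s⁻¹ per Bq m⁻².
* **Air submersion** — a semi-infinite, uniformly contaminated air volume
  (radioactive cloud).  Coefficients are in Sv s⁻¹ per Bq m⁻³.

## Monoenergetic tables and interpolation

Monoenergetic fetal organ coefficients (10 organs, 0.015–10 MeV) and
air-kerma rate coefficients at 1 m height, for both geometries, are packaged
exactly as published, to 3 significant figures, with no rescaling.  The
submersion grids have gaps (no 0.4, 0.6, 0.8 MeV rows) which the data layer
preserves; interpolation spans them.  The packaged ground air-kerma table
carries 25 nodes; its 0.7 MeV row is absent from the source digitisation, so
that energy is likewise obtained by interpolation.

Nuclide folding needs coefficients at arbitrary energies, obtained by a
*monotone piecewise cubic Hermite* interpolant (Fritsch–Carlson family) in
log-linear space: abscissa $\log_{10} E$, ordinate the coefficient on a
linear scale.  Node slopes use the interval-width weighted harmonic mean of
adjacent secants, zeroed at local extrema, which guarantees a
shape-preserving interpolant: it reproduces every node exactly, never
overshoots the bracketing node values, and stays non-negative.  The phrase
"log-linear" admits a second reading (linear energy, log value);
`dose_curve(..., log_value = TRUE)` exposes that convention for comparison,
with the log-abscissa/linear-ordinate form as the default, which is the
standard reading for dosimetric tabulations.  Below 0.015 MeV — the lower
end of the transport calculations behind the tables — coefficients are
defined as exactly zero.  Above 10 MeV, or beyond the last node of a user
table, evaluation is an error: no extrapolation, no invented data.

## Folding with radionuclide emissions

For a nuclide, exposure mode $S$ and tissue $T$, the coefficient is

$$\dot h_T^S \;=\; \sum_R w_R \Big[ \sum_i Y_{R,i}\,\dot d_{T,R}^S(E_i)
  \;+\; \int_0^\infty Y_R(E)\, \dot d_{T,R}^S(E)\, dE \Big],$$

summing radiation types $R$ (photons, electrons; $w_R = 1$ for both),
discrete lines $i$ with yields $Y_{R,i}$ per decay, and continuous spectra
with densities $Y_R(E)$ in MeV⁻¹ per decay.  Decay records are read from a
documented JSON schema carrying this content; a converter from any decay
database is the user's concern, and a seeded synthetic-nuclide generator
(`synth_nuclide()`) supplies test records with log-uniform line energies and
allowed-shape beta spectra.

* **Discrete photons** evaluate the curve at each line energy; lines below
  0.015 MeV contribute exactly zero.
* **Continuous photon spectra** (e.g. spontaneous-fission photons) are
  integrated by a composite trapezoid on the union of the spectrum grid, the
  curve nodes and a refinement to at least 2000 panels by default.  The scheme is
  deliberately simple and oracle-checkable; against 10⁵-panel references it
  agrees to better than 10⁻⁶ relative for smooth spectra.
* **Electrons** (discrete lines and beta continua) cannot themselves reach a
  person standing in the field: they stop within centimetres in air or
  millimetres in soil.  Their only penetrating pathway is the thick-target
  bremsstrahlung generated as they stop.  Both electron routes therefore go
  through a *bremsstrahlung kernel* $B(k \mid E_e)$, photons MeV⁻¹ per
  stopping electron: $d_{\mathrm{elec}}(E_e) = \int B(k \mid E_e)\,
  d_{\mathrm{photon}}(k)\,dk$, interpolated linearly between kernel electron
  energies.  The default kernel is a Kramers-like $1/k$ spectrum truncated
  at $E_e$ and at 2 keV, scaled so the radiated energy equals
  $Y_{\mathrm{rad}}(E_e)\cdot E_e$ with a synthetic radiative yield
  $Y_{\mathrm{rad}} = \min(1,\,3\times10^{-4}\,\bar Z\,E)$ — about 0.2% for
  a 1 MeV electron in air, the magnitude quoted for that medium.  Kernels
  tabulated from measured thick-target spectra can be loaded from CSV and
  configured per geometry (whether the soil or air medium should host the
  kernel is not prescribed; it is a configuration input).
* **Progeny are never summed implicitly.**  Coefficients apply to the
  indicated nuclide alone; `cmd_fold(sum_as=, branching=)` provides explicit
  documented arithmetic for composites such as a parent plus a short-lived
  daughter.

Results carry a per-organ component breakdown (discrete photon /
bremsstrahlung / continuous photon) whose sum is the total to within
rounding.  `kerma_normalize()` divides by a nuclide's air-kerma rate
coefficient to give Sv/Gy values usable with measured air-kerma rates, and
`detriment_weighted()` forms the tissue-weighted scalar
$\sum_T w_T \dot h_T$ (the standard 2007 weight set is provided).

The packaged per-nuclide summary (135 radionuclides: air kerma,
detriment-weighted dose, uterus of the pregnant phantom, fetal total body;
both geometries) feeds the uterus-as-fetus-surrogate report: ratios are
printed to 2 decimals with the raw value retained.  From these data the
Xe-133 ground ratio is 1.09 and the iodine/caesium/barium group lies at
1.04–1.06.  One caveat the tests document: from the printed 3-significant-
figure values the Cs-137 ratio rounds to 1.08, while full-precision values
round to 1.09; the package reports what the packaged data give.

## The simplified environmental Monte Carlo

The published monoenergetic tables were produced with production transport
codes and a voxel phantom; reproducing them is out of scope.  What the
package does provide is a desk-scale analog photon Monte Carlo of the
environmental field itself, for constructing coupling-cylinder phase-space
distributions and an air-kerma estimate:

* **World**: a right circular cylinder, default 500 m radius (about five
  mean free paths of 0.6 MeV photons in air), 500 m of air (1.2×10⁻³ g cm⁻³)
  over 1 m of soil (1.0 g cm⁻³), with the published elemental compositions.
* **Physics**: photons only, 2 keV cutoff.  Free-electron Klein–Nishina
  Compton sampling (rejection method, verified against the analytic angular
  distribution), photoelectric absorption, pair production absorbing the
  photon and emitting two 0.511 MeV annihilation photons back-to-back in a
  random direction.  No coherent scattering, no electron transport, and no
  environmental bremsstrahlung generation — the known fidelity gaps relative
  to the production codes (which used a thick-target bremsstrahlung
  approximation in-field).  Energy never increases along a track.
* **Cross sections**: no data library is bundled; synthetic tables are
  generated from closed forms — Klein–Nishina incoherent scattering, a
  calibrated $Z^{4.5}/E^3$ photoelectric law and a calibrated $Z^2$ pair
  term — and are labelled synthetic throughout.  They are within a few
  percent of reference values in the Compton-dominated regime
  (0.06–2 MeV) that controls the fields simulated here, and user tables
  (e.g. from a cross-section library) can be supplied as CSV.
* **Coupling cylinder**: an ideal absorber (2 m diameter × 2.5 m for ground,
  0.6 m × 2 m for submersion) standing on the interface.  Every photon
  entering is terminated and recorded.  Crossings are binned into
  $p_S(\cos\vartheta, h, E)$ on the side and $p_L(\cos\vartheta, E)$ on the
  lids: 0.1-wide $\cos\vartheta$ bins on $[-1,1]$, 10 cm height bins, and a
  per-decade energy grid with mantissas 1.0, 1.5, 2, …, 9.  $\cos\vartheta$
  is measured against the upward vertical; bins are half-open $[a,b)$ with
  the final bin closed; side and lid probabilities jointly sum to 1, and
  per-bin binomial standard errors are stored.  Because the field is
  rotationally invariant, position azimuth, lid radius and direction azimuth
  are not binned; `sample_phase_space()` restores them uniformly (area-
  uniform radius on lids), placing lid samples on the top lid for downward
  directions.
* **Air-kerma tally**: the published calculation scored fluence in a 30 cm
  sphere at 1 m height.  An analog estimator of that sphere would almost
  never be hit from a 500 m source plane, so the package exploits the
  lateral uniformity of the infinite-plane field: a track-length estimator
  in a thin horizontal disc slab (default 50 m radius × 0.2 m, centred at
  1 m) measures the same point fluence with usable variance.  The
  fluence-spectrum-to-kerma conversion itself,
  $\dot K = \sum \Phi(E)\,E\,(\mu_{tr}/\rho)(E)$, is a separate function
  testable against the closed form, with a synthetic air
  $\mu_{tr}/\rho$ table (Klein–Nishina energy transfer + photoelectric +
  pair kinetic fraction) replaceable by a measured conversion table.

With the default synthetic physics, a 10⁵-history run of the 1 MeV
ground-plane source reproduces the published air-kerma rate coefficient
(8.26×10⁻¹⁶ Gy s⁻¹ Bq⁻¹ m²) to within a few percent — comfortably inside
the ~25% envelope one should allow the simplified physics — and this value
is reported by `scripts/acceptance.R` as a diagnostic rather than asserted.

## Numerical and design choices

* Quadrature: composite trapezoid on union grids (union grids refined to ≥ 2000 panels by default, above the 400-panel floor); the source
  publication does not name its integration scheme, and trapezoid is simple
  and independently checkable.
* Rounding in reports: coefficients to 3 significant figures, ratios to two
  decimals, matching the published tables; raw values are always retained.
* Degenerate inputs: empty emission lists fold to zero; zero-density
  spectra fold to zero; a zero fetal coefficient flags the surrogate ratio
  as undefined rather than dividing.
* Problem sizes in the test suite: stochastic checks run at 10⁴–10⁵
  histories/samples with fixed seeds, the scales at which the binomial and
  χ² criteria they assert are sharp; the acceptance script uses 10⁵
  histories for the kerma diagnostic (batch standard error ≈ 6%).
* The seeded generator's defaults (line energies 0.02–3 MeV log-uniform,
  beta endpoints 0.1–2 MeV, allowed-shape spectra) emulate the emission
  ranges of common fission and activation products.  What it does not
  emulate: internal conversion/Auger cascades, forbidden beta shapes, and
  correlated line intensities — so passing property tests demonstrate the
  folding arithmetic, not decay-data realism.

## Known limitations

* Organ coefficients come from the packaged tables; the package cannot
  produce coefficients for organs or phantoms not tabulated (the mother's
  full organ set lives in the source's electronic supplement, not in the
  print tables packaged here).
* The simplified MC is a verification and phase-space tool, not a
  replacement for production transport: its absolute accuracy is limited by
  the synthetic cross sections and missing processes listed above.
* Two cells of the packaged submersion air-kerma table (6 and 10 MeV) are
  flagged in the data documentation as inconsistent with the physical trend
  of the surrounding rows; they are packaged as printed in the source
  digitisation.  They do not affect any other table.
* No decay-chain ingrowth, no time-integrated doses, no
  weathering/migration, and no location/occupancy shielding factors — these
  belong to assessment layers above per-nuclide rate coefficients.
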