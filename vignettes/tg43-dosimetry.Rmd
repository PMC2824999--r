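---
title: "Monte Carlo TG-43 dosimetry of an encapsulated HDR Co-60 source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo TG-43 dosimetry of an encapsulated HDR Co-60 source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cobrachy` simulates photon transport around the new-design BEBIG
high-dose-rate ⁶⁰Co brachytherapy source and reduces the resulting kerma
fields to the AAPM TG-43 quantities that treatment-planning systems
consume: air-kerma strength $S_K$, the dose-rate constant $\Lambda$, the
radial dose function $g_L(r)$ with its cubic parameterization, Cartesian
away/along dose-rate tables, and water-equivalence comparisons between
solid phantom materials and liquid water.  This vignette records the
model, its assumptions, and the numerical choices, so that every default
in the package is explained somewhere a maintainer can find it.

## The source and phantom model

The source is a metallic cobalt cylinder (active length 3.5 mm, diameter
0.5 mm) surrounded by a 0.1 mm air gap and a 0.15 mm AISI 316L steel
capsule; a 2 mm steel cable attaches at negative $z$.  The capsule is
modelled as a right circular cylinder with flat ends of outer radius
0.50 mm extending 0.15 mm beyond the air gap at both ends.  The true
capsule tips are rounded; a flat-end capsule is the simplest shape
consistent with the published wall thicknesses, and the difference only
affects points close to the long axis, which the reported lattice never
approaches within the capsule's angular shadow at short range.  The cable
is taken as solid 316L at 7.8 g/cm³ (its weave is not specified anywhere;
a solid cylinder bounds its attenuation).

Three phantoms surround the source, all centred on it:

* a 100 cm diameter × 100 cm height cylinder of the dose medium (water,
  Solid Water, RW1, PMMA or polystyrene), which provides full scatter up
  to 20 cm from the source;
* a 5 m diameter sphere of air (or vacuum) for air-kerma strength;
* a 100 cm radius sphere for fluence spectra.

Elemental compositions and densities of every medium are in
`material_library()`.  Air is dry air at 1.2×10⁻³ g/cm³; the humidity of
real calibration air changes its interaction coefficients at ⁶⁰Co
energies by far less than the statistical resolution of any run, so no
humid-air composition is carried.

## Photon physics

Each disintegration emits the 1.17 and 1.33 MeV gamma lines (2 photons
per decay).  Histories start one photon each, with the line chosen with
equal probability, uniformly over the active core and isotropically in
direction; all per-decay quantities are scaled by 2 at finalization.
Line correlations within a decay are irrelevant to mean kerma, which is
all the TG-43 quantities use.

Transport is analog: exponential free paths in the current region,
interaction channels chosen in proportion to the per-process attenuation
coefficients.  Compton scattering uses the Klein–Nishina distribution on
free stationary electrons, sampled by the standard two-branch
composition–rejection method; at 1.17–1.33 MeV in low-Z media the
binding/Doppler corrections this neglects are far below the few-percent
tolerances of the reported quantities, and this bias is accepted and
documented rather than half-corrected.  Pair production (enabled by
default, relevant only just above the 1.022 MeV threshold where it is a
$\sim10^{-5}$ fraction of interactions) replaces the photon with two
back-to-back 511 keV annihilation photons at the collision site,
consistent with not transporting charged particles.  Coherent (Rayleigh)
scattering is disabled by default: it deflects photons through small
angles without energy transfer, so leaving it out of the total
attenuation is the standard and nearly exact approximation for kerma
transport at these energies.  It can be switched on, in which case a
Thomson-like angular law is used.  Fluorescence after photoelectric
absorption is omitted because every constituent K edge lies below the
transport cutoff.

Photons are terminated below 10 keV without local deposition.  Secondary
electrons are never transported: the scored quantity is collision kerma,
which equals absorbed dose wherever charged-particle equilibrium holds —
everywhere in the reported tables except within about 1 cm of the source,
where the printed values should be read as kerma.

## Interaction coefficient data

The package ships per-element tables (energy grid 10 keV–1.4 MeV, ~80
log-spaced points) of photoelectric, incoherent, coherent and
pair-production mass attenuation coefficients, plus mass
energy-absorption coefficients $\mu_{en}/\rho$ for air and water on the
Hubbell & Seltzer (1995) reference grid.  The incoherent column is the
exact Klein–Nishina cross section times $Z N_A / A$, matching the
free-electron scattering model used in transport.  The photoelectric and
coherent columns are derived from the water and air reference tables:
below 80 keV the photoelectric component of water is extracted by
subtracting the Klein–Nishina energy-transfer part from
$\mu_{en}/\rho$, then distributed over elements with a $Z^{4.5}$
per-atom power law; the coherent column is the residual that makes the
water total attenuation reproduce the reference table exactly on its
grid.  Pair production uses a near-threshold $Z^2$ form.  Consequences
worth knowing:

* water (the medium that matters for every acceptance-grade quantity)
  reproduces the reference $\mu/\rho$ to better than 0.01 % across the
  grid, by construction;
* reconstructed dry air agrees with its reference table to 0.5 % above
  40 keV, degrading to ~5 % at 10 keV (the $Z^{4.5}$ law is imperfect
  for argon); air attenuation over the detector distances is below 1 %
  in total, so this is negligible;
* high-Z capsule elements are Compton-dominated at the source energies
  (photoelectric is ≲10⁻⁴ of their attenuation at 1.25 MeV), so the
  approximate photoelectric scaling does not measurably move capsule
  attenuation;
* because the residual "coherent" column also absorbs the difference
  between free-electron and bound incoherent scattering at low energy,
  transport with coherent disabled slightly underestimates total
  attenuation below ~30 keV.  Photons there carry a tiny share of the
  kerma at the tabulated distances.

All tables are versioned plain-text files under `inst/extdata/xs/` with
provenance headers, generated once by `tools/make_coefficients.R`;
nothing is downloaded at run time.

## Tallies

Collision kerma and fluence are scored with track-length estimators in
ring cells: revolutions about the source axis of 0.5 mm × 0.5 mm
rectangles in the $(y,z)$ plane, centred at every coordinate of the
published away/along lattice plus the 32 transverse radii of the radial
dose function grid (`standard_tally_cells()`).  Scoring only those cells,
rather than a dense half-plane mesh, keeps memory and variance where the
reported numbers are.  On-axis ($y=0$) positions use solid disk cells of
0.5 mm radius because a zero-radius ring has no volume; the three on-axis
positions blocked by the capsule and cable are omitted, as in the
published tables.  Kerma is converted from fluence segment by segment at
the photon's exact energy using water $\mu_{en}/\rho$ (kerma to water in
every phantom medium), so no spectrum-binning bias enters the dose
tables; the 20 keV spectrum bins (2 keV at the gamma lines) exist only
for spectrum output.  Uncertainties are history-by-history 1σ estimates:
per-cell sums and sums of squares of per-history scores.

Air-kerma strength uses next-event (point-detector) estimators at
$y = 25, 50, 75, 100$ cm on the transverse axis: every emission and
Compton vertex contributes its emission probability per steradian toward
the detector, attenuated along the connecting ray, at the energy the
photon would carry there.  $S_K/A$ is the intercept of the ordinary
least-squares line $\dot k_{air}(y)\,y^2 = S_K/A + b\,y$, with $b$
absorbing the build-up of air-scattered photons.

## TG-43 reduction

The dose-rate constant is the per-activity kerma rate in the ring cell
centred at $(y=1\ \mathrm{cm}, z=0)$ divided by $S_K/A$ — the cell value
is used directly, with no interpolation, matching cell-based scoring.
$g_L(r)$ uses the line-source geometry function
$G_L = \beta/(L r \sin\theta)$ with $L = 0.35$ cm, normalized to 1 at
$r_0 = 1$ cm exactly.  The cubic fit of $g_L(r)$ is unweighted ordinary
least squares over the 32 radii; inverse-variance weighting is deliberately
not applied because the published fit is stated without weights and the
per-point uncertainties vary little along the transverse axis.  Ratio
uncertainties combine first order in quadrature, adequate below the ~2 %
relative 1σ of any reported cell.  Phantom comparisons report
$100\,(\text{solid}-\text{water})/\text{water}$ per lattice point with a
2σ significance flag.

## Synthetic fixtures

`fixture_field_archive()` writes archives whose kerma field is a closed
form — inverse square, pure line-geometry, or line-geometry ×
exponential attenuation × polynomial build-up — times multiplicative
lognormal noise with chosen relative σ (the estimator's positive,
relative-error character mirrors the 0.04–2 % range of real tallies).
These fixtures exercise the whole analysis chain with known answers: a
geometry-only field must return $g_L \equiv 1$ to machine precision, the
attenuated field has an analytic $g_L$, and replicated noisy fixtures
calibrate the propagated uncertainties.  What they cannot show is the
correctness of the transport physics itself, which is why the test suite
also carries slab-transmission, Klein–Nishina-vs-quadrature,
uniform-flux-unbiasedness and detector-vs-ring cross-checks.

## Problem sizes and numerical choices

Default run sizes were chosen so the statistical resolution sits
comfortably inside the few-percent agreement expected of the published
quantities: the acceptance script uses 6×10⁶ histories for water,
4×10⁶ for PMMA and 1.5×10⁶ for the air sphere (the test suite uses
4×10⁶ / 2.5×10⁶ / 10⁶), giving ~0.4 % relative 1σ at the reference cell,
~1.2 % at $g_L(20)$ in water and ~0.05 % on $S_K/A$.  The published
tables themselves used up to 5×10⁷ histories; nothing but statistical
noise changes with more histories.

Other numerics: cross sections are interpolated log-log (photon cross
sections are near power laws between the tabulated energies, and no
absorption edge lies inside the transport range); the transport core
resamples free paths at region boundaries (valid by memorylessness);
points within 10⁻⁹ cm of a surface belong to the region ahead of the
ray, which prevents grazing-ray loops; ring-cell traversal collects all
radial and axial boundary crossings of a flight segment and classifies
sub-segment midpoints, which is robust to tangential geometry.  All
randomness flows through R's RNG, so `set.seed()` (or a `seed` in the
run configuration) makes any run bit-reproducible.

## Known limitations

* No secondary-electron transport: within ~1 cm of the capsule the
  tables are collision kerma, not dose.
* Free-electron Compton and the derived photoelectric/coherent columns
  bias the low-energy scattered tail slightly; the effect is within the
  few-percent tolerances at up to 20 cm but would matter for a
  spectroscopy-grade application.
* The 2D anisotropy function $F(r,\theta)$ is not computed; the package
  reports transverse-axis and Cartesian-table quantities only.
* Printed effective atomic numbers for the solid phantoms follow the
  Mayneord $p = 2.94$ convention; other conventions give different
  values, so `effective_atomic_number()` exposes the exponent rather
  than pretending there is one canonical $Z_{eff}$.
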