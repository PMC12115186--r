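---
title: "Membrane structure, permeability and DSC analysis with bilayr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane structure, permeability and DSC analysis with bilayr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bilayr` analyses two kinds of data that membrane-biophysics studies of
small amphipathic drugs produce: molecular configurations of a lipid
bilayer (with optional probe particles), and differential scanning
calorimetry (DSC) melting scans. This vignette records the models behind
each estimator, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where conventions were genuinely open.

## Units

One unit system at every in-memory interface: lengths in Å, times in ps,
energies in kcal/mol, temperatures in °C (Kelvin appears only inside the
van't Hoff formulas), diffusivities in cm²/s at the user surface. File
formats convert at the boundary only (GRO stores nm; 1 Å²/ps = 10⁻⁴ cm²/s).

## Structural observables

**Leaflet assignment.** A lipid is `upper` iff its head-reference atom lies
above the midplane, defined per frame as the mean head-reference z. A head
exactly on the midplane goes to the *lower* leaflet, with a warning — an
arbitrary but deterministic tie rule, preferred over any data-dependent
one. Assignments can be re-checked per frame (`check_flips = TRUE`), which
warns when lipids cross between frames.

**Density profiles.** Atom masses are binned along z after re-centring
each frame on its midplane, so slow box drift cannot smear the profiles,
then divided by the bin volume `Lx·Ly·bin_width` and averaged over frames.
The default bin width is 0.5 Å — fine enough to resolve thickness changes
of ~1.4 Å, coarse enough that typical profiles remain smooth. The profile
integral times the lateral area returns the selected mass exactly; the
test suite asserts this conservation on every builder output.

**Area per lipid** uses the projected-area convention `2·Lx·Ly/N`: correct
for ensemble means, oracle-checkable against the builder, and the quantity
a barostat actually controls. Voronoi per-lipid areas are out of scope.
With asymmetric leaflet populations the per-leaflet form `Lx·Ly/N_leaflet`
is reported for both leaflets instead.

**Thickness** is the z distance between the mean positions of the two
leaflets' phosphate atoms (head-reference beads when no phosphate role
exists). It is translation invariant and recovers the builder's head-plane
separation exactly at zero jitter.

**Interdigitation** is quantified as a fraction of mass overlap between
the leaflet-resolved tail densities,

\[
f_{ov} = \frac{\int \min(\rho_U, \rho_L)\,dz}
              {\tfrac12 \int (\rho_U + \rho_L)\,dz} \in [0, 1],
\]

evaluated by the trapezoidal rule on the shared grid. Absolute `f_ov`
values are convention-dependent (overlap metrics differ between analysis
packages); what carries between studies is the treated/control ratio
`D_int`, in which the convention cancels to first order. The package
therefore exposes both, refuses to form the ratio when the control overlap
is zero (returning an error from `interdigitation_ratio()` and `NA` from
the delta-table path), and the tests pin down the *monotone* response of
`f_ov` to the builder's interdigitation offset rather than its absolute
value.

**Order parameters.** `S_CD(k) = ⟨(3cos²θ − 1)/2⟩` over frames, lipids and
each carbon's hydrogens, with θ between the C→H vector and +z; reported as
`|S_CD|` per chain (sn-1, sn-2). The closed forms anchor the tests:
perpendicular C–H bonds give 0.5, bonds at the magic angle (54.7356°) give
0, isotropic orientations average to 0.

**Hydrogen bonds** use the de facto geometric criterion — donor–acceptor
distance ≤ 3.5 Å and H–D–A angle ≤ 30°, minimum-image in xy — both cutoffs
exposed as arguments. Hydrogens attach to donors by proximity in the first
frame (nearest donor heavy atom within 1.3 Å), or by an explicit
donor–hydrogen table.

**Averaging window.** All summary statistics discard the first 20% of
frames by default, mirroring the common practice of dropping the
equilibration fifth of a production run, and are reported as mean ± SD over
the retained frames. Block averaging is deliberately not applied: the SD
is the plain frame-to-frame value.

## Probe transport

**Region classification.** The hydrophobic core is the contiguous z
interval around the midplane where the tail density exceeds the head
density; its boundaries come from the two crossovers, linearly
interpolated between bins. Classification uses the discard-window-averaged
profile once, not per frame — per-frame boundaries would inject profile
noise into the occupancy counts. Bins where both densities are zero (as
happens between discrete atom planes at low thermal jitter) do not break
the core's contiguity.

**Partition coefficient** `K_p` is the time-summed count of probe
positions inside the core divided by the count outside, over all retained
frames and particles — frame-instantaneous counts, no residence-time
smoothing. The same 20% discard window applies by default, matching the
global averaging convention.

**MSD and diffusion.** The mean squared displacement is averaged over all
particles and all time-origin pairs per lag, up to half the trajectory
length, separately for z, xy and 3-D. xy positions are unwrapped by
accumulating minimum-image inter-frame displacements; z is treated as
bounded (a membrane-spanning box has no z-periodic diffusion to unwrap).
Diffusion coefficients come from ordinary least squares on a lag window:
`D = slope/(2d)` with d the dimensionality. The default window is the
2–10 ns span when the trajectory reaches 10 ns; otherwise the longest
window achieving r² ≥ 0.99 is auto-selected (flagged when that rejects the
full range), falling back to the first half of the lags with a
degenerate-fit flag. Non-positive slopes report `D = 0`, flagged, never a
negative coefficient.

**Permeability.** The simplified solubility–diffusion relation
`P_m = D_m·K_p/δ` is the contract; no inhomogeneous free-energy-profile
integral is attempted. The literature definition of `D_m` as a *ratio* of
z to xy diffusion coefficients is dimensionally inconsistent with
reporting `D_m` in cm²/s, so the package computes `D_z`, `D_xy` and their
ratio, and defines `D_m` by a configurable estimator defaulting to `D_z` —
membrane-normal transport is what permeation uses — while always reporting
the anisotropy ratio alongside. Every quantity the convention names is
therefore preserved, and the unit plumbing is pinned by a back-solve test:
with `D_m = 0.41×10⁻⁵ cm²/s` and `δ = 46.42 Å`, the `K_p ≈ 0.815` that
back-solves `P_m = 7.2 cm/s` forward-computes the same 7.2 cm/s.

## DSC thermogram parameterization

The baseline is a line through the median heat capacity of the first and
last 10% of the temperature range; a difference between those edge medians
exceeding 20% of the peak height flags a probably non-linear instrumental
baseline. Peaks are local maxima with prominence ≥ 5% of the global
maximum; bounds extend to 1% of the apex or a genuine local minimum
(bound-walking decisions run on a 9-point running median so noise upticks
do not truncate a descent; apexes and areas always use the raw trace). The
largest-area peak is the main transition; detected peaks at lower
temperature are pre-transitions.

- `T_m`: vertex of a parabola fitted over the apex neighbourhood (points
  ≥ 95% of the apex), falling back to the 3-point formula on sparse grids.
  This puts `T_m` resolution well below the sampling step, which matters
  when dose-response tables report 0.1 °C shifts.
- `ΔT_b`: full width at half maximum, by linear interpolation at half
  height. Width "at the baseline" is noise-dominated; FWHM is the
  convention that links width to van't Hoff cooperativity.
- `ΔH`: trapezoidal integral over the peak bounds. The 1%-of-apex bounds
  clip the far tails of a two-state peak: ~0.5% of the area, a known and
  accepted convention bias (tanh(3) of the sech²-shaped peak).
- `ΔT_h = T_m(heating) − T_m(cooling)`; a cooling apex above the heating
  apex yields a negative value, sign preserved.

Delta tables are heating-scan differences (`ΔT_m`, `ΔΔT_b`, `ΔΔH`) plus
the hysteresis difference `ΔΔT_h`; dose series order by increasing drug
fraction and flag a biphasic response when the `ΔT_m` increments change
sign exactly once (suppressed, with a message, below 3 ratios).

## The synthetic-data generators

The generators define the study conditions; they are geometric/stochastic
stand-ins with exactly known ground truth, not physical simulations.

**Bilayer builder.** Lipids are idealized bead-chains: one head bead, two
all-trans chains of point carbons with two geometric hydrogens each,
placed on the smallest enclosing lateral grid with spacing
`sqrt(target_apl)`. Defaults follow the experimental systems the package
targets: 60 lipids per leaflet (120 total), 16 carbons per chain
(DPPC-like), 1.27 Å C–C z-projection, 10 ps frame spacing, head and
particle masses from standard atomic weights with a 223.1 amu
phosphocholine head bead. Interdigitation is parameterized as the z offset
of the tail termini past the midplane — a monotone, oracle-verified proxy
for the mass-overlap fraction. An optional `target_thickness` back-solves
the head-plane gap, so published APL/thickness pairs can be reproduced
exactly. Probes (NO-like, 30.006 amu) start in the water slab; drugs go
into the headgroup region at a configurable insertion depth — how deep
such drugs sit is not established, so the depth is a free parameter
defaulting to the head plane itself. What the builder does *not* emulate:
chain conformational disorder (every chain is all-trans, so |S_CD|
profiles are flat), solvent structure, electrostatics, or any force-field
physics; conclusions from passing tests are about the estimators, not
about membranes.

**Langevin probes.** Overdamped dynamics on a piecewise-constant
diffusivity field (core vs outside, optional z anisotropy inside the
core) with a smoothed square well of depth `well_depth_kt`; edges use a
1 Å tanh ramp so gradients are well defined. The integrator is Itô
Euler–Maruyama *with* the `∇D` drift term,
`dz = (D′(z) − D(z)U′(z))dt + sqrt(2D(z)dt)·ξ`: without that term a
spatially varying diffusivity does not sample the Boltzmann distribution,
and the package's own K_p-vs-`exp(ΔU/kT)` recovery property would fail
whenever `d_core ≠ d_out`. Steps whose rms size exceeds a quarter of the
core half-width are rejected at spec time. xy is periodic; z reflects at
the box faces by default (periodic optional). Particles start uniform, so
equilibration is part of the run and the standard discard window applies.

**Thermograms.** Two-state van't Hoff excess heat capacity,
`Cp(T) = ΔH_vH·ΔH_cal/(R·T_K²) · K/(1+K)²` with
`K = exp[(ΔH_vH/R)(1/T_m − 1/T_K)]`; the noise-free main peak integrates
to `ΔH_cal` exactly, which anchors the enthalpy recovery tests. The van't
Hoff enthalpy is found by 1-D root finding so the peak FWHM equals the
requested width (narrow cooperative peaks such as 1.7 °C at 25 kcal/mol
correspond to ΔH_vH ≈ 400 kcal/mol, a cooperative unit of ~16 lipids).
The cooling trace shifts the main peak down by the hysteresis offset;
an optional pre-transition peak of the same functional form can be added,
and scan ranges too narrow to contain ~10 half-widths per side are
flagged as truncated.

**Determinism.** Every stochastic operation takes an explicit seed
(default 20240563) and restores the session RNG state, so identical specs
give bit-identical outputs and a pipeline run is reproducible
byte-for-byte.

## Problem sizes

The test suite validates at sizes chosen to make the statistical
tolerances comfortable while keeping a full run in minutes: bilayers of
16–60 lipids per leaflet over 2–100 frames for the structural oracles, 150
particles × 3×10⁴ steps for the quick diffusion checks, and 500 particles
× 10⁵ steps (the full stated scale) for the acceptance-level Langevin
recovery of D (within 10%) and K_p (within 15% of the Boltzmann ratio).
DSC round-trips run on 0.02 °C grids across a (T_m, ΔH, width) lattice
spanning 20–80 °C, 5–40 kcal/mol and 0.5–5 °C.

## Known limitations

- APL is a box-derived mean; no per-lipid (Voronoi) areas, splay/tilt
  fields or curvature analysis.
- Absolute `f_ov` values are convention-bound; compare only ratios across
  conventions.
- The builder's chains are rigid, so it cannot emulate the |S_CD|
  *profiles* of real disordered chains — only the closed-form limits.
- The MSD assumes uniformly spaced frames; z displacement is never
  unwrapped, so `D_z` from a strongly confined geometry reflects the
  confinement (use a tall box, or short lag windows, when free-diffusion
  recovery is the goal).
- Binary trajectory formats (XTC/TRR) are out of scope; the readers cover
  multi-frame GRO, multi-MODEL PDB (CRYST1 required) and extended XYZ.
- No multi-state DSC deconvolution, scan-rate correction, or instrument
  native-file parsing; negative enthalpy deltas inherit whatever
  integration-window convention the compared traces used.
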