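# bilayr

Quantitative analysis of lipid-bilayer simulations and differential scanning
calorimetry (DSC) thermograms, for studies of how small amphipathic drugs
alter membrane elastic properties and small-molecule permeability.

Membrane-active drugs (the motivating case: PDE5 inhibitors such as
sildenafil, vardenafil and tadalafil) intercalate into the headgroup region
of phospholipid bilayers, swelling the area per lipid, thinning the
membrane, and — when head–head repulsion outgrows what chain tilting can
absorb — driving the two leaflets' acyl chains to interdigitate. These
structural changes show up twice: in molecular-dynamics observables and in
the thermotropic parameters of DSC melting scans, and they modulate how fast
a small probe such as nitric oxide crosses the bilayer. `bilayr` implements
the full analysis chain for both data streams, plus a synthetic-data module
that generates bilayers, probe trajectories and thermograms with exactly
known ground truth so every estimator can be validated end to end.

## What it computes

**Bilayer structure** (from a multi-frame trajectory plus a role table):

- area per lipid, projected-area convention: `APL = 2 Lx Ly / N_lipids`
- bilayer thickness `δ`: distance between the leaflets' phosphate
  (or head-reference) planes
- mass-density profiles `ρ(z)` per atom selection, midplane-re-centred
- leaflet interdigitation as a fraction of mass overlap,
  `f_ov = ∫ min(ρ_U, ρ_L) dz / (½ ∫ (ρ_U + ρ_L) dz)`,
  and the treated/control ratio `D_int`
- deuterium order parameters per tail carbon,
  `S_CD(k) = ⟨(3 cos²θ − 1)/2⟩`, reported as `|S_CD|` for sn-1 and sn-2
- geometric hydrogen-bond counts (D–A ≤ 3.5 Å, H–D–A ≤ 30°)

**Probe transport** (from probe-particle positions):

- partition coefficient `K_p`: probe occupancy inside the hydrophobic core
  vs outside, with the core located from the head/tail density crossover
- mean squared displacement with multiple time origins, split into z, xy
  and 3-D components; diffusion coefficients by ordinary least squares on
  the linear MSD section (`D = slope / 2d`), 2–10 ns window by default
- membrane permeability by the solubility–diffusion relation
  `P_m = D_m · K_p / δ` (default `D_m = D_z`; the `D_z/D_xy` anisotropy
  ratio is always reported alongside)

**DSC thermograms** (two-column temperature / excess-heat-capacity CSV):

- linear baseline subtraction, multi-peak detection (main and
  pre-transition)
- `T_m` (parabolic apex interpolation), `ΔT_b` (full width at half
  maximum), `ΔH` (trapezoidal peak area), `ΔT_h` (heating-minus-cooling
  hysteresis)
- treated-minus-control delta tables across lipid:drug ratios, with
  biphasic dose-response detection

**Synthetic data** with known ground truth: geometric bead-chain bilayers
(controllable APL, thickness, tilt, interdigitation offset), overdamped
Langevin probes on a region-dependent diffusivity field with a smoothed
square-well core potential (Boltzmann-exact equilibrium), and two-state
van't Hoff thermogram pairs whose main peak integrates to the requested
calorimetric enthalpy exactly.

## Worked example

```r
library(bilayr)

spec <- bilayer_spec(
  lipid_types = tibble::tibble(name = "DPPC", count_per_leaflet = 60,
    n_tail_carbons = 16, head_mass = 223.1, carbon_mass = 12.011,
    hydrogen_mass = 1.008),
  target_apl = 48.6, target_thickness = 44.2,
  interdigitation_offset = 1.5, tail_tilt_deg = 12,
  n_frames = 25, thermal_jitter_sd = 0.8, probe_count = 10)
traj <- build_bilayer(spec)
structure_summary(traj)
#> <structure_summary>
#>   APL       48.60 +/- 0.00 A^2
#>   thickness 44.18 +/- 0.16 A
#>   f_ov      0.2117
#>   frames used 20 (discard 20%)
```

The summary reproduces the builder's targets: APL is exact by construction
(the lateral box area is `N · target_apl`), the thickness estimate recovers
the 44.2 Å head-plane separation to within the thermal jitter, and the
positive interdigitation offset yields a nonzero leaflet mass overlap.
`tidy()` / `glance()` return the same numbers as tibbles for downstream
dplyr work, and `autoplot()` draws the density, MSD, |SCD| and thermogram
objects.

A DSC round trip at typical untreated-DPPC control parameters:

```r
tg   <- generate_thermogram(thermogram_spec())  # T_m 41.5, FWHM 1.7, ΔH 25
heat <- transition_params(tg$heating)
glance(heat)[, 1:3]
#>     t_m delta_t_b delta_h
#> 1  41.5      1.70    24.9
hysteresis(heat, transition_params(tg$cooling))
#> [1] 0.4
```

The extracted `T_m` and width match the generator inputs; the enthalpy
comes back 0.5% low because the peak integral is taken over the
1%-of-apex bounds, which clip the far tails of the two-state peak.

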