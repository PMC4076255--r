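---
title: "Analysing structure and rotational dynamics of dry glycolipid lamellae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing structure and rotational dynamics of dry glycolipid lamellae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the questions

Synthetic glycolipids — a disaccharide headgroup (maltose, cellobiose,
isomaltose) glycosidically linked to one or two alkyl chains — self-assemble
into lamellar phases even without water. At room temperature the
monoalkylated lipids sit in a lamellar crystalline (L~C~) phase with mostly
extended, slightly tilted chains; branched-chain analogues form a fluid
L~α~ phase with far more chain disorder. Atomistic simulations of such
stacks (typically a double bilayer, four leaflets of 64 lipids, so that the
lamellar repeat is represented explicitly) are interrogated with a standard
battery of observables, and `glycolam` implements that battery as reusable,
tested code:

* **area per lipid** `A = Lx * Ly / n_leaflet`, per frame, with a
  block-average standard error;
* **local density profile (LDP)** along the layer normal, split into sugar
  and chain mass densities, block-averaged (5 blocks by default), and the
  **lamellar d-spacing** extracted from the headgroup-density maxima;
* **radial distribution functions** g(r) of selected chain carbons (C72,
  C76, C81: near the sugar, mid-chain, near the terminal methyl) against
  the same carbon on neighbouring lipids, under the minimum-image
  convention;
* **gauche/trans populations** for every chain torsion, resolved by
  leaflet;
* **chain tilt** distributions (angle of the chain vector to the layer
  normal) with peak detection, and a **protruding-lipid** classifier;
* **second-rank reorientational autocorrelation functions**
  C~2~(t) = ⟨P~2~(μ(t₀)·μ(t₀+t))⟩ for chain C–H vectors and sugar-ring
  vectors, fitted to a single exponential, with correlation times τ
  obtained by trapezoidal integration.

Because published trajectories of these systems are rarely deposited, the
package ships a synthetic-trajectory generator whose every statistical
property is known exactly. All tests, and the acceptance script, run the
real analysis code against that ground truth.

## Data model and conventions

Coordinates are in Ångström, times in ps, angles in degrees, masses in amu.
Boxes are orthorhombic; triclinic input is rejected (the simulated cells of
interest are orthorhombic under anisotropic pressure scaling, and
supporting shears would complicate every minimum-image computation for no
gain here). Frame indexing is 0-based and half-open everywhere, so "the
last 160 ns of a 200 ns run" is the window `[0.2 * n, n)` — the default
when no window is given. Two plain-text trajectory dialects are supported:
multi-model PDB with a CRYST1 record per MODEL, and extended XYZ whose
comment line carries `Lx Ly Lz time_ps` (standard XYZ has no box metadata,
so the convention is mandatory and validated).

Atom roles — which names are chain carbons (sn-1 C71..C82, sn-2 C83..C92),
chain hydrogens, sugar-ring anchors (C1, C4, C1p, C4p) — live in a
human-editable YAML role map, so every analysis is name-driven rather than
format-driven. A schema validator enforces chain-carbon contiguity, that
every hydrogen references a declared carbon, and anchor uniqueness.

## Leaflet assignment

Per-leaflet statistics need a lipid-to-leaflet map, and the operational
rule is a design choice of this package: headgroup centers are wrapped into
`[0, Lz)`, treated as points on a circle (so a leaflet straddling the
periodic seam is handled correctly), sorted, and cut at the four largest
circular gaps; labels run 1..4 by ascending mean z. The assignment is
deterministic and parameter-free. Separability is checked before the
result is trusted: each cutting gap must exceed twice the largest
within-cluster standard deviation, otherwise the function refuses and asks
for an explicit `leaflet_hint`. The width-based criterion (rather than the
largest within-cluster *gap*) was chosen because a single extreme order
statistic is far noisier than the spread it summarises.

## The synthetic generator

`lamellar_spec()` + `make_lamellar_trajectory()` build a double bilayer
(four leaflets of 64 lipids by default) on a square in-plane lattice
(lattice constant 6.28 Å, i.e. A ≈ 39.4 Å², typical of a dry maltoside
L~C~ phase). Chains are grown with ideal geometry — 1.53 Å C–C bonds, 111°
angles, torsions drawn independently per frame as trans/gauche± with a
per-dihedral gauche probability (default 0.16, a realistic L~C~ value) —
then rigidly rotated so the chain vector makes a sampled tilt angle with
the leaflet axis (default: one Gaussian mode at 18°, sd 3°, the tilt peak
of a dry maltoside bilayer). The default repeat distance is d = 32.2 Å and
the default trajectory length 50 frames at 5 ps spacing — long enough for
every estimator to resolve its target at the tolerances tested, small
enough that the full fixture builds in seconds.

Design notes, and what the generator does *not* emulate:

* Ideal geometry suffices because every analysis consumes only angles and
  distances; force-field bond-length fluctuations would only blur the
  ground truth.
* Torsions are resampled independently per frame (no Markov persistence):
  gauche-fraction estimation is a marginal statistic. Temporal correlation
  is exercised separately by the rotational-diffusion generator, which *is*
  Markov.
* Hydrogens are placed perpendicular to the local C–C–C plane — adequate
  methylene geometry for C–H vector work.
* Headgroups are four ring-anchor pseudo-atoms in a slab, not a sugar with
  internal conformational dynamics; hydrogen bonding, ring puckering and
  solvent are entirely absent. Tests passing on this fixture certify the
  *estimators*, not the physics of real trajectories.
* The tilt of a chain is applied as a rigid rotation, so the recorded tilt
  is exact ground truth for the chain-vector estimator, independent of the
  torsion state.

`simulate_rotational_diffusion()` performs isotropic rotational Brownian
motion of unit vectors. Each step rotates about a uniformly random axis by
a Gaussian angle whose variance is calibrated so that the one-step
second-rank factor E[P₂(cos δ)] equals exp(−6 D~r~ Δt) *exactly* (to
leading order the variance is 6 D~r~ Δt, the three body-axis rotations of
2 D~r~ Δt each). Because the chain is Markov and isotropic, C₂(t) then
follows the closed form exp(−6 D~r~ t) at every lag, not just in the
small-step limit — which is what makes this generator a clean oracle for
the ACF and correlation-time estimators. Steps with D~r~ Δt > 0.1 are
refused.

Two further oracles: `make_hex_lattice_slab()` (first RDF maximum of a
jittered hexagonal lattice sits at the lattice constant) and
`make_density_trajectory()` (headgroup planes a known distance apart, for
the LDP/d-spacing chain).

## Numerical choices

**RDF normalization.** g(r) = ⟨ΔN(r, r+δr)⟩ / (4π r² δr ρ) with ρ the
eligible-target number density, exactly the spherical-shell form even
though chain packing is quasi-two-dimensional; fidelity to the standard
definition wins, and a 2-D variant (2π r δr, areal density) is available
behind `norm = "2d"` for comparison — it moves the scale, not the peak
positions. Intra-lipid pairs are excluded by default (the selection is one
carbon per lipid against its neighbours). Default δr = 0.1 Å. Block curves
over contiguous frame blocks provide error bars. The implementation is
required by test to agree bin-for-bin with a literal O(N²) double loop.

**LDP and d-spacing.** Mass densities in amu/Å⁻³, default bin 0.5 Å, five
blocks. The d-spacing is the mean circular separation of consecutive
headgroup-density maxima: the profile is smoothed with a 3-bin circular
moving average, local maxima above half the global maximum are refined by
parabolic interpolation, and maxima closer than 5 Å are merged (a
headgroup *region* can show internal substructure — two apposed leaflet
head bands — that is not a lamellar repeat; 5 Å is far below any d of
interest, 22–42 Å). How a printed d relates to an LDP is genuinely
convention-dependent; peak-to-peak separation is this package's
convention and is stated with the result.

**Torsions.** Signed atan2 construction, range (−180°, 180°], trans at
±180°. The gauche window is the standard three-fold split: trans iff
|θ| ≥ 120°, gauche⁺ for 0 < θ < 120°, gauche⁻ otherwise; the boundary
value 120° counts as trans (a documented tie-break — any assignment of a
measure-zero set would do, but it must be fixed). gauche⁺ and gauche⁻ are
pooled for P(gauche) and also reported separately.

**Tilt and protrusion.** The layer normal is the fixed +z axis, not an
instantaneous fitted normal: the lamellae are built normal to z and the
0°/180° semantics of "aligned" versus "flipped" presuppose a fixed
reference. Histogram default 2° bins; peaks from a 3-bin moving average,
plateaus collapsed to the raw-count maximum, reported in descending
height. A lipid-frame is "protruding" when its chain angle, measured from
its own leaflet's normal (mirrored for −z leaflets), lies in [70°, 180°]:
the chain points sideways or back into the headgroup region. The angular
window is this package's operationalisation of a qualitative notion;
sensitivity to the 70° edge can be probed directly via the thresholds.

**ACF and correlation times.** C₂(t) uses all valid time origins
(maximally overlapping), averaged over lipids. It is evaluated through FFT
correlation of the six quadratic components u~a~u~b~ of the unit vector —
algebraically identical to the brute-force double loop (a test enforces
equality to 1e-8) but O(n log n). The single-exponential fit
a·exp(−t/τ~fit~) is unweighted on lags up to where C₂ first drops below
0.05 (tail noise would otherwise dominate), and the reported τ is the
trapezoidal integral of the fitted curve on the lag grid plus the analytic
tail a·τ~fit~·exp(−t~max~/τ~fit~); the closed-form integral a·τ~fit~ is
reported alongside, and the two agree for well-sampled decays. σ~τ~ takes
the larger of the fit-covariance delta-method estimate and the per-lipid
spread. A fitted decay exceeding 100× the window is flagged
`non_decaying`, never silently reported. For slow modes, the ACF lag
window should not exceed roughly a fifth of the series: beyond that, too
few independent origins remain per lag and the fit inherits the tail's
noise — the package default is half the series (the conventional maximum),
and the profile functions accept an explicit `max_lag`.

**Fit start values** come from a log-linear regression on the positive
part of the curve; on near-degenerate inputs (decorrelation within one
frame) the nonlinear refinement falls back to those start values rather
than failing.

## Problem sizes

The shipped tests and the acceptance script use: oracle comparisons at
200 atoms × 10 frames (RDF) and 500 frames (ACF); gauche recovery at 64
lipids × 500 frames; rotational-diffusion recovery at 10⁵ frames × 100
vectors for τ ∈ {1, 10, 45}·10³ frame intervals; tilt/protrusion recovery
at 144–256 lipids × 50–200 frames; and the full pipeline on the default
256-lipid, 50-frame fixture. These sizes make every estimate comfortably
significant at its tested tolerance while keeping the whole suite in the
minutes range on one core.

## Known limitations

* Orthorhombic boxes only; no triclinic cells, no trajectory alignment.
* The leaflet rule assumes z-stacked lamellae; vesicles or strongly
  undulating membranes would need a different operational definition.
* Single-exponential correlation times only — no stretched exponentials,
  wobble-in-cone models or NMR spectral densities.
* The synthetic fixture validates estimators, not force fields: agreement
  here says nothing about whether a given simulation is physical.
* Electron/neutron scattering profiles and structure factors are out of
  scope; the LDP is a plain mass density.

## A worked pass over the default fixture

```{r, eval = FALSE}
library(glycolam)

gen <- make_lamellar_trajectory(lamellar_spec(seed = 1))
lf  <- assign_leaflets(gen$trajectory, gen$map)
w   <- analysis_window(gen$trajectory, 0, n_frames(gen$trajectory))

compute_area_per_lipid(gen$trajectory, 64, w) |> glance()
compute_local_density_profile(gen$trajectory, gen$map, w) |>
  extract_d_spacing()
compute_gauche_profile(gen$trajectory, gen$map, lf, w) |> glance()
cv <- compute_chain_vectors(gen$trajectory, gen$map, window = w)
compute_tilt_distribution(cv, lf) |> tilt_peaks()
classify_protruding(cv, lf)
```

Every result object also has `tidy()` and `autoplot()` methods; the same
chain, driven from a YAML config, is available as `run_pipeline()` and the
`inst/scripts/glycolam-analyze.R` command line.
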