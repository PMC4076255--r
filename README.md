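# glycolam

Trajectory analysis for **anhydrous glycolipid lamellar assemblies** —
dry stacks of sugar-headgroup lipids (maltosides, cellobiosides,
isomaltosides, branched-chain maltosides) in lamellar crystalline (L<sub>C</sub>)
or fluid (L<sub>α</sub>) phases, simulated as double bilayers of typically
4 × 64 lipids. It is written for people who run atomistic MD of such
systems and want the standard structural/dynamical observables as tested,
reusable R functions rather than one-off scripts.

## What it computes

| Quantity | Definition |
|---|---|
| Area per lipid | A = L<sub>x</sub>·L<sub>y</sub> / n<sub>leaflet</sub>, per frame, block-average SE |
| Local density profile | mass density along z per component (sugar / chain / total), five 1/5-window block averages |
| d-spacing | mean circular separation of headgroup-density maxima (parabolic peak refinement) |
| RDF | g(r) = ⟨ΔN(r, r+δr)⟩ / (4π r² δr ρ), minimum image, intra-lipid pairs excluded; block error bars |
| Gauche populations | P(gauche) per chain torsion per leaflet; trans iff \|θ\| ≥ 120° |
| Chain tilt | θ = arccos(v·ẑ) of the chain vector (midpoint C71–C72 → C81–C82), histograms + detected peaks |
| Protruding lipids | fraction of lipid-frames with chain angle in [70°, 180°] from their leaflet normal |
| Rotational dynamics | C₂(t) = ⟨P₂(μ(t₀)·μ(t₀+t))⟩ for C–H and sugar-ring vectors; single-exponential fit; τ by trapezoidal integration |

Everything rests on a small core: multi-model PDB / extended-XYZ
trajectory I/O (the XYZ comment line must carry `Lx Ly Lz time_ps`), a
YAML **atom-role map** (which names are sn-1/sn-2 chain carbons, chain
hydrogens, ring anchors C1/C4/C1p/C4p), periodic minimum-image geometry,
and deterministic gap-based **leaflet assignment** along z.

A first-class **synthetic generator** builds lamellar fixtures with known
tilt mixtures, per-dihedral gauche probabilities, flip (protrusion) rates,
repeat distance and lattice constant — plus closed-form oracles for
rotational diffusion (C₂(t) = exp(−6·D·t)), hexagonal-lattice RDFs and
layered density profiles. Every analysis is tested against these ground
truths.

## Worked example

```r
library(glycolam)

gen <- make_lamellar_trajectory(lamellar_spec(seed = 1))  # 256 lipids, 50 frames
lf  <- assign_leaflets(gen$trajectory, gen$map)
w   <- analysis_window(gen$trajectory, 0, n_frames(gen$trajectory))

glance(compute_area_per_lipid(gen$trajectory, 64, w))
#>   mean_area_A2 se_A2 blocks n_frames
#> 1         39.4     0      5       50

extract_d_spacing(compute_local_density_profile(gen$trajectory, gen$map, w))
#> d-spacing: 32.2 A

glance(compute_gauche_profile(gen$trajectory, gen$map, lf, w))
#>   p_gauche      se      n chain
#> 1    0.161 0.00108 115200 sn1

cv <- compute_chain_vectors(gen$trajectory, gen$map, window = w)
tilt_peaks(compute_tilt_distribution(cv, lf))
#>   leaflet theta_deg height
#> 1       1        19   707.
#> 2       2       161   705
#> 3       3        17   707
#> 4       4       163   704
```

Reading the output: the default fixture is built at A = 39.44 Å²
(6.28 Å lattice), d = 32.2 Å, gauche probability 0.16 and a single 18°
tilt mode, and the estimators recover exactly those values — the tilt
peaks appear at ≈18° in leaflets whose chains point +z and mirrored at
≈162° in the opposite leaflets (2° histogram bins). `tidy()` and
`autoplot()` methods exist for every result type, and
`run_pipeline()` / `inst/scripts/glycolam-analyze.R` drive the whole chain
from a YAML config, writing per-stage CSVs plus a versioned
`summary.json`.

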