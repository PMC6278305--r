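# cunirgeom

Geometric analysis of nitrite binding at the catalytic type-2 copper (T2Cu)
site of copper-containing nitrite reductases (CuNiRs).

CuNiRs reduce nitrite to nitric oxide at a copper centre coordinated by
three histidine nitrogens. How the NO₂⁻ ion presents itself to the copper —
through its nitrogen (η¹-N, "N-bound"), through both oxygens (η²-O,O,
"top-hat"), or edge-on ("side-on") — is mechanistically decisive, and
distinguishing these orientations from coordinates alone requires a
well-defined local frame. This package is for structural bioinformaticians
and molecular modellers who want to classify binding orientations in crystal
structures, simulation snapshots, or optimised conformers, and to summarise
the accompanying distance and energy evidence.

## What it computes

**Ligand-local frame and binding angles.** An orthonormal frame is anchored
on the nitrite ion: origin at the NO₂⁻ centre of mass, +X towards the N
atom, the O atoms in the XY plane, and Z the plane normal signed so copper
has a non-negative Z component. Two angles of the copper position in this
frame classify the orientation:

- θ (altitudinal, "pitch") = angle between the projection of Cu onto the XZ
  plane and +X: 0° N-bound → 90° side-on → 180° top-hat;
- ψ (azimuthal, "yaw") = angle between the projection of Cu onto the XY
  plane and +X: 0° symmetrical N-bound, ~10–30° l-shaped, ~140–170°
  monodentate top-hat, ~170–180° bidentate top-hat.

Because the two oxygens are interchangeable, both angles are reported on
[0°, 180°]. Thresholds are closed at their printed boundaries and
configurable; angles outside every range are reported as
borderline/unclassified rather than force-assigned.

**Coordination twist φ.** With His1 the axial ligand (largest
N(NO₂⁻)–Cu–N(His) angle) and His2/His3 equatorial, φ is the angle between
the N(NO₂⁻)–Cu–N(His1) plane and the N(His2)–Cu–N(His3) plane: ~0°/180°
tetragonal, ~90° trigonal. The six Cu-centred ligand angles, both Cu–O
distances and their asymmetry (> 0.3 Å) are reported alongside.

**Trajectory metrics.** Per-frame Cu-to-sidechain-COM distances
(mass-weighted, heavy atoms from Cβ onward) and the
Tyr-phenolic-H···Asp/Asn hydrogen-bond distance (nearest acceptor,
re-selected per frame), with occupancy and split-regime summaries.

**Binding-preference statistic.** For paired relaxed conformers,
ΔE = E(top-hat) − E(N-bound), positive when N-bound is favoured, aggregated
per system and copper oxidation state. Absolute energies across snapshots
are never compared — only within-pair differences.

**Synthetic generator.** Every input the pipeline consumes can be generated
with known ground truth: active sites at prescribed (θ, ψ, φ) and
distances, multi-frame trajectories with hydrogen-bond-break events, and
conformer energy tables — the basis of the test suite.

## Worked example

```r
library(cunirgeom)

site <- make_site(site_spec(theta = 175, psi = 158, phi = 85,
                            cu_distance = 2.1))
analyze_site(site)[, c("theta", "psi", "mode_label", "phi", "shape_label",
                       "cu_o1", "cu_o2", "o_asymmetric")]
#>   theta psi          mode_label phi shape_label cu_o1 cu_o2 o_asymmetric
#> 1   175 158 monodentate top-hat  85    trigonal 1.765 2.534         TRUE
```

The site was built at θ = 175°, ψ = 158°: the copper sits almost
antipodal to the nitrite nitrogen (top-hat side) but rotated off the
bidentate pole, so one oxygen is 0.77 Å closer to Cu than the other —
the signature of a monodentate top-hat orientation — and the twist angle
85° labels the coordination shell trigonal.

```r
tbl <- make_energy_table(seed = 42)          # synthetic conformer energies
summarize_delta(pair_and_delta(tbl$records))
#> # A tibble: 6 × 6
#>   system oxidation_state n_pairs   mean    sd preference
#> 1 D97    CuI                   6 10.5    8.31 N-bound favoured
#> 2 D97    CuII                  6  0.766  1.95 N-bound favoured
#> 3 D97N   CuI                   9  5.64   6.35 N-bound favoured
#> 4 D97N   CuII                  9 -1.41   3.73 top-hat favoured
#> 5 D97p   CuI                   7  5.44   8.56 N-bound favoured
#> 6 D97p   CuII                  7  0.135  4.47 N-bound favoured
```

Each row averages ΔE over that system's conformer pairs: positive means the
N-bound orientation is energetically preferred, and the reduced Cu(I) rows
show the clear N-bound preference while the oxidised Cu(II) rows are close
to isoenergetic.

For file-based work there is a thin command-line wrapper
(`exec/cunirgeom`) with `classify`, `timeseries`, `denergy` and `synth`
subcommands over the same functions.

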