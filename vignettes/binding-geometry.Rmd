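---
title: "Classifying nitrite binding geometry at a type-2 copper site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nitrite binding geometry at a type-2 copper site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cunirgeom)
```

## The problem

Copper nitrite reductases bind NO₂⁻ at a catalytic type-2 copper
coordinated by three histidine sidechain nitrogens. The ion is a bent
triatomic with two chemically equivalent oxygens, so "how is it bound?"
is not answerable from raw coordinates without fixing conventions: the
same physical arrangement can be described with either oxygen first, from
either side of the nitrite plane, in any lab frame. This vignette records
the conventions this package uses, why they were chosen, and what the
accompanying tests do and do not establish.

## The ligand-local frame

`build_ligand_frame()` anchors an orthonormal frame on the nitrite ion:

- origin: mass-weighted centre of mass (COM) of the N, O1, O2 atoms;
- X: unit vector from the origin towards the nitrogen;
- Z: unit normal of the nitrite plane, *signed so the copper has a
  non-negative Z component*;
- Y = Z × X.

The two sign conventions deserve comment. The oxygens are interchangeable,
which makes the sign of the out-of-plane direction and the sign of the
in-plane Y component non-physical; the package therefore folds both out by
construction (Z towards Cu; ψ computed from |y|). In the measure-zero case
where copper lies exactly in the nitrite plane, the Z sign is chosen so the
Y component of copper is non-negative instead. Swapping the O1/O2 labels
consequently changes nothing downstream, which is enforced by a property
test.

The altitudinal angle θ = atan2(|z|, x) uses the *signed* x component:
this is the only reading under which θ runs 0° (Cu on +X, N-bound) through
90° (Cu above the plane, side-on) to 180° (Cu on −X, top-hat), matching
the standard progression of binding modes. The azimuthal angle
ψ = atan2(|y|, x) likewise runs 0° (symmetrical N-bound) to 180°
(bidentate top-hat). Both are undefined when the copper lies on the local
Y (for θ) or Z (for ψ) axis; these raise errors rather than returning an
arbitrary value. A consequence of the shared x sign is that θ and ψ always
lie on the same side of 90°, which the synthetic generator enforces as a
feasibility check.

A deliberate reading: ψ is referenced to the nitrite *COM*→Cu projection
(the frame origin is the COM), not to the N→Cu direction. The two differ
for bent ligands; the COM convention is the one under which a
crystal-like reconstruction at θ = 4.9°, ψ = 45.2° round-trips through
the full pipeline, which the acceptance checks exercise.

## Classification thresholds

`classify_mode()` applies closed angular ranges (degrees):

| altitudinal | θ | azimuthal | ψ |
|---|---|---|---|
| N-bound | 0–20 | symmetrical | 0–10 |
| | | l-shaped | 10–30 |
| top-hat | 160–180 | bidentate | 170–180 |
| | | monodentate | 140–170 |
| side-on | 70–110 | n/a | |

Boundary values belong to the class whose printed range includes them; the
two shared boundaries (ψ = 10 and ψ = 170) are assigned to the
symmetrical and bidentate classes respectively. Structures outside every
altitudinal range are labelled *borderline* and azimuthal values outside
every subclass *unclassified* — observed conformers do fall there (θ
around 145–155° sits between top-hat and side-on), and force-assigning
them would hide exactly the interesting cases. Thresholds are an argument,
not a constant, so sensitivity to them can be probed.

## The twist angle φ

`compute_phi()` identifies the axial histidine as the one with the largest
N(NO₂⁻)–Cu–N(His) angle, then measures the angle between the normal of
the N(NO₂⁻)–Cu–N(His_axial) plane and the normal of the
N(His_eq1)–Cu–N(His_eq2) plane, folded to [0°, 180°]: ≈0°/180° for
tetragonal coordination, ≈90° for trigonal. Two numerical choices:

- *Orientation.* The angle between plane normals distinguishes 0° from
  180° only given an orientation convention for each normal; the package
  fixes it by taking the equatorial histidines in residue-number order.
  The tetragonal band is symmetric ([0°, 30°] ∪ [150°, 180°] by default),
  so shape labels are unaffected by this convention — only the raw φ value
  folds as φ ↔ 180° − φ under the opposite ordering.
- *Ties.* When the two largest nitrite–Cu–His angles agree within 10⁻⁶
  degrees (e.g. exact C₃ᵥ symmetry) the lower residue number is taken as
  axial and a warning is emitted.

The shape bands (tetragonal [0, 30] ∪ [150, 180], trigonal [60, 120],
otherwise intermediate) are symmetric around the 0°/180° and 90° anchors
of the two ideal geometries; they are arguments with these defaults, since
no sharper boundary is defined by the geometry itself. Extra ligands (a
coordinated water giving penta-coordination) are outside the φ
construction, which is defined for the three-His + nitrite core only.

## Structure input and cleaning

PDB parsing is delegated to bio3d; `read_structure()` returns a tidy atom
table (one row per atom per model) and `clean_altlocs()` resolves
alternate locations by highest occupancy, then lowest B-factor, then
altloc character order, with partially occupied waters removed only on
request. The coordinating histidine nitrogen is chosen as the sidechain N
(ND1 or NE2) nearer to the copper, which is robust to tautomer naming.
Sidechain centres of mass use heavy atoms from Cβ onward with standard
atomic masses; hydrogens are excluded by default so crystal structures
(which carry none) and MD snapshots give comparable values, with
`include_hydrogens = TRUE` available for H-complete models. The package
consumes an already-assembled biological unit; symmetry expansion is a
preprocessing step outside its scope.

## Trajectory metrics

`com_distance_series()` tracks |Cu − sidechain COM| per frame;
`hbond_series()` tracks the Tyr phenolic H (falling back to the phenolic O
in H-free models) to the *nearest* acceptor, re-selected every frame (the
two carboxylate oxygens for Asp, sidechain O and N for Asn).
`summarize_series()` reports the arithmetic mean and, by default, the
population standard deviation — at thousands of frames the sample/
population distinction is far below any other source of uncertainty, and a
flag switches it. An optional split time yields separate before/after
summaries for trajectories whose baseline shifts mid-run (a Tyr sidechain
displacement). Hydrogen-bond occupancy uses a default 2.5 Å donor-H···
acceptor cutoff, exposed as an argument; the raw series is always
available, so the cutoff only affects the occupancy statistic. The
frame-to-nanosecond mapping (`dt`) is supplied by the caller, as stride
information is not recoverable from coordinates.

## Energetics

ΔE = E(top-hat) − E(N-bound) is computed strictly within a
(system, snapshot, chain, oxidation-state) pair key: absolute energies of
different snapshots are not comparable (different atom counts, different
solvent shells), and the implementation makes cross-snapshot comparison
impossible rather than merely discouraged. Unpaired records are excluded
with a warning and attached to the result; duplicates are an error.
Group summaries use the sample (n−1) standard deviation, since conformer
pairs are independent draws. Conformers whose relaxation produced an
unphysically short Cu–O(Asp) contact are discarded by flag: no numeric
cutoff defines "too short" in the source data, so the package requires an
explicit `flag_short_contact` column rather than inventing a threshold.

## The synthetic generator

`make_site()` is the deterministic inverse of the frame construction: it
lays the nitrite out in canonical position (ideal N–O bond 1.25 Å and
O–N–O angle 115° by default — standard values for the free ion, and
nothing downstream depends on them), places copper on the unique direction
realising the target (θ, ψ), and arranges the histidine shell so that the
axial-His rule and the twist angle recover their targets exactly. The
equatorial cone angle must exceed 90° for the normal-orientation
convention to recover φ rather than 180° − φ; the constructor enforces
this. `make_trajectory()` draws per-frame metric values i.i.d. from regime
Gaussians — defaults emulate a resting-state simulation with the Tyr–Cu
COM distance at 7.37 ± 0.19 Å, the Asp–Cu distance at 4.45 ± 0.18 Å, a
~1.8 Å hydrogen bond, and a displaced regime at 9.83 ± 0.49 Å after an
optional break — and builds minimal atom sets realising each drawn value
exactly. `make_energy_table()` draws ΔE per pair from per-group Gaussians
(defaults: the 6/7/9-pair, two-oxidation-state layout of
`energy_parameters()`) and adds large arbitrary per-pair offsets so gauge
invariance is genuinely exercised. `make_crystal_structure()` assembles a
single-model crystal-like neighbourhood — full heavy-atom sidechains
translated to prescribed COM distances, optional heme Fe/T1Cu pair — as a
labelled synthetic stand-in for deposited coordinates.

What these generators emulate is the *statistical and geometric structure*
of the real inputs: exact realisation of prescribed metrics, i.i.d.
Gaussian fluctuations, step-like regime changes. What they do not emulate:
autocorrelated dynamics, force-field-realistic rotamers, water networks,
or correlated noise between metrics. Passing tests therefore establish
correctness of the computations and conventions, not fidelity of any
simulation; conclusions about real trajectories still depend on the
quality of the coordinates supplied.

## Problem sizes and tolerances

The test suite recovers target angles over 500 random noiseless sites
(θ, ψ to 10⁻⁶ degrees; φ to 10⁻³ degrees), cross-checks frame, θ, ψ and φ
against independently coded oracles (Gram–Schmidt rotation matrix;
QR-null-space plane normals) on 1000 random sites to 10⁻⁶, verifies
invariance under 100 random proper rigid motions and oxygen relabelling,
and recovers generator means from 20 seeded replicates of 500-frame
trajectories and full conformer tables to within three standard errors.
Geometry through PDB files is exact only to the format's three coordinate
decimals, which bounds angle round-trips through files at a few
hundredths of a degree.

## Known limitations

- The frame construction assumes a bent triatomic ligand; linear or
  near-linear nitrite geometries are rejected as degenerate rather than
  approximated.
- Oxidation state is user metadata throughout — nothing is inferred from
  geometry.
- mmCIF input, symmetry-mate generation, hydrogen placement and
  protonation assignment are out of scope; supply an assembled,
  appropriately protonated model.
- The φ value (not its shape label) depends on the stated
  equatorial-ordering convention; compare φ values across software only
  after checking that convention.
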