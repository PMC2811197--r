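---
title: "Methods: profiling bromodomain histone-binding selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling bromodomain histone-binding selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bromoscope` chains five stages: peptide library design, dot-blot
normalization, molecular interaction fields (MIFs) over superposed binding
sites, PC1-based classification, and structure descriptors. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, the design choices made where the problem was genuinely open, and
what the synthetic benchmarks do and do not establish about real data.

## Peptide library

Peptides are 15-residue windows centred on an acetyl-lysine of a mature
(initiator-Met-removed) core histone, so that site labels follow the usual
mature numbering (H3K4, H4K16, ...). When fewer than 7 residues precede a
site, the missing length is taken from the left-truncation of the linker
`GGSG` (`GGSG` for 4 missing residues, `GGS` for 3), which reproduces both
linker variants used on N-terminal sites (H3K4, H4K5, H2AK5, H2BK5). The
window length (default 15, must be odd) and the linker are the only design
parameters.

Two decisions were open:

* **C-terminal short windows.** H2BK120 sits 5 residues from the H2B
  C-terminus; no C-terminal linker convention exists for such windows. We pad
  the right side with glycines to length 15 and record the count in `c_pad`,
  keeping the Kac central. This is a documented convention, not an inference.
* **Sites that are not lysine in the canonical human sequences.** The
  packaged site table lists H2A K21 and H2B K118, but canonical human H2A
  carries Ala21 and canonical human H2B type 1 carries Val118 — histone
  variants and numbering conventions differ between sources. Since a peptide
  library is synthesized to order, the default builder places the
  acetyl-lysine at the listed position within the canonical sequence context
  and flags those two peptides `substituted = TRUE`. Strict mode
  (`allow_substitution = FALSE`, the `build_peptide()` default) refuses such
  sites instead. Either way the library invariants hold: every peptide is 15
  residues with lysine at position 8.

Composition features count K/R (the Kac included), D/E, polar non-charged
(S, T, N, Q, C, H), and aromatic (F, Y, W) residues over the whole 15-mer —
tyrosine is counted as aromatic, not polar — plus two local features at
Kac ± 1: the proline count and `has_basic_flank`. The K56/K56′ control pair
can be built on the yeast H3 sequence (`k56_species = "yeast"`), matching the
convention under which that control is usually spotted.

## Dot-blot model

Raw integrated spot densities `Xi` (arbitrary units) are normalized as
`RI = (Xi − B)/G`, where `B` is the arithmetic mean of the densities of five
empty spots (the first five in layout order if more exist) and `G` is the
density of the GST 5 ng calibration spot. Membranes belong to one of four
subtypes; scaled values `Ws · RI` use the fixed factors
`Ws = 1.00, 0.95, 0.50, 0.20`. The subtype is metadata on the layout: nothing
in a membrane image identifies its subtype, so it must be supplied. Binder
calls use an inclusive threshold on the scaled RI, default 0.2 — the value at
the least-preferred-binder end of the reported 0.2–1.5 scale (we take that
range to be post-scaling). Negative scaled RIs are retained, not clipped, so
empty-spot statistics stay unbiased; clipping is a display decision.

Heat-map biclustering uses average-linkage agglomerative clustering on
Euclidean distances, rows (BRDs) and columns (peptides) independently; no
specific linkage is canonical for this display, and average/Euclidean is the
common default for intensity matrices. Rows and columns are label-sorted
before clustering, which makes the dendrograms invariant to input order and
ties deterministic.

## Interaction fields

The MIF energy at grid node *p* for a probe is

E(p) = Σ_atoms ε_ij [ (R_ij/r)¹² − 2 (R_ij/r)⁶ ] + Σ_atoms 332.0 · q_probe · q_atom / (ε(r) · r),

with Lorentz–Berthelot-style combination (R_ij = r_probe + r_atom, ε_ij =
√(ε_probe ε_atom)), a distance-dependent dielectric ε(r) = 4r (so the Coulomb
term is 83 · q_probe · q_atom / r²), energies in kcal/mol and distances in Å.
Values are clamped at +5 kcal/mol so that steric-clash nodes do not dominate
column variances downstream; nodes within 0.05 Å of an interacting atom are
set to the clamp. A probe that interacts through neither term (zero charge
and zero well depth) yields an identically zero field. No distance cutoff is
applied by default (binding sites are desk-scale); `energy_model(cutoff =)`
enables one. These functional forms and constants are this package's own
documented defaults, consistent with common MIF practice; empirical
hydrogen-bond directionality terms and solvent models are out of scope.

The packaged probes are `N1+` (sp3 amine NH cation, q = +1 e, ε = 0.16
kcal/mol, R = 1.85 Å), `DRY` (neutral hydrophobic, LJ only, ε = 0.21, R =
1.70) and `OH2` (small neutral water-like, ε = 0.15, R = 1.40). Only the
`N1+` probe is a named part of the original analysis; the neutral companions
are assumptions that double as negative controls — they carry no
class-discriminating signal in the synthetic benchmark.

Atom parameters come from a minimal formal-charge scheme (Asp/Glu −0.5 e per
carboxylate oxygen, Lys +1 on NZ, Arg +0.5 on each of NH1/NH2, termini
neutral, everything else zero) and a per-element LJ table; both are pluggable
arguments of `assign_params()`. Hydrogens are ignored throughout. Grids are
axis-aligned bounding boxes of the selected site expanded by `margin`
(default 4 Å) at `spacing` (default 1 Å). Structures must first be brought
into a common frame: `superpose()` implements the standard SVD (Kabsch)
least-squares fit with a determinant correction, and errors on collinear
inputs (second singular value below 1e-10 of the first).

## Field PCA and classification

Per-structure, per-probe fields are flattened (x-fastest node order) and
concatenated into one matrix, one row per structure. Pretreatment: columns
with SD below `min_sd` (default 1e-6 kcal/mol) are dropped, the rest
mean-centred, and each probe block scaled to unit total variance. The block
scaling is the "consensus" element of the analysis — it stops any one probe
from dominating PC1 by its raw energy scale; the exact multi-block consensus
PCA variant used originally is unspecified, so we implement block-scaled PCA
with post-hoc per-block contributions ("CPCA-lite").

PCA is the exact SVD of the pretreated matrix. The sign of each component is
fixed so the designated reference structure (a known good binder, the first
row by default) has a non-negative score; with that anchor, `classify_pc1()`
labels structures binder-like iff PC1 ≥ 0 (threshold configurable).
Explained variances are `d²/(n−1)` and sum to the total variance of the
pretreated matrix to 1e-8, which the tests assert.

Neighbor-joining clustering uses `|PC1_i − PC1_j|` distances — PC1 alone, as
only the first component is used for classification. The 3-taxon case is the
closed-form three-point solution; larger matrices go through `ape::nj()`,
whose output reproduces additive matrices exactly. Negative branch-length
estimates are clamped to zero with a message. Loading maps select, per
probe, the grid nodes whose |PC1 loading| is among the top
`ceiling((1 − quantile)·n)` of retained variables (default quantile 0.98),
with ties broken by column index so the mask is deterministic; `quantile = 1`
gives an empty mask.

## Structure descriptors

Surface potentials are sampled on Fibonacci lattices over solvent-extended
atom spheres (radius + 1.4 Å), discarding points buried in any other sphere;
the lattice is oriented in an intrinsic body frame built from the atom
coordinates, so all descriptors are rigid-motion invariant (asserted to
1e-6). The potential uses the same ε(r) = 4r dielectric as the fields — these
are deliberately *not* Poisson–Boltzmann surfaces. The ZA patch score is the
sum of negative-only potentials within 6 Å of the region's atoms; aromatic
pocket counts use an 8 Å shell around the pocket centroid; "C-terminus of
the third helix" means the last 2 residues of αB. The 6 Å/8 Å/2-residue
windows quantify qualitative descriptions ("around", "in the vicinity", "at
the C-terminus") that come with no stated distances; all three are
configurable.

## Synthetic generators: what they emulate, and what they do not

`simulate_membrane()` produces spot densities `B0 + θ·G0` (peptides), `B0`
(empty) and `amount/5 · G0` (GST, linear in loaded amount), each multiplied
by `(1 + ε)`, `ε ~ N(0, rel_sd)`. The default `rel_sd = 0.05` sits mid-way
in the 3–10% empty-spot variation observed across real membranes; `B0 = 100`
and `G0 = 1000` are arbitrary density units chosen so that background is 10%
of the calibration signal. Noise-free simulation inverts the normalization
exactly; under noise, θ is recovered with pooled RMSE ≤ 2 × `rel_sd` across
20 seeded replicates (the GST calibration error is shared by all spots of a
membrane, so individual replicates fluctuate around ~1.3 × `rel_sd`). The
generator does not model spatial blooming, scanner saturation, or
per-membrane background gradients.

`simulate_scaffold()` builds a concave pseudo-pocket (a 12-atom ring of
radius 6 Å, a rim ring at z = 2.2 Å, a 7-atom floor at z = −2.5 Å, all
generic carbons) with N(0, 0.15 Å) coordinate jitter. The "good" class
distributes −3 e over the ring atoms; the "poor" class is neutral. For a
given seed the two classes have *identical* coordinates, so geometry carries
no class signal and the Coulomb field is the only discriminant — the planted
analogue of the conclusion that electrostatics separates binders from
non-binders. These scaffolds are controllable ground truth, not protein
decoys: passing the recovery benchmark shows the pipeline isolates an
electrostatic class signal against geometric jitter at realistic grid
resolution, not that it classifies real bromodomain homology models, whose
discriminating signal is weaker and entangled with loop geometry.

The end-to-end benchmark (14 scaffolds = 7 + 7, three probes, 1 Å spacing,
4 Å margin — about 21×21×14 nodes per probe) classifies all scaffolds
correctly by PC1 sign and ranks `N1+` first in block contributions (share
~0.8) in at least 19 of 20 seeded replicates; one replicate takes about 2 s,
so the full benchmark and the rest of the suite run in well under a minute
each. All generators are bit-reproducible given (parameters, seed), and
every stochastic test fixes its seed.

## Known limitations

* Homology-model building, structural alignment and domain detection are
  upstream of this package: structures and equivalence pairings are inputs.
* The formal-charge model ignores protonation states, His tautomers and
  termini; the MIF model has no hydrogen-bond geometry term, so donor/
  acceptor chemistry beyond electrostatics is invisible to it.
* Membrane subtype assignment is metadata; the package cannot infer it.
* PC1 classification assumes the dominant variance direction is the
  binder/non-binder contrast; with strong unrelated structural variation
  (e.g. large loop insertions) PC1 may track that instead, and the loading
  maps/block contributions should be inspected before trusting the labels.
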