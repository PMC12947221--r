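---
title: "Methods: fluctuation, mutual information and network analysis in mdmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation, mutual information and network analysis in mdmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmi)
```

`mdmi` turns an ensemble of protein MD replicates (multi-model PDB) into
fluctuation profiles, collective-motion summaries, interaction
persistence tables, a GPCR microswitch panel, and finite-sample-corrected
mutual-information (MI) networks. This vignette records the models and
conventions behind each stage, the parameters that matter, and the
design choices made where more than one reasonable convention exists.

## Trajectory model and alignment conventions

A `Trajectory` is an atom table plus a frames × 3N coordinate matrix in
Å (0.04 ns per frame by default, matching common production output).
Residues are identified by `(chain, author residue number)`; helix
position labels such as Ballesteros–Weinstein numbers are treated as
config-supplied annotations, never computed. Alternate locations other
than `' '`/`'A'` are dropped — the simplest deterministic rule. The
element symbol comes from PDB columns 77–78 and falls back to the
leading letters of the atom name (names beginning with a digit are
hydrogens). Hydrogens are required only by the hydrogen-bond stage;
every other analysis ignores their absence, and the reader reports
hydrogen availability at load time.

Superposition is a Kabsch least-squares fit (SVD with determinant
correction, so reflections are impossible). Two alignment references
are used deliberately:

* **RMSD series** align each frame to a chosen reference frame
  (default: frame 1 of the replicate), the convention of per-replicate
  deviation traces.
* **RMSF, PCA and the MI fluctuation series** align all pooled frames
  to the *iterated pooled mean*: frames are aligned to a provisional
  mean, the mean is recomputed, and the cycle repeats until it moves by
  less than 1e-6 Å. A mean reference is required for consistency with
  the definition of the fluctuation `ΔR_i(t) = |r_i(t) − ⟨r_i⟩|`, whose
  mean displacement vector is zero by construction.

Alignment absorbs six rigid degrees of freedom. For an N-residue
selection that removes a `~2/N` fraction of apparent variance, which is
visible in closed-form tests (isotropic jitter of σ per coordinate has
RMSF `σ√3` minus this shrinkage) and is why the test suite uses a
spherical mean structure — equal lever arms spread the absorbed
variance evenly — and ≥100 residues when checking the closed form
to 3%.

## Fluctuation summaries

* `rmsd_series()` aligns on one selection and measures on another, the
  usual "all / core / loop" reporting pattern. Region ranges (e.g. an
  ICL3 core of 241–260 with edges 230–240 and 261–266 for β2AR) are
  configuration, not code: the boundaries vary between annotation
  conventions.
* `rmsf_profile()` pools all replicate frames (condition-level
  profiles); per-replicate profiles are obtained by passing single
  trajectories.
* `windowed_rmsf()` cuts non-overlapping windows (e.g. 25 ns = 625
  frames) for convergence QC, dropping a trailing partial window, and
  summarizes the across-window mean and SD per residue.
* `delta_rmsf()` is a plain per-residue difference (condition minus
  reference) with per-region maxima; it is antisymmetric by
  construction.

## PCA of Cα motion

The population covariance of the 3N-dimensional aligned Cα coordinate
vector is eigendecomposed; eigenvalues (Å²) sum to the total
mean-squared fluctuation (checked at 1e-8 relative). The cumulative
variance ratio of the top *c* modes is `Σ_{i≤c} λ_i / Σ λ_i`.
Projections use the model's mean and eigenvectors; the fluctuation
along a mode is `sqrt(mean_t (P_t − ⟨P⟩)²)`, which equals `√λ` on the
fitting ensemble. Subspace similarity between two models is RMSIP over
the first k = 5 modes (the number of modes that typically carries
70–85% of variance in receptor ensembles). Eigenvector signs are fixed
by making the largest-magnitude component positive — RMSIP is
sign-invariant, plots become reproducible.

Per-residue mode profiles are computed from the rank-1 reconstruction
`⟨x⟩ + P_t·U`, i.e. each residue's share of the mode's motion. Whether
published per-residue "RMSF along PC1" curves use this convention or
another is generally not recoverable from figure captions, so the
scalar and the per-residue profile are both returned.

## Hydrogen bonds and contacts

A donor–hydrogen–acceptor triple is counted when the H–acceptor
distance is ≤ 2.5 Å and the D–H–A angle is ≥ 120°. Donors are N/O atoms
with a covalently bonded hydrogen — inferred geometrically (H within
1.2 Å in the same residue) because the inputs are bare PDB frames with
no topology file; acceptors are all N and O atoms; water is excluded
(protein-only scope). Hydrogens of a multi-H donor (lysine ammonium)
yield distinct records. Occupancy is pooled across a condition's
replicates, and records below a 0.001 frame-fraction threshold are
discarded as rare stochastic contacts. Per-residue summaries report
record counts and occupancy-weighted sums for both roles (record counts
are the default reading of "number of hydrogen bonds"), distinct
acceptor residues per donor, and persistence — the mean occupancy of
the residue's surviving bonds.

Two residues are in contact in a frame when any pair of heavy atoms
(C/N/O/S — Cα-only maps underestimate side-chain contacts) is within
6.0 Å; a contact is persistent when present in ≥ 75% of frames.
Raising the cutoff can only add contacts; raising the persistence
threshold can only remove them.

## Microswitch panel

Shipped definitions (β2AR author numbering; all residue and atom ids
overridable, so the panel ports to other class-A receptors):

| switch | metric | inactive rule |
|---|---|---|
| ionic lock | Arg131(NH1)–Glu268(OE2) distance | < 10.5 Å |
| Y–Y gate | Tyr219(Cζ)–Tyr326(Cζ) distance | > 14.6 Å |
| NPxxY | RMSD over residues 322–327 | < 2.0 Å |
| PIF | RMSD over residues 121 + 282 | < 2.2 Å |
| toggle | RMSD over residues 286 + 290 | reported only |
| ECL2 disulfide | Cys106–Cys191 Cα distance | reported only |

Motif RMSDs superpose the motif's heavy atoms on the reference
(inactive-state) structure and measure over the same atoms — the
minimal reading of "RMSD after alignment", chosen because side-chain
repacking is precisely the signal for PIF and the toggle. Distances
need no alignment. The panel reports per-trajectory medians, IQRs and
the fraction of frames satisfying each rule. One published description
of the ionic lock names Leu268 as the partner; the acidic partner
Glu268 (OE2) is used, consistent with the salt-bridge definition, and
the config can override it.

## Adaptive binning, entropy, and corrected MI

Each residue's scalar fluctuation series is binned on an equal-width
grid over its own range. The bin count scan starts at 2 and stops at
the smallest N with `(H(N+1) − H(N))/H(N) ≤ 0.02`; a hard cap of `√N_c`
bins keeps small samples from chasing noise (a constant series is
flagged and assigned one bin, H = 0). The scalar (1-D) reading of "an
atomic fluctuation" is used because the binning criterion is written
for a one-dimensional histogram.

Finite-sampling corrections are applied exactly as the formulas above
state: entropy gains `(N_b − 1)/N_c`; MI, via
`MI = H_i + H_j − H_ij`, loses
`(N_b(i,j) − N_b(i) − N_b(j) + 1)/(2 N_c)`. Note the entropy correction
is used in its printed per-sample form, not the `1/(2 N_c ln 2)`
variant found elsewhere in the literature; at the pooled sample sizes
this under-corrects slightly, which is why the independence-null
acceptance bound is 0.02 bits rather than zero. Corrected MI can be
negative on independent data; such values are floored at zero and
counted. The corrected self-information of a series differs from its
corrected entropy by exactly `(N_b − 1)/(2 N_c)` — a direct consequence
of applying the two printed corrections consistently.

Cα MI matrices store each residue's corrected entropy on the diagonal.
Dihedral MI uses the same discrete engine on rotamer states:

* Backbone φ/ψ: three equal 120° sectors anchored at −180°; a boundary
  angle belongs to the lower sector's closed edge (so −180° is state 1).
  Anchored sectors were chosen over Ramachandran-basin boundaries as
  the parameter-free option; the library is overridable for
  sensitivity analysis.
* Side-chain sp3 χ: g+/t/g− sectors with boundaries at 0° and ±120°.
* Terminal planar dihedrals (Asp/Asn, Glu/Gln terminal, Phe/Tyr, His,
  Trp ring χ2): two states, |θ| ≤ 90° vs > 90°.

A residue pair's dihedral MI is the **sum** over its dihedral pairs by
default (max and mean are selectable): the pairwise formula is defined
per state pair and no residue-level reduction is canonical, so the sum
— which scales with the number of coupled degrees of freedom — is the
default and the choice is recorded in the output. Missing dihedrals
are marked absent, never zero-filled, and a residue pair with no usable
dihedral pair is flagged absent rather than reported as zero.

Two sequence-separation defaults coexist on purpose: distant-pair
dihedral summaries use |i − j| > 5, the Cα network rule uses
|i − j| > 6. Both are overridable; the discrepancy is preserved rather
than harmonized because each is stated in its own context.

Aggregation schemes over distant pairs: per-residue mean ⟨MI⟩,
condition difference ΔMI against a reference matrix, per-residue-type
and type-pair means, per-chemical-class (basic/acidic/amide/polar/
hydrophobic) and class-pair means, and means by rotatable-bond count.
The shipped χ-count table uses the standard number of side-chain χ
dihedrals per residue type (Arg/Lys 4, Met/Glu/Gln 3, …); published
rotatable-bond groupings vary in whether terminal planar dihedrals
count, so the table is part of `residue_class_table()` and overridable.

## The long-range network

Edges require all three of: sequence separation > 6, trajectory-mean Cα
distance `D_ij ≥ τ`, and `MI_ij ≥ τ_mi`. The distance condition *keeps*
spatially distant pairs — the network isolates long-range information
transfer from direct contact coupling, so the cutoff defaults to the
6.0 Å contact cutoff. The trajectory-mean distance is the default edge
test (per-frame and closest-approach reductions are available). Edge
weights are MI divided by the maximum MI over included edges, so a
non-empty network always has a unit-weight strongest edge. Degree
centrality is `deg(i)/(N−1)` with N the full residue count (isolated
residues included). Betweenness is the unnormalized shortest-path form
on hop counts, as the formula is stated without weights; a weighted
variant (length 1/w) is selectable. Both centralities are delegated to
igraph and cross-checked in the test suite against exhaustive
path-enumeration oracles on small graphs.

## Synthetic generators and what passing tests mean

`gen_gaussian_traj()` draws frames about a mean structure (an ideal
helix by default) with isotropic per-residue jitter, optional
correlated blocks, and optional planted collective modes:

* Block correlation is planted on displacement components along one
  shared random unit axis per block
  (`a_i = √ρ·z_common + √(1−ρ)·z_i`), making the axis-projection
  correlation exactly ρ; remaining jitter is confined to the
  perpendicular plane so the projection is undiluted.
* Planted modes are first projected out of the six rigid-body patterns
  (translations, infinitesimal rotations about the centroid): an
  alignment-based analysis can only ever recover the internal part of
  a motion, so the generator's ground truth is that internal part.

`gen_rotamer_series()` draws i.i.d. state pairs from a planted joint
table and returns the table's exact MI, so estimator tests never
re-derive their target. `gen_hbond_scene()` poses donor/acceptor
residues in isolated clusters; scheduled frames satisfy both geometric
criteria with ≥ 0.1 Å / ≥ 5° margin, other frames violate exactly the
distance criterion, and occupancy is realized by per-frame Bernoulli
draws. All generators are bit-deterministic under a fixed seed.

These generators emulate the *statistical* structure each estimator
assumes — Gaussian fluctuations, i.i.d. frames, categorical rotamer
draws, cleanly posed geometries. They do not emulate autocorrelated
dynamics, anharmonic or multi-basin landscapes, coupled
backbone–side-chain motion, or solvent-mediated interactions. Passing
tests therefore demonstrate estimator correctness and calibration at
known ground truth, not fidelity of any biological conclusion drawn
from real trajectories; on correlated real data the effective sample
size is smaller than the frame count and corrected MI values are
correspondingly more biased.

## Numerical choices and problem sizes

* Iterated-mean alignment tolerance 1e-6 Å; Kabsch via SVD with
  determinant correction; collinear or < 3-atom fits are errors.
* Histogram values at the range maximum fall in the last bin; bin
  index is otherwise `floor((x − min)/d)`.
* Corrected MI floored at 0 with the floor count reported.
* Eigenvalues clipped at 0; eigenvector sign fixed as above.
* Degenerate networks (no qualifying pair) are valid empty graphs with
  a warning, and centralities are all zero.
* The test suite and the acceptance script run at deliberately compact
  sizes — e.g. pooled conditions of 3 × 2500 frames (the scale at which
  the corrected estimators are designed to operate), 100-residue
  closed-form RMSF checks, ≤ 12-node graphs for enumeration oracles,
  10^5 draws for exact-table recovery — chosen so each statistical
  check has comfortable margin at its stated tolerance.

## Known limitations

* PDB is the only trajectory format (no DCD/XTC); topology-free donor
  typing cannot distinguish chemically unusual protonation states.
* The pipeline analyses protein atoms only; lipids, water and ions are
  out of scope, as is any titration/protonation modelling.
* Dihedral MI treats each dihedral pair independently; joint
  multi-dihedral states (up to 6 per the full rotamer-library reading)
  are representable through the overridable state-count table but the
  shipped default uses 3/2-state discretizations.
* Betweenness on hop counts ignores edge weights by default; use the
  weighted variant when edge strength should shape paths.
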