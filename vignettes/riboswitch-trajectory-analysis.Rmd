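---
title: "Trajectory analysis of riboswitch aptamer ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis of riboswitch aptamer ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptanet)
```

# Scope

`aptanet` analyses coordinate ensembles of a nucleic-acid–ligand complex —
typically the aptamer domain of a purine-family riboswitch bound to
2′-deoxyguanosine (dG) or riboguanosine (rG) — and asks how ligand identity
reshapes local geometry and global communication. It computes, per system:

1. substructure-resolved deviation/fluctuation metrics (RMSD, RMSF),
2. the pseudorotation state of the ligand's furanose ring,
3. geometric hydrogen-bond and base-pair/stacking occupancies,
4. a residue-level correlation network and its suboptimal communication
   paths, summarized as node-degeneracy profiles compared across systems by
   the square inner product (SIP).

Simulation itself is out of scope: the package consumes multi-model PDB (or
DCD) trajectories, and ships generators that produce synthetic ensembles
with *known* statistical ground truth so that every stage is testable
without molecular-dynamics output.

# Data model

A `structure_model` holds the topology (atom names, elements, residue
triples, reference coordinates in Å); a `substructure_map` names the
canonical regions of the three-way junction fold — helices P1, P2, P3,
junction strands J1/2, J2/3, J3/1, loops L2 and L3, and the ligand. Region
membership is user-supplied annotation: it comes from crystal-structure
knowledge, and inferring it from sequence would smuggle in a secondary
prediction step the analyses do not need. A `trajectory_ensemble` groups
replicate frame arrays; an `analysis_window` is a half-open `[start, end)`
frame interval applied per replicate, mirroring the common practice of
analysing the equilibrated tail of each run and concatenating replicates.

Hydrogens are retained in the model but excluded by the `heavy` selection
predicate: deviation metrics are computed over heavy atoms, while
hydrogen-bond detection needs explicit hydrogen positions, so both must
coexist in one topology.

# Fluctuation metrics

Frames are superposed by a proper-rotation Kabsch fit (SVD with a
determinant correction, so mirror solutions are never returned; fewer than
three or collinear fit atoms raise an error). The substructure RMSD table
fits *each region to its own heavy atoms* before measuring it, so a helix is
judged on internal deformation rather than on rigid-body excursion. RMSF
uses two-pass fitting (fit to the reference, average, refit to the average)
and aggregates atoms to one value per residue as the RMS over the residue's
heavy atoms — RMS rather than mean preserves units and lets the mobile atoms
dominate, which is what a per-nucleotide mobility plot is meant to show.
Reported dispersions are frame-to-frame standard deviations; the standard
error of the mean is emitted alongside (`sd_rmsd`, `sem_rmsd`) because the
two are easy to conflate in published tables and the frame count that
separates them is not always recoverable.

# Sugar pucker

Ring geometry is reduced to the five endocyclic torsions
(ν~0~ = C4′–O4′–C1′–C2′ through ν~4~ = C3′–C4′–O4′–C1′, IUPAC sign
convention) and analysed in the Altona–Sundaralingam pseudorotation frame,
ν~j~ = τ~m~ cos(P + 144°(j−2)):

- P = atan2((ν~4~+ν~1~)−(ν~3~+ν~0~), 2ν~2~(sin 36° + sin 72°)), mapped to [0°, 360°);
- τ~m~ = ν~2~/cos P, switching to the numerator form near P = 90°/270° where
  cos P vanishes;
- conformer labels are the ten 36° sectors starting with C3′-endo at
  [0°, 36°); C2′-endo sits at [144°, 180°).

Altona–Sundaralingam (not Cremer–Pople) was chosen because the conformer
vocabulary of the field — C3′-endo vs C2′-endo for ribo- vs
deoxyribonucleosides — *is* the A–S sector labelling. The atan2 form keeps P
continuous through 90° and 270°. A ring with τ~m~ below 5° (configurable) is
reported as planar/undefined instead of returning a numerically meaningless
phase. The torsion-space generator `gen_furanose_ring()` inverts this
analysis exactly; round-trip agreement over the full grid
P ∈ {0°, 18°, …, 342°}, τ~m~ ∈ {20°, 35°, 45°} is required to 10⁻⁹ degrees in
the tests. A Cartesian embedding (`furanose_ring_coords()`) exists for
sector-level checks only: exactly closing a five-ring at arbitrary (P, τ~m~)
in 3-D is over-constrained, and the classifier consumes torsions anyway.

# Hydrogen bonds and base-pair annotation

A hydrogen bond is scored purely geometrically: two polar heavy atoms (N or
O by default), at least one with a covalently bonded hydrogen (assigned by a
1.2 Å distance convention in the reference coordinates), heavy–heavy
distance < 3.5 Å and D–H⋯A angle > 120°. Bookkeeping is at the
(donor, hydrogen, acceptor) triple level, so two amino hydrogens reaching
the same acceptor are two records — this is the granularity at which
pocket interactions are usually tabulated. Occupancy is the fraction of
window frames in which the triple is formed.

The base-pair annotator is deliberately a *simplified geometric
Leontis–Westhof heuristic*, not a reimplementation of any annotation tool's
internals: a pair requires ≥ 2 hydrogen bonds between the residues'
edge-table atoms, base-plane normals within 65°, and ring centres within
8.5 Å. Each base's edge (Watson–Crick, Hoogsteen, Sugar) is the majority
edge of its hydrogen-bonded atoms, with ties resolved WC > Hoogsteen >
Sugar; glycosidic orientation is cis when the C1′–N(gly)⋯N(gly)–C1′
pseudo-dihedral magnitude is below 90°. Stacking requires ring centres
within 4.5 Å, normals within 40°, and lateral offset ≤ 2.5 Å. All thresholds
are exposed as arguments; the atom-to-edge tables live in one place
(`LW_EDGES`) for auditability. Results at threshold boundaries should not be
over-interpreted — the consumed claims are pair identity, edge class and
occupancy, which are robust at this fidelity.

# Correlation network and communication paths

The dynamic cross-correlation matrix is computed over one node per
nucleotide — the C1′ atom by default (configurable to another atom or the
heavy-atom centroid), with the ligand as one node:

C(i,j) = ⟨Δr~i~·Δr~j~⟩ / √(⟨|Δr~i~|²⟩⟨|Δr~j~|²⟩),

displacements taken from window-mean positions after frame-wise heavy-atom
superposition onto the reference. Nucleotide-level (not heavy-atom-level)
nodes match the granularity at which communication results are interpreted
and keep the network small enough that path ensembles are exactly
reproducible. Per-replicate matrices are combined by element-wise mean into
a consensus (a signed minimum-magnitude variant is available), the neutral
reading of "consensus" when no mechanism is specified.

Edges are restricted to residue pairs in persistent contact (minimum
heavy-atom distance ≤ 10 Å in ≥ 75% of frames by default) and weighted by

w(i,j) = −ln |C(i,j)|,

so strongly correlated contacts are short. Natural log is used; the base
only rescales all weights and cannot change path rankings, but lengths must
be reproducible, so the convention is fixed and documented. To compare
systems on equal footing the network can be equalized to an exact edge
count: the requested number of largest-|C| contact pairs is kept (ties
toward the lower node-id pair), and an unreachable request is a hard error —
never a silent smaller network.

Suboptimal paths use Yen's k-shortest-loopless-paths algorithm over an
internal Dijkstra that breaks equal-distance ties toward the
lexicographically smaller node sequence. Path length is the sum of edge
weights, recomputed canonically left-to-right so that equal paths have
bit-identical lengths. The ensemble is emitted in non-decreasing length with
lexicographic tie-breaks, and the collection continues past k until the next
candidate is strictly longer than the k-th best, so ties at the cut are
resolved deterministically rather than by generation order. On every graph
small enough to enumerate, the test suite requires the Yen ensemble to equal
the brute-force enumeration of all simple paths *exactly*.

Node degeneracy is the fraction of ensemble paths through each node
(endpoints exactly 1). Two degeneracy profiles are compared by the square
inner product, SIP = (d₁·d₂)² / ((d₁·d₁)(d₂·d₂)) — 1 for proportional
profiles, 0 for orthogonal support, invariant to positive rescaling.
Defaults follow the published protocol scale: k = 1000 paths for analysis,
200 for visualization export.

# Synthetic ground truth

The generators exist so that each analysis can be checked against a known
answer:

- `gen_fluctuation_ensemble()` draws zero-mean Gaussian displacements with
  covariance σ~i~σ~j~ρ~ij~ applied i.i.d. to x, y and z. Because the three
  components share one inter-node correlation, the *theoretical* DCCM equals
  ρ exactly, giving a closed-form oracle; at 5000 frames the estimate must
  recover prescribed entries within 0.05.
- `gen_system_trajectory()` lifts the same machinery to full-atom systems by
  displacing each residue rigidly (plus small per-atom jitter), so a
  full-atom pipeline run carries a known communication ground truth. Note
  that frame-wise superposition then removes the collective component of the
  motion, attenuating the recovered correlations relative to ρ — the
  analysis scripts therefore judge the *pattern* (correlation of
  off-diagonal entries), not absolute recovery.
- `gen_hbond_scene()` places donor–H–acceptor triples at exact requested
  distance and angle, present in an exact fraction of frames.
- `gen_basepair_scene()` docks an idealized cytosine onto a guanine edge
  (Watson–Crick or Hoogsteen; the Hoogsteen variant protonates cytosine N3,
  as in the physiological G–C⁺ motif) and scripts cis/trans interchange by
  rotating the cytosine 180° about the central hydrogen-bond axis.
- `gen_toy_aptamer()` builds a deterministic aptamer-like model from
  idealized nucleotide templates: all nine canonical regions populated,
  residue centres on a ring layout so sequence neighbours and cross-strand
  partners are in contact range, and a guanine-like ligand whose furanose is
  set to the conformer the corresponding nucleoside prefers — C2′-endo for
  dG-like (no O2′), C3′-endo for rG-like (with O2′).

What passing tests show — and what they do not: the synthetic ensembles
reproduce the *statistical and geometric structure* the analyses assume
(prescribed correlations, exact interaction geometry, known pucker), so the
tests validate the estimators and algorithms. They do not emulate
force-field physics, solvent, or the true conformational landscape of a
riboswitch; agreement on synthetic data says nothing about whether a given
simulation protocol samples adequately.

# Study configuration and problem sizes

The packaged two-system study (`inst/extdata/two-system-config.yaml`)
compares a dG-like and an rG-like toy aptamer: 24 residues, 2 replicates ×
50 frames each, residue fluctuation amplitude σ = 0.5 Å with a
distance-decay correlation (length 15 Å), 0.05 Å atomic jitter, networks
equalized to 40 edges, k = 100 paths. These sizes were chosen so the full
battery — including the exhaustive annotation stages — completes in well
under two minutes on one core while leaving every stage statistically
non-trivial; the acceptance checks use larger dedicated ensembles (5000
frames for DCCM recovery, 10000 for RMSF closed forms) where the property
under test needs the sampling.

# Numerical choices and degenerate inputs

- Superposition requires ≥ 3 non-collinear fit atoms; the rotation is always
  proper (det = +1).
- Zero-variance nodes make a correlation undefined: hard error naming the
  node, not NaN propagation.
- |C| = 0 pairs cannot carry a −ln|C| edge and are excluded from candidacy.
- Planarity threshold τ~m~ < 5° returns an undefined pucker state.
- All tie-breaks (edge selection, path ordering, Dijkstra relaxation) are
  lexicographic on node ids, making network, paths, degeneracy and SIP
  bit-reproducible under a fixed seed; the pipeline-level test rereads every
  artifact byte-for-byte across two runs.
- Windows are validated against every replicate before any computation, and
  selection errors name the offending token.

# Known limitations

- The Leontis–Westhof annotator is a geometric heuristic; it does not
  implement full edge-vector mathematics or the Saenger catalogue, and
  unknown residue types are skipped with a warning.
- The stacking criterion is a declared threshold heuristic; published
  protocols delegate it to tools whose exact criteria differ.
- DCD input is supported via bio3d; XTC is not read (no installed reader),
  and multi-model PDB is the reference interchange format.
- Insertion codes are rejected; residue identity is (chain, resnum,
  resname).
- No binding-energy, normal-mode or secondary-structure-prediction stages:
  those require force-field energetics or sequence models outside this
  package's scope.
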