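# aptanet

Post-simulation analysis of nucleic-acid–ligand trajectory ensembles,
built around the aptamer domain of purine-family riboswitches that
discriminate 2′-deoxyguanosine (dG) from riboguanosine (rG). The package is
for structural-bioinformatics work that starts *after* the simulations: it
takes coordinate ensembles (multi-model PDB or DCD) plus a substructure
annotation of the three-way-junction fold (P1, J1/2, P2, L2, J2/3, P3, L3,
J3/1, Ligand) and quantifies how ligand identity reshapes local geometry and
global communication.

## What it computes

- **Substructure fluctuations.** Kabsch superposition (proper rotations
  only), per-region RMSD with each region fitted to its own heavy atoms, and
  per-residue RMSF with two-pass mean-structure fitting.
- **Sugar pucker.** Endocyclic torsions ν0–ν4 and Altona–Sundaralingam
  pseudorotation, νj = τm·cos(P + 144°(j−2)): phase
  P = atan2((ν4+ν1)−(ν3+ν0), 2ν2(sin 36° + sin 72°)), amplitude τm = ν2/cos P,
  and the ten 36°-sector conformer labels (C3′-endo at [0°, 36°), C2′-endo at
  [144°, 180°)).
- **Interactions.** Geometric hydrogen bonds (polar heavy atoms < 3.5 Å with
  a D–H⋯A angle > 120°, bookkept per donor–H–acceptor triple), a simplified
  geometric Leontis–Westhof base-pair annotator (edges by majority vote over
  atom-to-edge tables, cis/trans from the C1′–N⋯N–C1′ pseudo-dihedral),
  aromatic stacking, and frame-fraction occupancies for all of them.
- **Correlation-network communication.** Nucleotide-level dynamic
  cross-correlation matrices C(i,j) = ⟨Δri·Δrj⟩/√(⟨|Δri|²⟩⟨|Δrj|²⟩),
  replicate consensus, a persistent-contact filter, edge weights
  w(i,j) = −ln|C(i,j)| with exact edge-count equalization across systems,
  Yen's k shortest loopless paths (deterministic lexicographic tie-breaks),
  node degeneracy (fraction of paths through each node), and the square
  inner product SIP = (d1·d2)²/((d1·d1)(d2·d2)) to compare degeneracy
  profiles between systems.

Synthetic-data generators (correlated Gaussian ensembles, exact-geometry
hydrogen-bond and base-pair scenes, furanose rings at prescribed
pseudorotation states, a deterministic toy aptamer with all canonical
regions) provide known ground truth so the whole stack is testable without
molecular-dynamics output.

## Worked example

```r
library(aptanet)

# scripted hydrogen-bond scene: 3.4 A, 150 deg, present in 70 of 100 frames
scene <- gen_hbond_scene(3.4, 150, n_frames = 100, fraction = 0.7)
hbond_occupancy(scene$traj, scene$model)[, c("donor_label", "acceptor_label", "occupancy")]
#>   donor_label acceptor_label occupancy
#> 1   A:DON1@N3      A:ACC2@O2       0.7

# canonical G-C pair with scripted 60/40 cis/trans interchange
bp <- gen_basepair_scene(n_cis = 60, n_trans = 40)
as.data.frame(interaction_occupancy_map(bp$traj, bp$model)$pairs)
#>   label_i label_j       edge_i       edge_j orientation occupancy
#> 1    A:G1    A:C2 Watson-Crick Watson-Crick         cis       0.6
#> 2    A:G1    A:C2 Watson-Crick Watson-Crick       trans       0.4

# pseudorotation round trip at the deoxyribose-typical conformer
pseudorotation(gen_furanose_ring(P = 162, tau_m = 35))
#> pucker: P = 162.00 deg, tau_m = 35.00 deg (C2'-endo)
```

The occupancy is exactly the scripted frame fraction; the pair annotator
separates the cis and trans episodes of one pair into two records; and the
pseudorotation analysis inverts the torsion generator exactly.

## The two-system study

`analysis/01_simulate.R` … `analysis/06_compare_systems.R` run a complete
synthetic study from the packaged configuration
(`inst/extdata/two-system-config.yaml`): a dG-like and an rG-like toy
aptamer (24 residues, 2 replicates × 50 frames), analysed end to end with
networks equalized to 40 edges and k = 100 suboptimal paths. Each script
prints what it found and writes tables under `results/`. The comparison
stage ends with:

```
pairwise SIP of node-degeneracy profiles:
          dG-system rG-system
dG-system     1.000     0.951
rG-system     0.951     1.000
```

i.e. under the generator's shared correlation ground truth the two ligand
variants communicate near-identically — the SIP quantifies that in one
number, and the per-region degeneracy table underneath localizes the small
differences.

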