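# Two-system synthetic study: a dG-bound and an rG-bound toy aptamer with
# distinct fluctuation seeds, analysed end to end.
seed: 20220209
output_dir: results/two-system
systems:
  - id: dG-system
    synthetic:
      n_residues: 24
      ligand: dG
      n_frames: 50
      n_replicates: 2
      sigma: 0.5
      corr_length: 15
      atom_jitter: 0.05
      rng_seed: 101
  - id: rG-system
    synthetic:
      n_residues: 24
      ligand: rG
      n_frames: 50
      n_replicates: 2
      sigma: 0.5
      corr_length: 15
      atom_jitter: 0.05
      rng_seed: 202
analyses:
  rmsd: true
  rmsf: true
  pucker: true
  hbonds: true
  annotate: true
  dccm: true
  network:
    target_edges: 40
    d_cut: 10
    frame_fraction: 0.75
  paths:
    source: 2
    target: 12
    k: 100
  sip: true
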