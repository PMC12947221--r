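# Shipped pipeline defaults. Every value can be overridden per run.
output_dir: mdmi_output
seed: 1
stages: [simulate, fluct, pca, contacts, mi_calpha, network]

simulate:
  n_res: 30
  n_frames: 500
  replicates: 3
  sigma: 0.5
  blocks:
    - residues: [5, 6, 7, 8]
      rho: 0.9

# region annotation (author residue numbering; beta2AR loop ranges)
regions:
  ICL3:      {from: 230, to: 266}
  ICL3_core: {from: 241, to: 260}
  ICL3_edge_n: {from: 230, to: 240}
  ICL3_edge_c: {from: 261, to: 266}
  ECL2:      {from: 171, to: 196}

parameters:
  hbond:
    angle_min: 120      # degrees, minimum D-H-A angle
    dist_max: 2.5       # Angstrom, maximum H--acceptor distance
    min_freq: 0.001     # minimum fraction of frames
  contact:
    cutoff: 6.0         # Angstrom, heavy-atom contact cutoff
    persistence: 0.75   # minimum contact frame fraction
  binning:
    tol: 0.02           # relative entropy-gain convergence
  network:
    mi_threshold: 0.25  # bits
    dist_cutoff: 6.0    # Angstrom
    min_sep: 6          # sequence separation for network edges
  dihedral:
    min_sep: 5          # sequence separation for dihedral MI summaries
  microswitch:
    ionic_lock: 10.5    # Angstrom, inactive below
    yy_gate: 14.6       # Angstrom, inactive above
    npxxy: 2.0          # Angstrom RMSD, inactive below
    pif: 2.2            # Angstrom RMSD, inactive below
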