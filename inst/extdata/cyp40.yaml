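# Analysis configuration for the two-domain co-chaperone cyclophilin 40:
# an N-terminal peptidyl-prolyl-isomerase (cyclophilin) domain, a charged
# linker, and a C-terminal TPR helix bundle (helices P-V). Residue numbers
# are 1-based author numbering; all ranges are inclusive.
domains:
  cyclophilin: [1, 183]
  linker: [184, 213]
  TPR: [216, 362]
helices:
  P: [216, 235]
  Q: [239, 259]
  R: [262, 285]
  S: [289, 300]
  T: [307, 319]
  U: [323, 336]
  V: [341, 362]
# linker-TPR salt bridges monitored as acidic-O / basic-N COM distances
salt_bridges:
  - [200, 245]
  - [200, 248]
  - [204, 248]
pca_residue_range: [2, 365]
temperature: 310            # K
chain: A
frame_interval_ps: 50
production_length_ns: 720   # per replica; 14400 stored frames
n_replicas: 2
parameters:
  distance_bin_width: 0.5          # Angstrom
  angle_bin_width: 2               # degrees
  shell_cutoff: 10                 # Angstrom
  anticorrelation_threshold: 0.1
  anticorrelation_margin: 0.05
  distance_change_windows: [4, 10] # Angstrom
  distance_change_mode: strict
  salt_bridge_threshold: 4.5       # Angstrom
  min_prominence_fraction: 0.05
  fes_bins: 50
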