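# demo pipeline configuration: five-nucleoli phantom, nucleolus/cytoplasm
# band set, 2 um nucleolus filter, and a short FCS simulate-and-fit study
seed: 0
phantom:
  kind: five_nucleoli
  noise_sd: 0.0
bands:
  - label: nucleolus
    lo: 1.356
    hi: 1.370
  - label: cytoplasm
    lo: 1.343
    hi: 1.356
min_diameter: 2.0
fcs:
  components:
    - D: 25.0
      fraction: 1.0
  mean_particles_in_volume: 2.0
  n_reps: 3
  rep_duration: 2.0
  dt: 2.0e-6
  volume:
    w: 0.2
    s: 5.0
  model: auto
  compartment: nucleolus
timelapse:
  nucleolus_ri: [1.364, 1.376]
  cytoplasm_ri: [1.348, 1.354]
  interval_min: 20
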