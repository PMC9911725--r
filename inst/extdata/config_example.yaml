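# pipeline configuration consumed by run_pipeline(); fields mirror
# default_run_config()
mode: synthetic
seed: 42
synthetic:
  n_plots: 2000
  n_habitats_per_level: [6, 18, 54]
  tau1_sq: [0.2, 0.0, 0.0, 0.0]
traits: [plant_height, sla, seed_mass, srl]
models: [1, 2, 3, 4, 5]
n_components: 4
stratify:
  enabled: true
  cell_deg: 0.01
model_options:
  spatial: false
  k: 100
  weights: false
min_n_slopes: 100
out_dir: results/run
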