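# Demo configuration for run_pipeline(load_pipeline_config(...)).
# Values mirror the package defaults; the coexpression soft threshold of
# 12 and the NBS settings (primary p < 0.001, 5000 permutations) are the
# conventional analysis choices this pipeline emulates.
seed: 1
cohort:
  n_regions: 90
  edge_effect: 2.0
  affected_group: MDDSI
  noise_sd: 0.1
  density: 0.15
nbs:
  primary_p: 0.001
  n_perm: 5000
wgcna:
  power: 12
  min_module_size: 100
  target_r2: 0.85
  mm_threshold: 0.8
  gs_threshold: 0.5
enrichment:
  p_cutoff: 0.01
  min_overlap: 3
  min_enrichment: 1.0
  top_n: 5
  n_boot: 1000
validation:
  n_per_group: 30
  n_de: 50
  effect_size: 2.0
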