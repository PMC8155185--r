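seed: 1
simulation:
  profile: default
  cells_scale: 0.3
qc:
  dialect: day32
  min_genes_per_cell: 150
  min_cells_per_gene: 3
  mito_mads: 12
  mito_prefix: MT-
  target_sum: median
cluster:
  n_pcs: 17
  auto_pcs: no
  n_max_pcs: 30
  pc_tolerance: 0.01
  n_neighbors: 10
  resolution: 0.2
  sweep: no
  alpha: 0.05
  min_abs_lfc: 1
  z_min: 1.96
signature:
  target: mature
  min_target_prevalence: 0.5
  max_rest_prevalence: 0.25
  ratio_threshold: 3
  tf_ratio_threshold: 2
  tf_list: bundled
enrichment:
  gmt: bundled
  n_bins: 25
  ctrl_per_gene: 50
  alpha: 0.05
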