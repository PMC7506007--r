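# Bundled toy study: a compact synthetic cross + expression + behaviour
# experiment exercising every pipeline stage.
seed: 20
map:
  n_autosomes: 5
  length_cM: 50
  length_bp: 5.0e6
panel:
  sites_per_chrom: 400
  n_haps: 20
  diagnostic_frac: 0.7
pedigree:
  n_bc: 4
  marker_chrom: chr5
  marker_pos: 360000
cohort:
  n_bc3: 6
ancestry:
  window_bp: 1.0e6
  min_informative: 30
expression:
  n_genes: 300
  n_per_group: 6
  frac_de: 0.1
  effect_log2: 1.5
  alpha: 0.05
  mean_q: 200
ase:
  n_individuals: 8
  depth: 500
qtl:
  chrom: chr5
  start: 0
  end: 2.75e6
fd:
  n_sites: 4000
  window_bp: 1.0e5
  step_bp: 2.0e4
  min_sites: 20
behaviour:
  n_males: 60
  trials_per_male: 5
  chr18_effect: 1.5
  sigma_male: 0.5
  n_draws: 400
  n_warmup: 300
  n_chains: 2
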