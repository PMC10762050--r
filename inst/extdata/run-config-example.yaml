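# Example hrrscan pipeline configuration.  All values shown are the
# package defaults for a ~50k caprine SNP array; only `ped`/`map` (and
# optionally `groups`) need editing.
ped: goats.ped
map: goats.map
groups: groups.tsv        # TSV with columns: breed, group
max_per_breed: 30
seed: 1
qc:
  min_maf: 0.05
  max_snp_missing: 0.05
  max_ind_missing: 0.20
  autosomes_only: true
detect:
  min_snp: 10
  max_miss: 0
  max_opp: 0
  max_gap_bp: 1.0e6
  min_length_bp: 250000
  window_size: 10
  max_opp_window: 0
  max_miss_window: 0
  min_density: 1.0e-5     # one SNP per 100 kb
  snp_in_run_threshold: 0.05
islands:
  top_frac: 0.001
  min_freq: 0.20
  min_snp: 4
  merge_gap_bp: 1.0e6
# genome_bp: 2.4e9        # optional D_HRR denominator override
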