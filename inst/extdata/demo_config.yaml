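# Annotated demo configuration for isosip::run_pipeline().
# Every stochastic step derives from `seed`; rerunning with the same
# config reproduces all outputs byte for byte.
seed: 42
outdir: isosip_demo_out

community:
  n_taxa: 20              # taxa in the synthetic community
  carrier_fraction: 0.1   # fraction of genomes carrying one isoA copy
  labeled_taxa:           # taxa assimilating the 13C substrate (atom fraction 1)
    - taxon003
    - taxon007
  abundance_dist: dirichlet   # dirichlet | lognormal | equal
  genome_length: 20000        # bp per genome

reads:
  n_reads: 4000           # shotgun reads to simulate
  read_length: 143        # bp, post-QC short-read regime
  sub_error_rate: 0.005   # per-base substitution probability

search:                   # translated-search thresholds
  evalue_cutoff_target: 1.0e-4   # isoA screen
  evalue_cutoff_norm: 1.0e-6     # recA screen
  min_verify_identity: 50        # % identity; hits below are discarded

sip:
  enabled: true
  min_fold_13C: 5         # heavy/light fold for a labeled call
  min_control_ratio: 2    # fc_13C / fc_12C required when a control exists
  pseudocount: 1.0e-4     # RA floor
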