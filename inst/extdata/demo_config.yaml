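# Demo configuration for run_pipeline(): a small end-to-end run of every
# stage on seeded synthetic data. Completes in well under a minute.
seed: 1
counts:
  n_mirnas: 100
editing:
  coverage: 200
pingpong:
  n_pairs: 300
  region_length: 20000
clusters:
  genome_length: 2000000
  k: 4
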