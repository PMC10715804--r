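# Desk-scale experiment: synthetic 5-class data, instance-aware objective.
# Run with the CLI wrapper, e.g.
#   Rscript inst/cli/contrawr.R synth    --config config-desk.yaml --out data.rds
#   Rscript inst/cli/contrawr.R pretrain --config config-desk.yaml --data data.rds --run-dir runs/demo
#   Rscript inst/cli/contrawr.R probe    --config config-desk.yaml --data data.rds --run-dir runs/demo
profile: desk
data:
  synthetic:
    K: 5
    n_subjects: 40
    epochs_per_subject: 50
    C: 4
    n_samples: 3000   # N; unquoted "N" would be read as a YAML boolean
    fs: 100
    seed: 1
split:
  pretrain: 0.5
  train: 0.25
  test: 0.25
  seed: 1
contrastive:
  mode: contrawr_plus
epochs: 30
seeds: [1, 2, 3, 4, 5]
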