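# Full-scale Monte Carlo configuration: 1320 networks trained on 10 million
# simulated strokes with the wide [10, 400, 400, 400, 16, 7] architecture.
# This is a cluster-scale workload (flagged below); desk machines should use
# default_config.yaml. Body parameters and sampling ranges inherit the
# package defaults, which are hawkmoth-scale stand-ins.
dataset:
  n_train: 10000000
  n_test: 5000000
  seed: 1
  test_seed: 90001
architecture:
  widths: [10, 400, 400, 400, 16, 7]
training:
  optimizer: adam
  batch_size: 128
  lr: 1.0e-3
  min_delta: 0.01
  patience: 1000
ensemble:
  n_networks: 1320
  base_seed: 1
  threshold: 1.0e-3
  cluster_scale: true
pruning:
  scope: global
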