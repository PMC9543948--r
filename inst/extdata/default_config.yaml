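# Desk-scale defaults: a small ensemble on a reduced architecture, suitable
# for a single CPU. All omitted keys take the package defaults.
dataset:
  n_train: 50000
  n_test: 2000
  seed: 1
  test_seed: 90001
architecture:
  widths: [10, 50, 50, 50, 8, 7]
training:
  optimizer: adam
  batch_size: 128
  max_epochs: 30
ensemble:
  n_networks: 8
  base_seed: 1
  threshold: 1.0e-3
pruning:
  scope: global
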