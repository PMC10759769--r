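# Example config for `kiwifuse run-all --config ... --out results/`
dataset:
  n_per_region: 12
  seed: 3
  separation: 1.0
  noise_scale: 0.5
  image_size: 320
feature_sets: [enose, image, fused]
targets: [region, ssc, firmness]
n_components: 4
folds: 10
seed: 3
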