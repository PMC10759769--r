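# Example config for `kiwifuse simulate --config ... --out dir/`
n_per_region: 3
seed: 1
separation: 1.0
noise_scale: 1.0
image_size: 400
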