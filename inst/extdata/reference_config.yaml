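# Frozen full-scale reference architecture for the 3D DenseNet brain-age
# regressor. Resolved once by enumerating (stem_width, growth_rate,
# bottleneck_scale, compression, final_conv_width, bias toggles) with the
# closed-form parameter counter; this configuration's trainable-parameter
# count is exactly 251098737.
stem_width: 120
growth_rate: 56
bottleneck_scale: 2
block_layers: [3, 6, 12, 8]
compression: 0.5
final_conv_width: 7848
stem_kernel: 5
stem_stride: 1
bias_stem: true
bias_bottleneck: false
bias_growth: false
bias_final: true
pre_final_norm: false
stem_pool: false
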