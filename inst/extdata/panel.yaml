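# Physician panel for response simulation: latent treatment thresholds
# follow Beta(2.56, 9.14); per-physician discrimination (cumulative-logit
# slope in risk) uniform on the given range; cutpoint offsets s2..s7 with
# s3 = -s6 so the collapsed-scale balance point equals the latent
# threshold.
n_physicians: 50
threshold_shape1: 2.56
threshold_shape2: 9.14
discrimination_range: [20, 60]
spacing: [3, 1.5, 0.5, -0.5, -1.5, -3]
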