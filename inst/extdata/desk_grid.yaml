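# Desk-scale subset of the full simulation grid: both models, all settings,
# three sample sizes, five censoring proportions, the high signal-to-noise
# calibration, 200 replicates. The full study grid (nine sample sizes,
# twenty proportions, both R-squared targets, 1000 replicates) is reachable
# by editing these lists; values outside the study design additionally need
# `allow_custom: true`.
models: [1, 2]
settings: [S1, S2, S3, S4, S5]
n: [45, 300, 1000]
proportions: [0.1, 0.3, 0.5, 0.7, 0.9]
r2: [0.6]
reps: 200
seed: 20260101
compute_mse: false
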