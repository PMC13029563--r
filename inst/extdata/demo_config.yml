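# demo configuration for run_pipeline(): a small seeded end-to-end run
# over synthetic data (see ?run_pipeline for the available fields)
seed: 20260923
n_patients: 23
hct_range: [0.35, 0.46]
k: 1.0
n_draws: 10000
curve_policy: auto
band: [0.35, 0.46]
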