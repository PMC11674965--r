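# Packaged default cohort configuration (mirrors cohort_config() defaults)
n_gamers: 28
n_nongamers: 19
n_runs: 4
samples_per_run: 860
tr_seconds: 0.535
coupling_gamer: 0.21
coupling_nongamer: 0.15
coupling_sd: 0.075
rt_mean_nongamer: 620
rt_gap: 190
rt_noise_sd: 30
behavior_link_strength: 8
fa_shift: 0.05
qa_shift: 0.06
seed: 1
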