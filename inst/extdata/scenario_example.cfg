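# Example simulation scenario: a 6 Hz wrist tremor, moderate sensor noise,
# subject fully responsive to the cue with a 1-s tracking lag
f_tremor = 6
amplitude = 1
noise_sd = 0.1
responsiveness = 1
tracking_lag = 1
jitter_sd = 0.05
sample_rate = 50
duration = 1800
seed = 1
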