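# Example protocol configuration (defaults shown; any key may be omitted)
baseline_duration = 10
ratio_phase1 = 0.6666666667
ratio_phase2 = 0.3333333333
f_min = 1
f_max = 5
f_default = 4.5
day1_duration = 3600
daily_duration = 1800
n_days = 7
band_low = 1
band_high = 12
goal_tolerance = 0.10
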