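# MEK-inhibitor cohort: mildly delayed G1/S entry (26.6 +/- 11.5 h),
# downstream programme unchanged (slope ~0.95, independent durations).
name: MCF7-MEKi
n_cells: 120
frame_min: 20
horizon_h: 72
t_g1s_mean: 26.6
t_g1s_sd: 11.5
s_dur_mean: 13.5
s_dur_sd: 5.9
g2m_dur_mean: 6.9
g2m_dur_sd: 1.5
coupling: independent
coupling_strength: 0.0
noise_sigma: 0.1
arrest_fraction: 0.3
seed: 1
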