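# Heregulin-stimulated control cohort: G1/S at 19.0 +/- 7.2 h, S/G2 at
# 32.5 +/- 9.3 h, M/G1 at 39.4 +/- 8.7 h (n = 77 completing cells).
# S duration = 32.5 - 19.0; G2M duration = 39.4 - 32.5; S-duration SD from
# sqrt(9.3^2 - 7.2^2) under independent additive durations.
name: MCF7-control-HRG
n_cells: 77
frame_min: 20
horizon_h: 72
t_g1s_mean: 19.0
t_g1s_sd: 7.2
s_dur_mean: 13.5
s_dur_sd: 5.9
g2m_dur_mean: 6.9
g2m_dur_sd: 1.5
coupling: independent
coupling_strength: 0.0
noise_sigma: 0.1
arrest_fraction: 0.0
seed: 1
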