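# CDK4-inhibitor non-responder cohort: delayed G1/S entry (49.5 +/- 13.2 h)
# with negative coupling between G1/S time and S/G2/M duration. Total
# duration mean 19.05 = (22.3 + 15.8) / 2 (early/late group means); the
# duration SD (8.6) and coupling strength (-0.675) are solved from the
# cohort regression slope 0.56 and Pearson r 0.76 under the linear
# shrinkage model. Most treated cells arrest in G1.
name: MCF7-CDK4i
n_cells: 150
frame_min: 20
horizon_h: 72
t_g1s_mean: 49.5
t_g1s_sd: 13.2
s_dur_mean: 12.7
s_dur_sd: 7.7
g2m_dur_mean: 6.35
g2m_dur_sd: 3.8
coupling: negative
coupling_strength: -0.675
noise_sigma: 0.1
arrest_fraction: 0.4
seed: 1
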