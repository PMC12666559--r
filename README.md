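# fuccikit

Quantitative single-cell cell-cycle analysis for dual-reporter FUCCI
live-cell imaging, with companion tools for rule-based promoter/enhancer
classification from histone-mark peaks and single-cell immunofluorescence
quantification. The package is aimed at cell biologists studying G1/S
commitment (restriction-point) kinetics — for example how CDK4 inhibition
reshapes cell-cycle entry in ErbB2-driven breast cancer lines — who have
per-cell reporter intensities exported from tracking software and want
reproducible phase calls, transition times, and cohort statistics.

## What it computes

**Phase calling.** A FUCCI cell carries a geminin-degron reporter (hGem;
accumulates from S phase, destroyed at mitotic exit) and a PIP-degron
reporter (present in G1 and G2/M, degraded during S). With per-channel
positivity thresholds θ_hGem, θ_PIP, each frame is labelled

| PIP > θ_PIP | hGem > θ_hGem | phase |
|---|---|---|
| yes | no | G1 |
| no | yes | S |
| yes | yes | G2/M |
| no | no | U (indeterminate) |

Thresholds are estimated automatically as the antimode (deepest
kernel-density minimum between the two dominant modes) of each channel's
pooled intensity distribution, or supplied manually. A label median filter
and a dwell-filtered state machine over the canonical cycle
G1 → S → G2/M → G1 then yield per-cell transition times t\_{G1/S},
t\_{S/G2}, t\_{M/G1} and phase durations.

**Kinetics statistics.** Phase-fraction time courses, nuclear ratio
(fold-change in nucleus count), transition-time summaries (mean ± SD/SEM),
the phase-coupling OLS regression t\_{M/G1} = s · t\_{G1/S} + i with
Pearson r (s ≈ 1 means a fixed-length downstream programme; s < 1 means
late-entering cells compress S/G2/M), and an early/late median split of
G1/S times compared by Welch's t test.

**Chromatin regions.** H3K27Ac peaks are classified as promoters (peak
centre within 250 bp of the nearest TSS, no H3K4me1 overlap), enhancers
(> 250 bp with H3K4me1 overlap) or other; differential calls use coverage
|log2 FC| > 0.3 (promoters) plus same-direction target-gene expression
|log2 FC| > 0.2 (enhancers). E-box (CANNTG) scanning with a one-sided
binomial enrichment test is included.

**Imaging quantification.** DAPI-quantile G1/S intensity thresholds,
p-c-Myc / cyclin D1 ratio profiles over DNA content with per-bin modal
ratios, pixelwise Pearson and Manders (M1/M2, tM1/tM2) colocalization, and
positive-cell fractions.

**Synthetic data.** Every analysis has a seeded generator with ground
truth: FUCCI trace cohorts with configurable transition-time distributions
and negative G1/S-vs-duration coupling, planted regulomes, bimodal 2N/4N
immunofluorescence tables, and correlated image pairs.

## Worked example

```r
library(fuccikit)

cfg <- fucci_scenario("control")        # 77 cells, 20-min frames, 72 h
sim <- gen_fucci_traces(cfg)
timings <- call_cycle_timings(sim$traces)

summarize_transitions(timings, "g1s")
#> # A tibble: 1 × 5
#>   transition     n  mean    sd   sem
#>   <chr>      <int> <dbl> <dbl> <dbl>
#> 1 g1s           77  19.5  6.62 0.754

transition_regression(timings)
#> Transition coupling fit (n = 77 cells)
#>   t_mg1 = 0.947 * t_g1s + 21.03 h
#>   Pearson r = 0.749
```

The cohort's G1/S transition occurs at 19.5 ± 0.8 h (mean ± SEM) after
stimulation — the full pipeline (automatic thresholding, phase calling,
timing extraction) recovering the scenario's configured 19-h mean — and
the near-unit slope says the downstream S/G2/M programme runs for a fixed
duration regardless of when a cell passes G1/S. Under the packaged CDK4
inhibitor scenario (`fucci_scenario("cdk4i")`, negative coupling) the same
call chain gives a slope well below 1 and a lower Pearson r, and
`early_late_split(timings)` shows late-entering cells compressing S/G2/M.

`autoplot()` methods cover phase-fraction time courses, coupling fits and
ratio profiles; `tidy()`/`glance()` give broom-style summaries.

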