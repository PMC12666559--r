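---
title: "Methods: FUCCI phase calling, transition kinetics, and companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FUCCI phase calling, transition kinetics, and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccikit)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where a published description leaves the design
open.

## The reporter model

A FUCCI cell expresses two degron reporters read out as mean fluorescence
per frame. The geminin fusion (hGem) is an APC/C substrate: absent in G1,
accumulating from the onset of S, and destroyed at mitotic exit. The
PIP-degron fusion is a CRL4-Cdt2 substrate degraded during DNA
replication: present in G1 and G2/M, absent in S. Joint positivity
therefore encodes phase: PIP alone is G1, hGem alone is S, both is G2/M,
and neither (the brief mitotic window, or a tracking dropout) is
indeterminate, written U. The rule table is exhaustive and mutually
exclusive for any finite intensity pair, and is invariant to rescaling a
channel together with its threshold — so arbitrary acquisition gain does
not affect calls.

### Thresholds

Positivity thresholds are per channel, shared across a cohort.
`estimate_thresholds()` places each threshold at the *antimode*: the
deepest kernel-density minimum between the two dominant modes of the
pooled intensity distribution (off cells vs on cells). Two numerical
choices matter:

* **Log-scale density.** Reporter noise is multiplicative, so the off and
  on modes have very different widths on the linear scale; when the "on"
  phase occupies a minority of frames (heavily arrested cohorts) its mode
  can disappear under a linear-scale bandwidth. For strictly positive
  samples the KDE therefore runs on log intensities, where both modes
  have comparable widths and mode heights track their mass; the antimode
  is mapped back with `exp()`. Samples containing zeros fall back to the
  linear scale.
* **Mode screening.** Local maxima below 5% of the global density peak
  are ignored as ripple; if fewer than two modes remain the channel is
  reported as unimodal and a manual override is requested rather than
  guessing. Manual thresholds always pass through unchanged.

### Phase calling and smoothing

`call_phases()` applies the rule table per frame, then a label median
filter of width `smooth_frames` (default 3 frames = 1 h at the nominal
20-min frame interval). The majority label in each centred window wins;
ties keep the previous output label, a causal rule that cannot introduce
oscillation. Width 1 disables smoothing.

### Timing extraction

`extract_timings()` walks the label sequence with a forward state machine
over the canonical first cycle G1 → S → G2/M → (U?) → G1. A state change
is accepted only when the new label persists for `min_dwell_frames`
consecutive frames (default 3 = 1 h), so single-frame flicker cannot
create transitions. Transition times are the time stamp of the first
frame in the new state; no sub-frame interpolation is attempted, since
the 20-min acquisition grid is the native resolution of the data. The
M/G1 transition is defined by geminin loss after G2/M — the first
accepted exit from G2M, whether to U or directly to a G1 call.

Eligibility and exclusion rules:

* A cell must begin in G1 (its first non-U run); traces starting in S or
  G2/M are flagged `pre-cycling` and excluded, because the start of their
  cycle was not observed.
* A dwell-accepted label that violates the cycle order (e.g. S → G1, or
  G1 → G2M skipping S) flags the cell `non-canonical`. This also catches
  cells whose true S phase is shorter than the dwell window — a
  deliberate trade: such cells cannot be timed reliably at this frame
  rate.
* U runs while in G1 or S are treated as transparent dropout rather than
  a phase, since the cycle model places an indeterminate gap only around
  mitosis. This keeps cells with temporary tracking loss scoreable.
* Cells that never complete all three transitions within the horizon are
  `incomplete` (this includes fully arrested cells); partial transition
  times are kept but `complete = FALSE`, and all cohort statistics use
  complete cells only.

## Cohort statistics

`phase_fraction_timecourse()` reports per-frame percentages over G1, S
and G2M, excluding U from the denominator so the three phases sum to
100%; a frame with no labelled cell yields `NA`, never a silent zero.
`summarize_transitions()` uses the sample SD (n − 1) and reports both SD
and SEM. `transition_regression()` is ordinary least squares of the M/G1
time on the G1/S time (y on x; no errors-in-variables correction) with
the Pearson correlation of the pairs: slope 1 indicates a downstream
programme of fixed duration appended to whenever the cell entered S
phase, slope below 1 indicates compression of S/G2/M in late-entering
cells. `early_late_split()` cuts at the median G1/S time with ties
assigned to the early group (a deterministic ≤ rule), summarises the
S/G2/M duration per group, and compares groups with a two-sided Welch t
test; if a degenerate tie pattern leaves a group with fewer than two
cells the p-value is `NA` with a warning.

## Chromatin-region classification

Coordinates are 0-based half-open (BED convention) throughout; TSS
positions are 0-based points, and distance is measured from the peak
centre `floor((start + end)/2)` ignoring strand, since the classification
rule is symmetric. "Within 250 bp" is inclusive (≤), while the
fold-change thresholds are strict (>), so boundary values never flip a
call. Overlap means at least one shared basepair (computed with
`GenomicRanges`). Nearest-TSS ties break by lexicographic gene symbol for
determinism. Differential coverage uses
`log2((treat + 1)/(ctrl + 1))` — the pseudocount (configurable) guards
zero coverage; coverage values are consumed as-is, with no length
normalization, matching the upstream coverage-table convention.
Enhancer calls additionally require the nearest gene's expression change
to exceed 0.2 in log2 in the same direction; an enhancer whose target has
no expression value is conservatively `unchanged`, with a warning.

E-box scanning counts all (including overlapping) occurrences of CANNTG
with N restricted to unambiguous bases: a sequence-side N never matches,
so assembly gaps cannot create hits. The motif is its own reverse
complement, so one strand suffices. Enrichment between region sets is a
one-sided binomial test of the foreground count against the background
per-position rate — a deliberately minimal, self-contained alternative to
full motif-suite enrichment, appropriate for a single fixed-width motif.

## Imaging quantification

The DAPI G1/S threshold is the `(1 − sgm_fraction)` quantile of per-cell
DAPI intensities with linear interpolation between order statistics
(`stats::quantile` type 7); by construction the fraction of cells at or
above the threshold reproduces the supplied S/G2/M fraction up to
interpolation. The p-c-Myc/cyclin D1 profile excludes cells with zero
cyclin D1 rather than producing infinite ratios (the exclusion count is
reported); the per-DAPI-bin "vertex" is the centre of the tallest bin of
a within-bin ratio histogram (default 50 bins over the within-bin range,
ties to the lowest bin), which makes the vertex exactly scale-equivariant
in the marker channels. Thresholded Manders coefficients use
user-supplied thresholds; automated threshold search (Costes-style) is
out of scope.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed by the packaged scenarios and are not
tuning knobs.

`gen_fucci_traces()` draws each cell's G1/S time from a normal truncated
at zero, then S and G2/M durations. Under `coupling = "negative"` the
total S/G2/M duration is shrunk linearly in the standardized G1/S time to
hit the configured correlation, then the two phases are rescaled
proportionally, each floored at one frame. Reporter traces are piecewise
two-level signals (PIP high except during S; hGem high from G1/S to
M/G1) with multiplicative log-normal noise whose log-SD is
`noise_sigma` (default 0.1, i.e. ~10% of the dynamic range since the
"on" level is 1). A configured fraction of cells is arrested in G1.
Ground truth is emitted alongside, sufficient to compute every downstream
statistic without running the pipeline.

Packaged scenarios (YAML under `inst/extdata/scenarios/`) encode the
modeled cohorts:

* **MCF7-control-HRG** — 77 cells; G1/S 19.0 ± 7.2 h; S duration
  13.5 ± 5.9 h and G2/M 6.9 ± 1.5 h, so the implied S/G2 and M/G1 means
  are 32.5 and 39.4 h. The S-duration SD comes from the S/G2 time SD
  under additive independence (√(9.3² − 7.2²)); the printed M/G1 SD is
  *smaller* than the S/G2 SD, which no additive independent model can
  produce, so the G2/M SD is set small (1.5 h) and the M/G1 spread is
  accepted as slightly wide. Means, which the validation targets grade,
  are unaffected.
* **MCF7-CDK4i** — G1/S 49.5 ± 13.2 h, negative coupling, 40% arrest.
  The cohort's printed early/late duration statistics and its printed
  regression (s = 0.56, r = 0.76) over-determine the linear-shrinkage
  model and are mutually incompatible: the late group's SD is smaller
  than the spread implied by the coupling slope alone, and an
  early/late-derived coupling (total SD 6.0, ρ ≈ −0.68) would push the
  cohort's Pearson r *above* the control's, inverting the qualitative
  ordering the scenario exists to reproduce. The scenario therefore
  solves the coupling from the printed regression — total duration SD
  8.6 h and ρ = −0.675 reproduce s = 0.56 and r = 0.76 exactly before
  horizon censoring — keeping the duration *mean* at
  (22.3 + 15.8)/2 = 19.05 h from the early/late means. The early/late
  gap then comes out larger than the printed 6.5 h; its sign and
  significance, which the tests assert, are preserved. A saturating
  (floor-limited) coupling could reconcile all four numbers but would
  depart from the linear model used throughout.
* **MCF7-AKTi / MCF7-MEKi** — delayed entry (39.6 ± 14.8 / 26.6 ± 11.5 h)
  with the control's independent duration model.

What the generator deliberately does *not* emulate: photobleaching and
focus drift, cell division and lineage (each trace is one tracked
object), gradual reporter accumulation ramps (levels switch at the
transition, so recovered times are exact to the frame on noise-free
traces), segmentation errors, and density-dependent arrest. Passing
tests therefore demonstrate correctness of the *measurement* chain under
controlled noise, not robustness to every imaging artifact.

`gen_regulome()` places each region class in well-separated 4-kb slots so
the classification rules hold by construction, plants coverage folds that
clear the thresholds after the pseudocount (validated at generation
time), assigns matching expression signs to enhancer targets, and embeds
E-box copies in promoter sequences. `gen_if_table()` draws DAPI from a
two-component normal mixture (2N/4N modes 0.08/0.16, CV 0.1) with
log-normal markers. `gen_coloc_pair()` uses a bivariate normal field with
the target correlation, shifted five SDs above zero so the non-negativity
clamp is inert.

All generators run under a single seed (`withr::with_seed`), and
identical config plus seed gives byte-identical output.

## Orchestration

`run_scenario()` reads a YAML config, runs the requested branches
(generate → call → summarize; regulome; imaging), writes every table as
CSV/TSV/BED/FASTA, and records a manifest (config MD5, seed, version,
per-stage counts, file list). The packaged `inst/scripts/fucci-run.R` is
a thin shell wrapper over this function. Validation problem sizes — 77
and 100-cell trace cohorts, a 25-region regulome, 2 000–4 000-cell IF
tables, 10⁴-pixel image pairs, 2 000 Welch null replicates — were chosen
so each check exercises the estimator well inside its asymptotic regime
while the whole suite remains quick to run at a desk.

## Known limitations

* Thresholds are cohort-level; per-cell threshold drift is not modelled
  (the equivariance property makes global gain harmless, but slow
  per-cell drift would need detrending upstream).
* Cells are timed over their first observed cycle only; second cycles
  and lineage effects are ignored.
* The antimode rule needs a genuinely bimodal pooled distribution; fully
  arrested cohorts must use manual thresholds.
* The regression is plain OLS; with measurement error in the G1/S time
  the slope is mildly attenuated (harmless here, where x-error is at
  most one frame against an SD of hours).
* Incomplete cells are dropped rather than censored; survival-style
  estimators for transition-time distributions are out of scope.
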