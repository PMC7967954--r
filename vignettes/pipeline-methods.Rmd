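---
title: "Models and methods: attentional modulation under local pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: attentional modulation under local pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnpharm)
```

## The scientific setting

A direction-selective extrastriate neuron is recorded while a subject performs
a cued spatial-attention task: on each trial a brief static cue (150 ms after
a 150 ms fixation delay, followed by a 350 ms inter-stimulus interval) directs
attention either into the neuron's receptive field (attend-in), to the
opposite hemifield (attend-out), or to the fixation point itself (attend-fix);
a fixation-only condition shows no motion stimulus at all. The animal reports
a small direction change that occurs 200-2500 ms after stimulus onset; on
one in ten trials no change occurs (catch trials, rewarded for withholding).

During a session a substance (a cholinergic agonist or antagonist, or saline)
is pressure-injected near the electrode roughly once per minute for part of
the session. The session therefore decomposes into a **control block** (trials
before the first injection), an **injection block** (from the first trial more
than 150 s after the first injection until 150 s after the last one), and a
**recovery block**. Trials in the 150 s gap after the first injection are a
transition period and enter no analysis.

Two indices quantify modulation of the firing rate $R$, averaged in a
300-800 ms window after stimulus onset:

$$\mathrm{AMI} = \frac{Q_2 - Q_1}{Q_2 + Q_1}, \qquad
  \mathrm{IMI} = \frac{R_2 - R_1}{R_2 + R_1},$$

where $Q_1, Q_2$ are the attend-out and attend-in mean rates within a block
and $R_1, R_2$ the control- and injection-block mean rates within a
condition. Both convert to an equivalent percent rate change via
$\mathrm{perc} = 2x/(1-x) \times 100$, which equals $100\,(Q_2/Q_1 - 1)$ —
an algebraic identity unit-tested in the package. Under a multiplicative
attention gain $g$ on a common baseline, $\mathrm{AMI} = (g-1)/(g+1)$.

The central question the pipeline answers is whether the injected substance
changes the *magnitude of attentional modulation*: a two-sided Wilcoxon
signed-rank test on the paired per-cell differences
$\mathrm{AMI}_{\text{injection}} - \mathrm{AMI}_{\text{control}}$, run within
subgroups of cells whose sensory response the substance demonstrably
increased or decreased.

## Pipeline structure

1. **Rates** — `window_rates()` counts spikes per trial in the half-open
   window [300, 800) ms after stimulus onset. Half-open intervals tile time
   without double counting; a spike exactly at 800 ms is excluded.
   `compute_psth()` provides trial-averaged histograms (default 10 ms bins,
   no smoothing); indices are always computed from raw window counts, never
   from smoothed histograms.
2. **Segmentation** — `assign_blocks()` applies the 150 s rule. The boundary
   is read strictly: the injection block starts *after* first injection +
   latency. Repeated injection cycles are segmented per cycle (a gap of more
   than twice the latency between injections starts a new cycle) and all
   injection-labelled trials are pooled downstream.
3. **Inclusion** — `check_criterion1()` requires (a) at least 3 trials per
   task condition in the injection block, (b) a mean preferred-stimulus rate
   of at least 7 spikes/s, and (c) a significant Kruskal-Wallis difference
   (p < 0.05) among the three control-block fixation conditions (preferred,
   null, fixation-only). `classify_injection_effect()` then labels each
   passing cell increase/decrease/none by a two-sided rank-sum test between
   control and injection attend-fix rates at the preferred direction.
4. **Indices** — `modulation_indices()` computes per-cell AMI per block and
   IMI per condition from unweighted means of per-trial rates.
5. **Population** — `summarize_population()` builds the result ladder:
   population IMI against zero, subgroup splits, per-subgroup AMI against
   zero in both blocks, the paired block comparison, and (when two subjects
   are present) a rank-sum check that their attentional modulation does not
   differ before pooling.

Only completed (hit) trials are analyzed by default: aborted trials are
repeated during acquisition, so they carry no usable response window.

## The synthetic session generator

Because raw recordings of this kind are not publicly deposited, the package
ships a generator (`generate_session()`) that emulates the task and injection
timeline with *known* ground truth, so every downstream stage is testable and
parameter recovery verifiable.

Spiking is homogeneous Poisson within each trial epoch (pre-stimulus at the
fixation-only rate; stimulus epoch at the condition rate), the simplest model
under which the attentional index has the closed form $(g-1)/(g+1)$. This is
a deliberate idealization: real responses have onset transients, adaptation,
non-Poisson count variance and rate drift. Passing recovery tests therefore
demonstrates correctness of the *analysis*, not realism of the cells.

Defaults encode the study conditions the pipeline is meant for:

* `baseline_rate = 20` spikes/s — a responsive direction-selective cell,
  comfortably above the 7 spikes/s inclusion floor.
* `attention_gain = 1.25` — index 0.111, i.e. a 25% enhancement, in the range
  reported for sustained spatial attention in extrastriate cortex.
* `null_rate = 8`, `fix_only_rate = 5` spikes/s — clear direction
  selectivity, so the sensory Kruskal-Wallis check has power at realistic
  trial counts.
* `injection_mixture = (0.18, 0.22, 0.60)` increase/decrease/unaffected —
  matching the reported pattern that roughly 40% of cells respond to a
  non-selective cholinergic manipulation, with slightly more decreases than
  increases; `injection_gains = (1.5, 0.6)` are a choice of clearly
  detectable but physiologically moderate effect sizes (no published effect
  size exists for the per-cell rate change).
* Injections once per minute (`injection_interval_s = 60`); 15 trials per
  condition per block, consistent with "at least 11" control repetitions.
* `catch_fraction = 0.1`, allocated as an exact floor proportion per
  condition rather than by coin flips, so a generated session hits one in
  ten exactly.

The drug effect is a step function: all rates of an affected cell are
multiplied by its injection gain from `first injection + 150 s` to
`last injection + 150 s`. No pharmacokinetics are claimed — published
concentration time-courses for this preparation are explicitly speculative —
so a declared step mirroring the block rule is used instead; with the default
latency and washout, effect period and block labels coincide, which makes
recovery tests exact.

The trial clock is laid out so that each block receives exactly the
configured trial count per condition: control trials, then the injection
train starting 2 s after the last control trial, a 150 s gap, the injection
trials (with injections continuing throughout), and recovery trials starting
one washout after the last injection. An explicit `injection_times` vector
switches to a free-running layout when a specific timeline must be tested.

All randomness flows from one seed; each cell uses a substream derived by a
stable string hash of its id, so datasets are byte-identical across runs and
insensitive to generation order.

## Statistical choices

All tests are two-sided and nonparametric: one-sample/paired Wilcoxon
signed-rank (statistic W, zeros dropped, mid-ranks for ties) and
Mann-Whitney rank-sum (statistic U). Exact p-values are computed for
samples up to n = 25 without ties, otherwise the normal approximation with
continuity correction is used; the test suite verifies exact agreement with
full enumeration of sign patterns and rank splits for n ≤ 8. The tests
delegate to `stats::wilcox.test()` / `stats::kruskal.test()`; the enumeration
oracles in the test suite are written independently. No multiple-testing
correction is applied — each test in the ladder is reported with its raw p,
matching standard practice for this analysis design.

Population percent modulation is reported two ways: the percent conversion
of the median index, and the median of per-cell percent values. The two
differ in general because the conversion is nonlinear, and published tables
are ambiguous about which aggregation they use; the package therefore
reports both and asserts neither as canonical.

Degenerate inputs are handled explicitly: an index is undefined (error, or
`NA` in table builders) when both rates are zero — such cells cannot pass the
responsiveness floor anyway; classification with fewer than 2 trials per
block returns "none" with a warning; an all-zero sample makes the signed-rank
test degenerate with p = 1 and a warning.

## Verification scales

The heavier simulation checks in the test suite run at fixed, seeded scales
chosen to make Monte-Carlo error small relative to the assertion margins:

* Gain recovery: 100 cells × 100 trials/condition at gains 1, 1.25, 1.5;
  the population-median control-block AMI must land within 0.02 of
  $(g-1)/(g+1)$ — about 8 standard errors of the median at this scale, and
  far less than the 0.089 separation between adjacent targets.
* Null calibration and power of the paired AMI test: 200 simulated
  populations of 12 cells × 15 trials/condition each; under the null
  (attention gain unchanged by injection, sign-mixed rate effects) the
  rejection rate must lie inside the 99.5% binomial interval around 0.05;
  with the attention gain raised 25% during injection it must exceed 0.9 —
  demonstrating the pipeline would have detected a true attentional effect
  of the substance had one existed.
* Type-I control of the injection classifier: 500 unaffected cells; the
  significant-classification rate must not exceed 0.05 plus ~2.6 binomial
  standard errors.

## Known limitations

* The generator's Poisson model has no onset transient, so synthetic PSTHs
  lack the early peak and cue response seen in real data; the analysis
  window logic is unaffected.
* Eye movements, reaction times and behavioral error structure are not
  modeled; non-hit outcomes exist only as an optional label fraction for
  testing the filters.
* The recovery block is labeled and reported but no quantitative recovery
  criterion is applied.
* Dose, volume and electrode-distance effects are retained as metadata in
  the interchange schema but not analyzed.
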