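# attnpharm

Analysis of single-unit recordings collected while a subject performs a
cued spatial-attention task and a substance (a cholinergic agonist or
antagonist, or saline) is pressure-injected next to the electrode. The
package is for electrophysiologists who want a tested, reproducible version
of the standard analysis chain for such experiments: trial-aligned firing
rates, segmentation of the session into control / injection / recovery
blocks, two-stage cell inclusion, modulation indices, and nonparametric
population statistics — plus a spike-train simulator with known ground truth
so the whole chain can be validated by parameter recovery.

## The quantities at the core

Firing rates are averaged per trial in a 300–800 ms window after stimulus
onset. Two normalized indices quantify modulation:

- **Attentional modulation index**, per block:
  `AMI = (Q2 − Q1) / (Q2 + Q1)`, where `Q1`/`Q2` are the mean rates with
  attention directed out of / into the receptive field. A multiplicative
  attention gain `g` gives `AMI = (g − 1)/(g + 1)`.
- **Injection modulation index**, per condition:
  `IMI = (R2 − R1) / (R2 + R1)`, where `R1`/`R2` are the control- and
  injection-block mean rates.
- Both convert to an equivalent percent rate change:
  `perc = 2x / (1 − x) × 100`.

The injection block runs from the first trial more than 150 s after the
first injection until 150 s after the last one; earlier post-injection
trials are a transition period and are excluded. Cells enter the analysis
when they have ≥ 3 trials per condition in the injection block, respond at
≥ 7 spikes/s to the preferred stimulus, and discriminate the three sensory
fixation conditions (Kruskal–Wallis, p < 0.05). Cells whose attend-fix rate
the substance significantly increased or decreased (two-sided rank-sum,
p < 0.05) form the subgroups on which the paired control-vs-injection AMI
comparison — the question of interest — is run.

## Worked example

Simulate 30 cells under the default study conditions (attention gain 1.25;
40% of cells affected by the injection, sign-mixed) and run the ladder:

```r
library(attnpharm)

cfg <- generator_config(n_cells = 30, trials_per_condition_per_block = 15)
s   <- generate_session(cfg, seed = 2)

rt <- window_rates(s$trials, s$spikes)          # per-trial rates, 300-800 ms
rt$block   <- assign_blocks_all(s$trials, s$injections)
rt$subject <- sub("-.*$", "", rt$session_id)

inc <- inclusion_report(rt)                      # criteria 1 and 2
idx <- modulation_indices(rt)                    # per-cell AMI / IMI
pop <- summarize_population(idx, inc)
cat(population_report(pop, "scopolamine"), sep = "\n")
```

Output:

```
## Population results: scopolamine

Control-block AMI compared between subjects O and P: U = 123, p = 0.683; data were pooled.

### Subgroup: all (N = 30)
- median IMI (attend-fix) = 0.021 (4.33%), W = 225, p = 0.88
- control block: median AMI = 0.111 (25.1%), W = 434, p = 3.0e-06
- injection block: median AMI = 0.120 (27.2%), W = 463, p = 2.2e-06
- paired AMI comparison (injection - control): W = 236, p = 0.951

### Subgroup: increase (N = 6)
- control block: median AMI = 0.114 (25.7%), W = 15, p = 0.0625
- injection block: median AMI = 0.105 (23.4%), W = 21, p = 0.0313
- paired AMI comparison (injection - control): W = 9, p = 0.844

### Subgroup: decrease (N = 7)
- control block: median AMI = 0.124 (28.3%), W = 28, p = 0.0156
- injection block: median AMI = 0.071 (15.4%), W = 26, p = 0.0469
- paired AMI comparison (injection - control): W = 6, p = 0.219
```

Reading it: attention reliably enhances firing (control-block median AMI
0.111 ≈ the 25% gain built into the simulation; p against zero ≪ 0.001).
The substance shifts rates up in some cells and down in others, so the
population-median IMI sits near zero. Crucially, the paired AMI comparison
is non-significant in every subgroup: the injected substance moved firing
rates without changing the magnitude of attentional modulation — exactly the
structure the generator embodies, since its injection gain multiplies all
conditions equally.

The same analysis runs end-to-end from CSV inputs or a YAML config via
`run_pipeline()`, which writes `inclusion_report.csv`, `indices.csv`,
`population_results.csv`, PSTH tables, a markdown report, and a run log
that reproduces the run (config, seed, package version). A thin CLI wrapper
with `simulate` / `validate` / `analyze` / `report` subcommands is in
`inst/cli/attnpharm.R`.

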