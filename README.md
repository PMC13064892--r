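# centroquant

Quantification machinery for centromere protein dynamics in single
cells. Centromere (CCAN) proteins such as CENP-C and CENP-T appear as
~46 diffraction-limited foci per interphase nucleus; comparing their
levels across conditions — cycling cells versus quiescent (G0) cells,
or cells re-entering the cell cycle — requires a per-cell,
background-adjusted intensity statistic, careful replicate-level
inference, and a way to classify which cells have passed through
S phase. `centroquant` implements that pipeline together with a
synthetic-data generator with known ground truth, so every stage is
testable without any imaging data.

## What it computes

**Per-cell foci intensity.** Nuclei are segmented on the DNA channel
(Gaussian smoothing, Otsu threshold, hole filling, 8-connected
labelling). Foci are detected on a reference (ACA) channel with a
scale-normalized Laplacian-of-Gaussian filter, subpixel-refined local
maxima and minimum-separation suppression — the reference channel marks
centromeres even when the target protein is gone. At each focus the
target channel is measured as

> adjusted intensity = mean(disk r = 3 px) − median(annulus 4–7 px, clipped to the nucleus, other foci excluded)

and the per-cell value is the unweighted mean over that cell's foci.
All quantification runs on unprocessed maximum-intensity projections.

**EdU gating.** Per-cell mean nuclear EdU intensity is fit with a
two-component Gaussian mixture (EM); the positivity threshold is the
smallest value on a grid between the component means that the
posterior assigns to the high component. For weights w₁/w₂, unit
variances and means 0 and 6 the threshold solves
w₁·φ(x) = w₂·φ(x−6), e.g. (18 + ln 9)/6 ≈ 3.366 for w₁ = 0.9.

**Superplot statistics.** Per-cell values are normalized to a reference
condition within each replicate, averaged per (condition, replicate),
and compared with Welch's unpaired two-tailed t test on the replicate
averages:

> t = (x̄_A − x̄_B) / √(s²_A/n_A + s²_B/n_B), Welch–Satterthwaite df.

**Live traces.** Time-lapse centromere traces are snapped to a common
timebase (no interpolation), aligned to mitotic entry (t = 0) on a
±12 h window, and summarized as pre-mitosis (trace start → entry) and
post-mitosis (exit + 1 h → end) means, daughters contributing to the
parent's post window.

**qPCR.** ΔCt against a housekeeping gene per sample, fold change
2^−ΔΔCt per biological replicate, transcription-shutoff decay courses
vs the 0-h value, and an optional log-linear half-life fit.

## Worked example

```r
library(centroquant)
cfg <- default_run_config()   # cycling (1.0x) vs quiescent (0.25x),
                              # 3 replicates x 3 fields x 12 cells
res <- run_pipeline(cfg, out_dir = "demo_run")
res$rep_means
res$comparisons[, c("condition_a", "condition_b", "t", "df", "p")]
```

```
[centroquant] simulate: 2 conditions x 3 replicates x 3 fields
[centroquant] quantify: 216 cells, 9936 foci from 18 fields
[centroquant] gate: threshold 212, 48.61% EdU-positive overall
[centroquant] stats: 6 replicate means, 1 pairwise comparisons
  condition replicate mean_value n_cells
1   cycling         1      1.000      36
2   cycling         2      1.000      36
3   cycling         3      1.000      36
4 quiescent         1      0.253      36
5 quiescent         2      0.250      36
6 quiescent         3      0.250      36
  condition_a condition_b   t df        p
1     cycling   quiescent 684  2 2.14e-06
```

The simulated quiescent target amplitude is 0.25× cycling; the pipeline
recovers normalized replicate means of ~0.25 (the cycling reference is
exactly 1 by construction), and the replicate-level Welch test is
strongly significant. The EdU gate on the same cells calls 96.3% of
cycling and 0.9% of quiescent cells positive (simulated truth: 95% and
0.2%). `run_pipeline()` writes `cells.csv`, `foci.csv`,
`replicate_means.csv`, `comparisons.csv`, `gate_report.yaml` and a
`manifest.yaml` that reproduces the run exactly.

A command-line front end with `simulate`, `quantify`, `gate`, `trace`,
`qpcr`, `stats` and `run` subcommands is installed at
`system.file("cli", "centroquant.R", package = "centroquant")`.

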