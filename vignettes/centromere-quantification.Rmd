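---
title: "Quantifying centromere foci dynamics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centromere foci dynamics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroquant)
```

## The measurement problem

Centromeres appear in fluorescence microscopy as ~46 diffraction-limited
foci per human interphase nucleus. The quantity of interest is the
amount of a target centromere protein (a CCAN subunit such as CENP-C or
CENP-T, or GFP-CENP-A) at those foci, compared across conditions such as
cycling versus quiescent cells, where the target can drop to a fraction
of its cycling level (CENP-C plateaus near one quarter) or vanish
entirely (CENP-T). Because the target itself may be absent, foci are
located on an independent reference channel (anti-centromere antibody,
ACA) and the target channel is measured at those reference-defined
positions.

The per-cell statistic is the arithmetic mean, over all detected foci in
a nucleus, of the background-adjusted target intensity at each focus.
Hypothesis tests are never run on pooled cells: cells within a
biological replicate share staining and imaging conditions and are not
independent, so per-cell values are averaged per replicate and Welch's
unpaired two-tailed t test is applied to those replicate averages (the
"superplot" convention).

## The generative model behind the simulator

Every downstream stage is validated against `generate_field()`, which
renders what the measurement model assumes:

* nuclei are non-overlapping disks (radius 21–25 px by default) filled
  at a constant DNA-channel amplitude;
* each focus is an isotropic 2-D Gaussian of sd `spot_sigma` (default
  1 px, the diffraction-limited spot width at a high-NA 60x objective
  with ~0.1 µm pixels), evaluated at pixel centres, with peak amplitude
  `channel_amplitudes` scaled per condition;
* the background is uniform plus a linear ramp (default 100 photons +
  0.02 photons/px), emulating uneven illumination;
* photon shot noise is Poisson per pixel, followed by additive Gaussian
  camera read noise (sd 3);
* the optional EdU channel is filled uniformly inside each nucleus at a
  per-cell level drawn from a two-class lognormal mixture (Gaussian on
  log intensity, since fluorescence intensities are right-skewed):
  negative cells around 50, positive cells around 500, both with
  log-sd 0.35. The positive fraction is condition-dependent (defaults
  0.95 cycling, 0.002 quiescent, matching a 48-h labelling window).

Foci are placed by rejection sampling inside 0.9 of the nucleus radius
with a minimum pairwise separation of `4 * spot_sigma`. At 46 foci this
is a dense packing; the geometry (region radius at least ~19 px) was
chosen so placement succeeds reliably, and the generator fails loudly
rather than silently relaxing the separation.

What the simulator deliberately omits: 3-D point-spread functions,
photobleaching, stage drift, chromatic shift, clumped or overlapping
nuclei, and mitotic cells. Passing tests therefore demonstrate that the
measurement machinery is correct under the stated noise model, not that
it is robust to every artefact of real microscopes; on real data the
segmentation and detection parameters are the knobs that absorb those
differences.

## Quantification pipeline

All fixed-cell quantification runs on unprocessed maximum-intensity
projections (`max_project()`); deconvolved data are never quantified.

**Segmentation** (`segment_nuclei()`): Gaussian smoothing (sd 2 px),
global Otsu threshold on the rescaled image (a fixed threshold is
available), hole filling, removal of objects under `min_area` (200 px)
and of border-touching objects, then 8-connected labelling. No
watershed splitting is attempted: the simulator guarantees separated
nuclei and clumped real data are out of scope.

**Detection** (`detect_foci()`): a scale-normalized
Laplacian-of-Gaussian response at `log_sigma` (default 1 px, matched to
the spot width). Candidates are 3x3 local maxima above `min_peak`
(default: response median + 8 robust sds — conservative enough that
pure noise yields no foci at the default imaging settings). Each
candidate is refined to subpixel precision by separable parabolic
interpolation *before* the minimum-separation test, so that two spots
whose true distance exceeds `min_separation` (default 3 px) are not
merged by rasterization; suppression is greedy from the strongest
response. Maxima outside segmented nuclei are discarded.

**Measurement** (`measure_foci()`): per focus, the mean target
intensity in a 3-px disk minus the median of a 4–7 px annulus clipped
to the focus's nucleus. Two details matter at centromere densities:

* *Neighbour exclusion.* At 46 foci per nucleus the annulus of one
  focus routinely contains the cores of neighbouring foci. Noise-free,
  the median ignores them; under shot noise their contribution smears
  into the annulus distribution and biases the background upward
  (empirically about −3 intensity units on the adjusted value, enough
  to distort a 0.25 condition ratio to 0.22). Pixels within
  `disk_radius` of any other detected focus are therefore excluded from
  background estimation (`exclude_neighbors = TRUE`), as in standard
  kinetochore-intensity protocols. A whole-nucleus median background is
  available as an alternative (`background = "nucleus"`).
* *No clipping.* Negative adjusted intensities are retained, so that
  condition means near zero (a lost protein) remain unbiased.

Cells with no usable focus keep their record with a missing mean — they
are absent cells, not zero-intensity cells.

## The EdU gate

S-phase passage is called from the per-cell mean nuclear EdU intensity
with a two-component Gaussian mixture fit by EM (`fit_gmm_em()`):
log-sum-exp responsibilities, initialization at the 25th/75th
percentiles (k-means and random available), a variance floor of 1e-6
of the data variance against singular collapse, and convergence when
the log-likelihood improves by less than 1e-8. The fit is on linear
intensity by default with a log-scale option matching the simulator's
lognormal components; the scale is recorded in the result. The gate is
fit on cells pooled across conditions — a per-condition fit is
impossible when one condition has essentially no positive cells.

The threshold is derived by scanning the maximum-posterior assignment
on a 1000-point uniform grid between the two component means
(`find_threshold()`); the threshold is the smallest grid value assigned
to the high component and is reported with its grid step. The grid is
restricted to between the means because, with unequal variances, the
posterior assignment can revert outside that interval; between the
means the crossing is unique. Against the analytic posterior-equality
root the grid value is accurate to one grid step (for weights 0.9/0.1,
unit variances, means 0 and 6, the closed form is (18 + ln 9)/6 ≈
3.366). Cells at exactly the threshold classify positive; the direction
is arbitrary but fixed for determinism.

## Live-cell traces

Time-lapse traces (per-timepoint mean intensity over up to 10
centromeres per cell, background-adjusted) are handled without any
interpolation. `resample_timebase()` snaps observations to the nearest
mark of a common grid (default 5 min), keeping the nearer observation
on collisions; missing marks stay missing. `align_to_mitosis()` sets
t = 0 at mitotic *entry* and aggregates the across-trace mean and SD on
a ±12 h window; mitosis itself is a measurement gap (default 30 min),
because foci are not followed as a per-cell average during chromosome
congression. `pre_post_mitosis_means()` anchors the post window at
mitotic *exit* plus 1 h (closed on the left: an observation at exactly
exit + 1 h is included), the pre window at trace start up to (open)
entry. Daughters inherit the parent's clock; to avoid double-weighting
divided cells, a parent's post value is the mean of its daughters'
post-window means. Traces are treated as globally normalized (to the
cycling level) rather than per-trace normalized, preserving the pre- to
post-mitosis level difference that is the quantity of interest.

## qPCR fold changes

`delta_ct()` averages technical replicates on the cycle scale, then
subtracts the housekeeping (GAPDH) Ct per sample, cancelling
per-sample offsets such as input amount. `fold_change()` computes
2^−ΔΔCt per biological replicate *before* averaging (mean ± SD across
replicates); amplification efficiency is fixed at 2 and no efficiency
calibration is attempted. `decay_course()` expresses each
transcription-shutoff timepoint as fold of the same condition's 0-h
value and can optionally fit ln(fold) against time for a first-order
decay rate and half-life — the fit is an extension beyond plotted fold
changes and is labelled as such.

## Replicate statistics

`normalize_to_reference()` divides per-cell values by the reference
condition's mean, by default within each replicate so that
between-replicate staining efficiency cancels; the normalized reference
then averages to exactly 1. The mean (not the median) is the reference
statistic precisely so that this identity holds; a median option exists.
`welch_t_test()` requires at least two replicate values per group and
refuses degenerate zero-variance input; all pairwise condition
comparisons are reported with raw per-comparison p values — no
multiple-testing correction, matching the per-comparison reporting
convention the pipeline mirrors. `intensity_edu_regression()` is an
ordinary least-squares fit of per-cell centromere intensity on per-cell
nuclear EdU intensity, both normalized within replicate, reporting
R² = 1 − SS_res/SS_tot.

## Numerical and design choices

* Coordinates are 0-based (row, col); spot centres are real-valued and
  rendering evaluates Gaussians at pixel centres. No physical pixel
  calibration is required anywhere.
* TIFF output is 32-bit float, scaled to [0, 1] with the scale and
  offset recorded in a YAML sidecar; round trips are exact at single
  precision (~1e-7 relative).
* Determinism: every generator takes a seed and identical seeds give
  bit-identical outputs; `run_pipeline()` derives per-field seeds from
  the run seed, and reruns with one config write byte-identical tables.
* Problem sizes: the default study design is 2 conditions × 3
  replicates × 3 fields of 12 cells (448 × 448 px, single z plane, 46
  foci/cell), i.e. 36 cells per condition per replicate — large enough
  that condition ratios and replicate-level tests are stable, small
  enough to run interactively. The generic field default keeps a 3-plane
  stack so projection is exercised; the study design uses one plane
  since quantification only ever sees projections.
* Known limitations: no 3-D detection; no chromatic-shift correction;
  no tracking of cells across live frames (traces arrive pre-linked);
  touching nuclei are not split; the mixture gate assumes exactly two
  populations.
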