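---
title: "In-silico synchronization and cell-cycle scoring: models and choices"
author: "protcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico synchronization and cell-cycle scoring: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protcycle)
```

# The measurement model

The package analyses movies of cells in which one protein is fluorescently
tagged at its endogenous locus (the "yellow" channel) and a constitutive
marker fills nucleus and cytoplasm (the "red" channel, used only for
segmentation). Three per-cell, per-frame quantities drive everything
downstream:

* **total fluorescence** — background-subtracted yellow summed over the
  cell mask, a proxy for protein copy number;
* **nuclear ratio** `NR` — the same sum over the nucleus mask divided by
  the cell total, in `[0, 1]`;
* **texture** — four Haralick summaries (contrast, energy, homogeneity,
  correlation) of the gray-level co-occurrence matrix (GLCM) of the yellow
  pixels inside the cell mask, sensitive to localization changes that the
  nucleus/cytoplasm split cannot see (spindle association, granularity,
  punctae).

A median-pixel variant of the level (a concentration rather than copy
proxy) is carried through the same path as the quantity `median_pixel`;
it is noisier than the summed total and is scored with the same 0.3
threshold.

# In-silico synchronization

Movies cover ~24 h but cycles last about 21 ± 4 h, so most cells are seen
for only part of a cycle. Rather than perturbing cells into synchrony
chemically, each cell is synchronized *in silico*: divisions are detected
from the exact twofold drop of total fluorescence between consecutive
frames (`detect_divisions()`, ratio within a ±25% band around 2, optionally
gated on the mitotic rounding of the cell, eccentricity < 0.6), and each
observation is mapped to a cycle fraction:

* after a division: `tau = (t - t_div) / T_cc`;
* before a division: `tau = 1 - (t_div - t) / T_cc`;
* between two observed divisions: exact rescaling
  `tau = (t - t_div1) / (t_div2 - t_div1)`, which takes precedence.

Points falling outside `[0, 1]` are dropped; cells with no observed
division cannot be placed and are excluded. `T_cc` defaults to 21 h and is
configurable; conclusions are insensitive over roughly 18–23 h.

**Mitosis normalization.** Level traces are made dimensionless per cell by
dividing by the value at the last frame before the cell's first observed
division. Cells observed only after their division use twice the first
post-division value instead — the twofold-drop identity makes the two
anchors equivalent up to noise. The normalization is per *cell*, not per
averaged profile; for noise-free data the two conventions coincide, and
for noisy data the per-cell form keeps each cell's anchor error local to
that cell rather than correlating the whole profile.

**Profiles.** Synchronized points from all cells and fields of view of one
protein are averaged in `n_bins = 50` equal τ-bins. At 20-min sampling and
a 21-h cycle there are ≈ 63 frames per cycle, so 50 bins give ≈ 1 frame
per bin per cell without oversmoothing. Empty bins are filled by linear
interpolation and flagged.

# Scoring cell-cycle dependence

A protein with no program of its own still shows the universal growth
shape: a drop to one half at division and recovery to one by the next
division. The cohort-average profile `A(tau)` (unweighted bin-wise mean
over all proteins) carries exactly that shape — plus any systematic assay
artifact, such as the effect of mitotic rounding on fluorescence — so each
protein's profile is divided bin-wise by `A(tau)` and scored by its
deviation from the constant 1:

* `s90` — the 90th percentile of `|P/A - 1|`, tolerant of outlier bins;
* `rms` — the root-mean-square deviation, reported alongside.

Percentiles interpolate linearly between order statistics
(`stats::quantile` type 7). The convention is otherwise arbitrary, but the
bootstrap calibration below uses the same one, so classifications are
convention-consistent.

The nuclear ratio is **not** normalized by the cohort average: nuclear and
cytoplasmic proteins sit at entirely different NR baselines, so dependence
is variation around a protein's own mean — the population standard
deviation of the binned NR. Bins in the first and last 10% of the cycle
are excluded because nucleus and cytoplasm cannot be distinguished while
the cell rounds up and the nuclear envelope is down. The population
divisor (n, not n−1) makes a two-level step of height `a` score exactly
`a/2`.

Texture features are dimensionless, so they skip mitosis normalization but
follow the level path otherwise (cohort-average normalization, `s90`).

**Thresholds.** Classification uses strict inequalities at the study's
bootstrap-calibrated cutoffs: level 0.3, NR 0.08, contrast 0.4, energy
0.15, homogeneity 0.02, correlation 0.05 (`default_thresholds()`). These
constants are tied to the noise of the data they came from;
`bootstrap_threshold()` recomputes them for any cohort with replicate
movies: 100 random sets of 4 movies (the per-protein field-of-view count)
are drawn without replacement within a set from ≥ 40 replicates of a
non-cycling reference, each set is averaged, normalized by the
all-replicates average, and scored; the threshold is the 99% quantile of
the 100 scores. With several reference proteins the maximum threshold is
the conservative choice. No multiple-testing correction is applied beyond
the 99% confidence — the thresholds are deliberately stringent, so the
flagged fraction is an underestimate.

# The synthetic cohort

The generator is the package's test bed and defines the conditions every
claim is checked under:

* **Layout** — 4 fields of view per protein, 10–20 tracked cells each,
  24 h movies sampled every 20 min; cycle durations `N(21, 4²)` h
  truncated at 8 h; the starting cycle phase of each cell is uniform.
* **Growth law** — total fluorescence doubles exponentially over each
  cycle (`2^tau`), the simplest law consistent with gradual, slightly
  accelerating accumulation; the true per-cell form is not identifiable
  from the data this emulates, and this choice is a documented stand-in.
* **Division** — frame values are built recursively (per-frame growth
  factor `2^(dt/T)`), and the frame pair straddling a division steps down
  by an exact factor of 2 including the modulation term. A continuous law
  sampled on a 20-min grid would drop by `2^(1-dt/T)` ≈ 1.96 instead;
  the recursion keeps the halving exact, which is the identity the
  division detector and the post-division normalization fallback rely on.
  The cost is a drift of `2^(-dt/T)` ≈ 1% per cycle in the baseline,
  invisible after mitosis normalization.
* **Cell-cycle programs** — a raised-cosine bump of full width 0.3 cycle
  fractions (smooth, bounded, phase-parameterized, periodic so profiles
  are continuous across division), multiplying the level as
  `1 + amplitude · m(tau - peak)` and shifting NR additively with clipping
  to `[0, 1]`. Cycling cohort members draw their peak phase uniformly in
  `[0.15, 0.85]` so the NR bump is not generated inside the trimmed
  mitosis windows.
* **Noise** — multiplicative lognormal with CV 0.05 on total fluorescence
  (fluorescence noise scales with signal), additive Gaussian sd 0.02 on
  the observed NR, mean-corrected so neither biases the profile.
* **Censoring** — 20% of cells have their traces truncated at a uniform
  random frame, emulating cells that leave the field of view; partial
  traces are the regime in-silico synchronization exists for.
* **Images** — single-cell 64×64 tiles: the red channel is near-uniform
  over the cell with a 2× brighter nuclear core (the constitutive marker
  is denser in the nucleus; this is also what makes the secondary
  nucleus threshold identifiable) and Gaussian-blurred edges; the yellow
  channel distributes the trace's total fluorescence by program (nuclear /
  cytoplasmic / shuttling split by NR, uniform diffuse, or separated
  Gaussian punctae for texture tests), conserving the total exactly;
  optional Poisson shot noise at a configurable photon gain. One cell per
  tile with known identity — multi-cell tracking is out of scope by
  design.

What the generator does **not** emulate: photobleaching, flat-field
shading (background correction reduces to constant subtraction from
non-foreground pixels), cell death, cell–cell contact, shape change over
the cycle (rendered geometry is fixed; rounding enters only the
eccentricity column of traces), or texture programs that evolve within a
movie. Tests passing on this cohort therefore validate the *analysis
logic* — synchronization, normalization, scoring, calibration — not the
segmentation robustness needed for crowded, unevenly illuminated real
movies.

# Numerical and degenerate-case choices

* GLCM quantization is min–max within the mask into 8 levels (cells are
  small; coarse bins keep counts stable), so features are invariant to
  additive intensity shifts; constant regions map to level 0 and yield
  the analytic identities contrast 0, energy 1, homogeneity 1.
* The symmetric GLCM (each horizontal pair counted in both orders) is the
  default; correlation of a zero-variance marginal is defined as 0.
* A mask with no valid pixel pair at the offset is a degenerate-region
  error, not a silent zero.
* Division calls use the frame-interval midpoint; detection is therefore
  accurate to half a sampling interval.
* A non-positive mitosis anchor excludes the cell with a warning rather
  than propagating infinities.
* Scores require ≥ 10 bins; thresholds are strict inequalities, so a
  score exactly at the cutoff is non-cycling.

# Known limitations

* Phase smearing: anchoring single-division cells on a fixed 21-h axis
  while true cycles vary by ±4 h blurs narrow programs. For the NR score
  the attenuation is ≈ 35% for a width-0.3 bump, so an NR amplitude of
  0.3 scores ≈ 0.07 — just below the 0.08 cutoff; detectability sets in
  around amplitude 0.4 under these noise conditions. This mirrors the
  conservative character of the thresholds on real data.
* Cells with no observed division contribute nothing; no phase inference
  without an anchor is attempted.
* The texture path is validated on static rendered programs (punctate vs
  diffuse), not on programs that change within a movie; cohort-level
  texture classification is exercised only where texture columns are
  present in the trace table.

# Problem sizes used in the checks

The packaged checks run on cohorts of 30–50 proteins × 4 fields of view ×
10–20 cells (profile-shape, specificity and label-recovery checks), 48
replicate movies × 100 bootstrap sets (threshold calibration), and 10
rendered single-cell movies of 73 frames (the image path). These sizes
were chosen to put sampling error well inside the tolerances asserted
while keeping the default test run fast.
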