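# protcycle

Cell-cycle dependence of protein **level** and **localization** from
single-cell time-lapse fluorescence movies, without chemical
synchronization.

## The problem and the approach

In live-cell libraries where each clone carries one endogenously tagged
fluorescent protein, time-lapse microscopy follows protein level and
localization in individual cells over ~24 h. Movies rarely contain a full
cell cycle per cell (cycles last about 21 ± 4 h and cells wander out of the
field of view), so the package uses **in-silico synchronization**: division
events are detected from the sharp twofold drop in total fluorescence (and
optionally the rounding of the mitotic cell), and every measurement is
placed on a fractional cell-cycle axis τ ∈ [0, 1] anchored at those
divisions — `τ = (t − t_div)/T_cc` after a division, `τ = 1 − (t_div −
t)/T_cc` before one, and exact rescaling between two observed divisions
(default `T_cc` = 21 h).

Per protein, three families of cycle profiles are scored:

- **Level** `P(τ)`: each cell's total fluorescence, normalized by its value
  at mitosis, averaged into 50 τ-bins, then divided bin-wise by the
  cohort-average profile (which carries the common halve-then-double growth
  shape). The score is `S = Q90(|P(τ)/A(τ) − 1|)`, the 90th-percentile
  deviation from one (an RMS variant is reported alongside). Cycling if
  `S > 0.3`.
- **Nuclear ratio** `NR(τ)` = nuclear / total fluorescence. Score:
  standard deviation of the binned NR over mid-cycle (first and last 10%
  of the cycle excluded — the nuclear envelope is down around mitosis).
  Cycling if `std > 0.08`.
- **Texture**: four Haralick features of the per-cell gray-level
  co-occurrence matrix (contrast, energy, homogeneity, correlation),
  profiled and scored like the level. Cycling if any feature's score
  exceeds its cutoff (0.4 / 0.15 / 0.02 / 0.05).

Thresholds are calibrated by **bootstrap**: from ≥ 40 replicate movies of a
non-cycling reference protein, 100 random sets of 4 movies are averaged,
normalized and scored; the 99% quantile of those scores is the noise
threshold.

A first-class synthetic-data module (`simulate_cohort()`,
`render_cell_image()`) generates traces and two-channel cell images with
known ground truth (growth law doubling per cycle, exact twofold drop at
division, configurable level/localization programs, lognormal measurement
noise), so every stage — EBImage-based seeded-watershed segmentation,
measurement, division detection, synchronization, scoring — is testable end
to end.

## Worked example

```r
library(protcycle)

cfg <- run_config(mode = "simulate", out_dir = "out",
                  sim = sim_config(level_amplitude = 0.8, nr_amplitude = 0.4,
                                   localization_program = "shuttling"),
                  n_proteins = 20, fraction_cycling = 0.5, seed = 1)
res <- run_pipeline(cfg)
res$summary$counts
#>                      n                  level          nuclear_ratio
#>                     20                      7                     10
#>                texture           localization level_and_localization
#>                      0                     10                      7
#>                    any
#>                     10

head(res$scores[, c("protein_id", "s90_level", "nr_std", "peak_tau")], 4)
#>   protein_id s90_level     nr_std peak_tau
#> 1       P001 0.4067274 0.09319437     0.33
#> 2       P002 0.2951669 0.09663602     0.69
#> 3       P003 0.3244914 0.10348569     0.79
#> 4       P004 0.3322750 0.10430235     0.81
```

Of 20 simulated proteins, the 10 that carry a cell-cycle program are all
recovered (`any` = 10): 7 cross the level threshold `s90 > 0.3`, all 10
cross the nuclear-ratio threshold `std > 0.08`, and none of the 10
non-cycling proteins is flagged (recall 1, specificity 1 against the
generator's ground truth). `peak_tau` is the cycle fraction of each
protein's largest deviation from the average profile. The output directory
holds `traces.csv`, `profiles.csv`, `scores.csv`, `classification.csv`,
`summary.csv` and a reproducibility `manifest.yaml`.

A shell entry point wrapping the same pipeline ships in
`inst/scripts/protcycle-run.R`.

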