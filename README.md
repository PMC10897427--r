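# ipanr

Quantification and simulation of interplanar microtubule (MT) network
dynamics and coordinated mitosis in the two-layered *Drosophila* pupal wing.

## The problem

During the early inflation stage of pupal wing development, the dorsal and
ventral wing epithelia are connected across a 50–80 µm interepithelial gap
by a network of vertical, microtubule-based membrane protrusions (the
Interplanar Amida Network, IPAN). Programmed disassembly of this network
releases interepithelial cell–cell contacts, which in turn releases cells
from G2 arrest: over a four-hour live-imaging window, interepithelial MT
signal decays while mitoses accumulate in both layers in a tightly
coordinated fashion. `ipanr` is for researchers who want to quantify this
process in two-channel 4D time-lapse volumes (a tubulin channel plus a
pericentriolar-material channel) and to validate every analysis stage on
ground-truthed synthetic data.

The package provides:

* **The interepithelial MT ratio.** Per frame, the z-profile of mean
  intensity is computed, the dorsal and ventral layer peaks `(z_d, I_d)`
  and `(z_v, I_v)` are found by a constrained dual argmax (dorsal among
  the first `3·dallow` slices, ventral from `z_d + h_expected` down), and
  the statistic is `r = 2·I_int / (I_d + I_v)`, with `I_int` the mean over
  the inclusive slice window `[z_d + margin, z_v − margin]` (defaults:
  `dallow = 10`, `h_expected = 25`, `margin = 10` slices of 1.0409333 µm).
* **Automated mitosis counting.** Blob detection of pericentriolar (Cnn)
  foci, closest-first pairing within a spindle length, spindle-bar
  confirmation in the tubulin channel, layer assignment by depth, and
  cross-frame linking into one-shot events with monotone cumulative
  per-layer counts. Plus per-cell apical MT focus counting (~30/cell).
* **A synthetic experiment generator.** An agent-based contact-loss-gated
  mitosis model (per-pair hazard `λ0·max(m_d, m_v)` after a ramp time,
  Gamma-delayed mitotic onset, at most one division per cell,
  cell-autonomous G2/M blocks) rendered into OME-TIFF volumes with depth
  attenuation/compensation, PSF blur and Poisson noise, with full ground
  truth. Presets cover the control plus hTau, Kat60, patronin, shot, stg
  and polo perturbations of either or both layers.
* **Replicate reports**: per-run summaries, dorsal–ventral coordination
  scores, and five-replicate scenario reports with percentile-bootstrap
  95% CIs, as tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate the default control experiment (350 cells per layer, 48 frames at
5-minute intervals) and summarise one run:

```r
library(ipanr)

s <- run_scenario("control", seed = 1)
s
#> <ipan_run_summary> control (seed 1): final D=100 V=100 (28.6% / 28.6% divided),
#>   onset D=110 V=110 min
```

One hundred dorsal and 100 ventral cells divided in this replicate (28.6%
of each layer), with the first mitosis at 110 min — mitoses start around
two hours into the window and reach on the order of a hundred per layer,
about a third of the cells, by four hours.

Run the five-replicate convention and report means with bootstrap CIs:

```r
rep <- run_full_experiment("control", seeds = 1:5)
tidy(rep)
#> # A tibble: 9 × 5
#>   metric                mean   ci_lo   ci_hi     n
#>   <chr>                <dbl>   <dbl>   <dbl> <int>
#> 1 coord_max_abs_diff   8.4     7.4     9.8       5
#> 2 coord_pearson_r      0.998   0.997   0.999     5
#> 3 final_dorsal       114.    107.    120.        5
#> 4 final_ventral      111.    105.    115.        5
#> 5 frac_dorsal          0.325   0.301   0.342     5
#> 6 frac_ventral         0.318   0.301   0.329     5
#> 7 onset_min_dorsal   114     110     120         5
#> 8 onset_min_ventral  113     111     115         5
#> 9 ratio_slope        NaN      NA      NA         0
```

Across replicates ~32% of cells divide per layer (≈110–115 mitoses), the
dorsal and ventral cumulative curves never differ by more than ~8 cells
(Pearson r ≈ 0.998 — the coordination the model encodes), and onsets sit
near 113 min. `ratio_slope` is only defined when a volume is rendered and
quantified; add `render = TRUE` to run the full image pipeline
(render → interepithelial ratio → detection) instead of the ground-truth
fast path, and `out_dir = "runs/ctrl1"` to write the OME-TIFF volume,
event CSVs, six-column profile table and a checksummed manifest.

```r
cfg <- scenario_config(n_cells_per_layer = 30, roi_px = c(40, 80))  # renders in seconds
s <- run_scenario(cfg, seed = 1, render = TRUE)
plot_ratio_timeseries(s$ratios)   # monotone decay of interepithelial MTs
autoplot(s)                       # dual mitosis curves + ratio overlay
```

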