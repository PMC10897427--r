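---
title: "Quantifying interplanar microtubule dynamics and coordinated mitosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interplanar microtubule dynamics and coordinated mitosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipanr)
```

## The biological system and the model

The developing *Drosophila* pupal wing consists of two apposed epithelial
sheets - dorsal and ventral - separated by an interepithelial gap of
roughly 50-80 µm. During the early inflation stage the two layers are
physically linked by an interplanar network of vertical, microtubule-based
membrane protrusions (the Interplanar Amida Network, IPAN), nucleated by
non-centrosomal microtubule-organizing centers whose minus-end foci sit
medioapically (~30 foci per cell). Over a four-hour window this network is
programmatically disassembled: protrusions bundle and regress, interepithelial
cell-cell contacts are lost, and cells - until then held in G2 arrest - enter
mitosis. Because the contacts couple the two layers, mitosis is tightly
coordinated between them, even though the G2/M transition itself executes
cell-autonomously.

`ipanr` packages three things around this system:

1. **A quantification statistic.** The interepithelial microtubule ratio
   summarises, per 3D frame, how much tubulin signal sits in the gap between
   the two layers relative to the layers themselves.
2. **An automated mitosis counter** reproducing manual counting criteria
   (cell rounding/spindle in a tubulin channel plus two pericentriolar
   Centrosomin foci) as a deterministic detector.
3. **A synthetic experiment generator** that embodies a contact-loss-gated
   mitosis model and renders ground-truthed two-channel 4D volumes, so the
   full pipeline is testable without microscope data.

## The interepithelial ratio statistic

For each frame, every z slice is averaged over (y, x) to give a z-profile
of mean intensity. The dorsal layer position $z_d$ is the brightest slice
among the first $3 \cdot d_{allow}$ slices (default $d_{allow} = 10$); the
ventral position $z_v$ is the brightest slice at or below
$z_d + h_{expected}$ (default 25 slices, half of the expected ~50 µm gap).
Ties break toward the more apical slice. With peak intensities $I_d$ and
$I_v$ and the mean $I_{int}$ over the inclusive slice window
$[z_d + m,\; z_v - m]$ (margin $m = 10$ slices), the statistic is

$$ r = \frac{2\, I_{int}}{I_d + I_v}. $$

All indices are in z-slice units of 1.0409333 µm (the acquisition z-step).
Slice indices are 1-based apical-to-basal in this package; offsets, window
inclusivity and tie-breaking match the 0-based reference semantics
exactly. $r$ is exactly 1 on a uniform profile, 0 when the window is empty
of signal, invariant to rescaling all intensities by a positive constant,
and *not* invariant to additive offsets (documented, not corrected).

Numerical choices:

* Arithmetic is in double precision. A `quantize_uint8` compatibility
  switch truncates intensities to unsigned 8 bit before profiling,
  reproducing legacy workflows that cast raw data; it is off by default
  because quantization is an implementation detail, not part of the
  statistic. On 8-bit integer input both paths agree identically.
* Lateral downsampling to 5 x 10 block means (the memory-saving step of
  the reference workflow) partitions each image as evenly as possible,
  folding remainder pixels into the final block along each axis; the
  reference implementation of this step is not public, so this dialect is
  explicit here. When blocks tile the image evenly the z-profile is
  unchanged by downsampling (mean of means), so the statistic is identical
  with or without it.
* The margin can be given in micrometres (`margin_um`); it converts to
  slices by the z-step with half-up rounding.
* Degenerate geometries (profile shorter than the dorsal search range,
  empty ventral search range, empty window, all-zero peaks) raise typed
  errors rather than producing silent NaN.

## The synthetic experiment generator

### Study conditions (defaults)

The default configuration reproduces the reference control experiment:
48 frames at 5-minute intervals (4 h, nominally from 10.5 h after
puparium formation at 29 °C), 350 cells per layer in the region of
interest (the reference reports 300-400), a flat dorsal layer at 10 µm
depth, a ventral layer slanting from 62 to 80 µm across the ROI (the
ventral epithelium recedes from the objective distally; mitoses there
span a thicker optical band), a 1.0409333 µm z-step over 85 slices, and
~30 apical foci per cell (Poisson). The ROI is 60 x 120 px at 1 µm/px,
giving a mean cell spacing of ~4.5 µm, matching the small apical domains
of the proximal wing.

### Contact-loss-gated mitosis

Cells are placed on jittered grids and paired with their nearest
opposite-layer neighbours (union of the choices from both sides, so
contacts are not strictly one-to-one; interepithelial contacts in the
tissue are mediated by protrusion branches touching several cells).
Each contact pair carries a loss hazard

$$ \lambda(t) = \lambda_0 \cdot \max(m_d, m_v) \cdot \mathbf{1}[t > t_{ramp}], $$

where $m_d, m_v$ are the layer perturbation rate modifiers. Taking the
maximum of the two layers' modifiers encodes the observed rescue: when one
layer is wild type, disassembly and contact release proceed essentially
normally even if the other layer is compromised. Upon pair loss both
partner cells leave contact; each draws a delay
$\tau \sim \Gamma(\text{shape} = 2, \text{mean} = 20\ \text{min})$ and
becomes mitotic at $t_{loss} + \tau$ for 15 min, then divided - at most
once per cell. Cells of a layer carrying a G2/M-blocking perturbation
(*stg*, *polo*) become G2-blocked instead; the block is cell-autonomous.
Contact-abolishing perturbations (*Kat60*, *shot*) prevent contact
formation outright for **both** layers (the intact layer alone cannot form
the complexed contact structure), so no cell is ever released by contact
loss. The loss hazard is realised on the 5-minute acquisition grid; the
implementation draws the piecewise-exponential loss time and snaps it up
to the grid, which has exactly the law of the per-step Bernoulli
discrete-time model.

Calibration: the ramp start (100 min) and
$\lambda_0 = 0.0035\ \text{min}^{-1}$ are free constants tuned once so
that, under the defaults, first mitoses appear around frame 24 (~120 min)
and roughly a third of cells divide by 240 min, the reference control
measurements (first mitoses ~120 min; ~100-150 mitoses and ~30-35% of
cells per layer by 4 h). The reference reports no quantitative
disassembly kinetics, so these two constants are calibration choices, not
measured values. Rate modifiers default to 1 (control), 0.25 (*hTau*
stabilisation, strong slow-down) and 0.5 (*patronin* knockdown, delayed
disassembly); the *patronin* magnitude is likewise a free calibration
constant chosen to reduce both-layer mitoses clearly below control while
remaining nonzero. *stg* and *polo* are modelled identically - their
biology differs, their count-level outcome does not.

### Rendering and optics

The tubulin channel renders the two layer slabs (half-width 2.5 µm), one
vertical interepithelial column per contacting cell (removed at contact
loss - so the true interepithelial signal is non-increasing in time for
control runs), aggregated apical focus intensity per cell (the per-cell
focus count decays linearly to zero over 30 min after contact loss and is
zero from mitotic onset), and a 4 µm spindle bar during mitosis. The cnn
(pericentriolar material) channel renders two point foci at the spindle
poles during mitosis only - the two-focus criterion used for manual
counting. Optics apply in order: depth attenuation $e^{-\alpha z}$ with
acquisition compensation gain $e^{+\beta z}$ (defaults
$\alpha = \beta = 0.01/\mu m$, i.e. full compensation, emulating the
hardware z-compensation of the reference protocol), isotropic Gaussian
blur ($\sigma = 0.8$ µm), and Poisson noise on background (5 counts) plus
signal. A separate apical render draws the individual foci of the dorsal
layer at 0.2 µm/px with a 0.15 µm PSF and a minimum focus separation of
0.5 µm inside a 2.2 µm apical disk, with the ground-truth cell mask.

### What the generator does and does not emulate

It emulates: the two-layer geometry with slant, interepithelial columns
that disappear as contacts are lost, apical focus decay, spindle and
centrosome-foci mitotic figures, depth attenuation/compensation, PSF blur,
and shot noise. It does not emulate: bundling dynamics and the
higher-order interepithelial basement (bundle fates are observational in
the reference; only contact loss gates mitosis in the model), lateral
filopodia, hinge contraction, trachea/hemocytes, the midleg (so no leg
exclusion is needed), real cell segmentation, or mechanical tissue
deformation. Passing tests therefore demonstrate correctness of the
pipeline on data with known geometry and noise - they do not certify
performance on real volumes, where background structure, bleaching and
drift add failure modes the generator does not produce.

## Mitosis detection

Per frame, the cnn channel is searched for blobs by scale-space Gaussian
smoothing at 0.8 and 1.2 µm; local maxima above a robust threshold
(median + 6 MAD of the smoothed volume; in noise-free volumes, where the
MAD is zero, the fallback is the background median plus 10% of the peak
excursion) become focus candidates with sub-voxel centroids. Foci are
paired greedily, closest first, within 6 µm (about one spindle length);
greedy pairing was chosen over optimal matching because collisions are
rare at the observed event densities and the behaviour is deterministic.
A pair is confirmed only if the mean tubulin intensity along the
inter-focus segment exceeds twice the local background median (the
spindle-bar criterion); confirmation is on by default since both markers
were used jointly in the manual workflow. Mitotic cell *rounding* is not
used as a detection feature - the reference gives no quantitative
rounding criterion, and foci plus spindle suffice; this is a deliberate
divergence from the manual workflow.

Candidates are assigned to a layer by depth: dorsal within ±2.5 µm of the
dorsal z-profile peak (the ~5 µm optical slice of dorsal mitoses), ventral
within the ventral band. Because the ventral layer is slanted, a fixed
window around the single ventral peak slice would clip events at the
extremes of the slant; the pipeline instead estimates the ventral band per
frame as the region below $z_d + h_{expected}$ where the profile exceeds
half the ventral peak, padded by 2.5 µm. Candidates between the bands are
dropped.

Finally, candidates are linked across frames: a candidate within 5 µm of
an event whose latest detection is at most 3 frames old joins that event,
otherwise it opens a new one (mitotic figures are temporally contiguous;
without the gap rule, a later division of a close neighbour could be
swallowed by an earlier event). Events must be seen in at least 2 frames,
except events still visible in the final frame, whose persistence cannot
be observed - mirroring the counting convention in which each newly
arising mitosis is carried into every subsequent frame and the final
frame holds the total.

Apical focus counting max-projects the apical slab, smooths lightly,
finds local maxima above the same robust threshold, and counts them per
label of a supplied cell mask. At the full default density (350
cells/layer, ~4.5 µm spacing) the apical field is too crowded for
reliable per-cell counting - neighbouring apical disks overlap; the focus
recovery checks therefore run at 100-150 cells per layer in the same ROI,
where disks are well separated.

## Summaries and replicate statistics

`summarize_run()` produces per-layer cumulative mitosis curves, final
counts, divided fractions, onset times, and the ratio trace with its
least-squares slope. "Tight coordination" of the two layers is not
quantified in the reference; `coordination_score()` reports two
transparent, artifact-defined proxies - the maximum absolute
dorsal-ventral difference of the cumulative curves and their Pearson
correlation (undefined for constant curves). `scenario_report()` follows
the replicate convention (five replicates; mean ± 95% CI), using seeded
percentile-bootstrap intervals with 2000 resamples because replicate
counts are tiny and the sampling distributions unknown. Comparisons
against control are reported as deltas of means; no hypothesis tests are
performed, matching the mean-±-CI reporting convention.

## Reproducibility

Every stochastic stage draws from a named substream seed derived from one
master seed (tissue, events, noise, apical layout, bootstrap), so stages
can be re-run independently and a run directory written by
`run_scenario()` is bit-reproducible: the manifest records MD5 checksums
of every artifact, and re-running with the same configuration and seed
reproduces them exactly. Volumes interchange as OME-TIFF (uint16, OME-XML
metadata with physical calibration, readable by standard OME consumers);
ratio traces as the six-column tab-delimited profile table; events as
plain CSV; configurations as YAML.

## Problem sizes used in the tests

The packaged tests exercise the statistic on analytic profiles and small
random volumes, the simulator at the full default scale (350 cells/layer,
where only event simulation is needed), and rendering/detection at
reduced scale (20-30 cells per layer in a 30 x 60 to 40 x 80 px ROI with
the full default z-geometry and 48-frame schedule). These sizes keep the
default test run short while preserving the geometry that drives the
detection problem; detection operating characteristics at full lateral
density are unchanged because cell spacing, not cell count, controls
difficulty, and the reduced-ROI spacing (~9 µm) is conservative relative
to the default (~4.5 µm) only for the rare adjacent-simultaneous-mitosis
collisions that the temporal gap rule already handles.

## Known limitations

* The generator's absolute ratio values depend on rendered amplitudes
  (column vs slab intensity); only the *shape* (monotone decay) is a
  modelled property. Reference ratio curves are figure-only quantities
  and are not reproduced numerically.
* Apical focus counting requires a cell mask; unsupervised segmentation
  is out of scope.
* The detector assumes two well-separated pericentriolar foci; midbody
  stages and mitotic-stage classification are not modelled.
* Real-data concerns - vendor file formats, bleaching correction,
  background subtraction, leg exclusion masks beyond a rectangle - are
  out of scope.
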