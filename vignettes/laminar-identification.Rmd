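---
title: "Laminar identification from AP-band metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar identification from AP-band metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dense linear probes (Neuropixels-class: 384 simultaneously recorded
channels, two columns, 20 µm row pitch, 3.84 mm of rows) span the full
depth of primate primary visual cortex, where at least ten layers and
sublayers — some under 100 µm thick — must be told apart before recorded
neurons can be assigned to circuits. The classical route, current source
density (CSD) analysis of the stimulus-evoked LFP, is spatially coarse and
inconsistent across penetrations and stimuli: synaptic currents spread far
from somata, so CSD sink/source borders need not coincide with the
anatomical (cell-density, soma-size) borders that define layers.

`laminarid` implements the alternative: a family of metrics computed from
the high-frequency action-potential band (300–3000 Hz), which attenuates
over tens rather than hundreds of micrometres and therefore carries genuine
laminar resolution, plus a rule-based assembly of layer boundaries with
anatomical fallbacks, and a cross-penetration layer template.

## Depth conventions

Every metric lives on one shared axis: depth 0 at the deepest active
(non-reference) contact, increasing toward the pia, step equal to the probe
row pitch (20 µm). Channels that share a row are averaged — reference
channels excluded — before any depth-resolved analysis; this exclusion is
applied uniformly to LFP and AP-band metrics. All analysis windows are
relative to stimulus onset: window \[−40, 150\] ms, baseline \[−40, 10\] ms,
response \[10, 150\] ms.

## Stimulus-independent metrics (spike features)

From spike-sorted units with per-channel mean waveforms (≤ 1000 randomly
chosen spikes per unit, seeded):

* **Unit position** — centre of mass of channel coordinates weighted by
  spike height (peak − trough), over channels within 65 µm of the
  largest-height channel.
* **Spatial spread** — from the peak channel, the axial distance up and
  down to the nearest channel whose height drops below 15 % of the
  maximum. The verbal rule ("largest vertical distance … closest
  channels") is internally tense; we read it as *nearest sub-threshold
  channel per direction*, which matches how the spread shading is drawn on
  waveform insets. If no channel falls below threshold before the probe
  end, the spread is capped there and flagged.
* **Duration and peak–trough ratio** — on the largest-height channel,
  duration = t(peak) − t(trough) (negative for peak-leading spikes) and
  ratio = peak/trough (signed; < −1 flags inverted axonal spikes).
* **Unit density** — weighted count (single = 1, multi-unit = 1.2,
  configurable in \[1, 2\]) in a 40 µm segment of a 100 µm-radius cylinder
  slid along the probe at 20 µm steps, divided by segment volume, smoothed
  with a σ = 28 µm gaussian. Absence of units is a true zero here; for the
  other depth distributions empty windows are explicitly missing and the
  smoothing renormalises over non-missing neighbours.

Before profiling, double-counted spikes are removed (pairs closer than
0.35 ms within a cluster, and across clusters within 60 µm — the spike is
dropped from the lower-amplitude cluster, keeping the better-resolved
unit), and clusters at or below 0.5 spikes/s are discarded as noise.

## Stimulus-evoked AP-band metrics

The AP band is conditioned by a 300 Hz order-3 Butterworth high-pass, a
median common average reference (the median is robust to large spikes; the
classical mean is available as an option), a 300–3000 Hz band-pass, and
resampling to 10 kHz. All filtering is zero-phase (forward–backward):
latency metrics must not inherit filter group delay, and the upstream
acquisition chain's phase handling is not part of this package's scope.

* **Power spectrum (Pf)** — multitaper PSD per channel over the response
  window, averaged over trials and same-depth channels, smoothed along
  depth (σ = 20 µm). Multitaper parameters default to NW = 3 with K = 5
  DPSS tapers, ≈ 21 Hz resolution on the 140 ms response window. The DPSS
  tapers are computed from the standard symmetric tridiagonal eigenproblem
  (no R implementation of multitaper analysis is available to build on)
  and were verified against an independent reference implementation.
* **Instantaneous power (P_t) and ΔP/P** — mean of squares in a 10 ms
  sliding window (1 ms step), trial-averaged; ΔP/P = (P_t − P̄_b)/P̄_b with
  P̄_b the baseline-window mean. Depths with zero baseline power are
  flagged missing. Onset latency is the first time ΔP/P exceeds half its
  own post-stimulus maximum; depths whose peak ΔP/P is below 0.5 (a 50 %
  power rise) return no latency rather than a noise crossing.
* **Local coherence (Cf)** — magnitude-squared coherence
  |S_ij|²/(S_ii·S_jj) between channel pairs within 55 µm, gaussian
  distance-weighted (σ = 25 µm), self-pairs excluded (C_ii ≡ 1 would
  inject a constant bias). Coherences are estimated per trial by averaging
  cross-/auto-spectra over tapers, then averaged over trials and
  same-depth channels — matching the "average across depth and trials"
  aggregation — and depth-smoothed with the same σ = 20 µm as Pf
  (switchable off). Cf is invariant to per-channel amplitude scaling while
  Pf scales quadratically; that contrast is the point of computing both.

## Inverse CSD

The LFP (60 Hz notch, 1–100 Hz band-pass, 1 kHz) is depth-averaged,
epoched and trial-averaged, then inverted with the thin-disc model:
sources are uniform discs of radius R = 500 µm at each electrode depth, so
the forward matrix is
`F_ji = h/(2σ_cond) · (sqrt((z_j − z_i)² + R²) − |z_j − z_i|)` with h the
source pitch. Conductivity σ_cond defaults to 0.3 S/m, the standard
cortical value; the ΔCSD *shape* is conductivity-invariant, only absolute
units depend on it. (Note the two sigmas: σ_cond is a conductivity,
σ_smooth a gaussian width; they are named distinctly everywhere.) CSD
profiles are smoothed after inversion along depth (σ_smooth ∈ {20, 30,
40} µm; 30 µm is the working default), which is demonstrably equivalent to
down-sampling contacts to ≈ 60 µm pitch and re-inverting with the
pitch-adjusted forward matrix — both experiments ship in the package. No
boundary-padding (Vaknin) correction is applied; edge rows are inverted
as-is under the disc model. ΔCSD subtracts the per-depth temporal mean of
the baseline window.

## Boundary assembly

No single metric reveals every boundary, so `delineate_layers()` codifies
the delineation workflow as ranked evidence plus fallback rules:

1. **L6/WM** from spike features: the deepest depth above which, over a
   40 µm persistence window, duration > 0, ratio > −1 and spread is above
   the white-matter floor (default 50 µm).
2. **L1/L2**: the shallowest strong falling edge (toward the pia) of the
   band-mean Pf/Cf profiles, at least a plausible cortex above the WM
   border.
3. Remaining sharp edges — gradient extrema of max-normalised band-mean
   profiles exceeding 2× the median absolute gradient (adjacent tied
   extrema merge to their midpoint: a step between samples lies between
   them) — are assigned to L4B/L4C, L4Cb/L5, L5/L6A, L6A/L6B by gradient
   sign and proximity (default ±150 µm) to positions predicted by scaling
   an anatomical thickness prior between the two anchors.
4. **L4A** as an interior elevated band 30–110 µm wide in the expected
   zone, under *any* stimulus condition (maximum over conditions); a
   ladder of elevation thresholds is scanned so that depth-smearing cannot
   disqualify a genuine band, and runs touching the zone edge are rejected
   as shoulders of neighbouring layers.
5. **L4Ca/L4Cb** at the largest onset-latency step inside L4C (scored by
   a t-like statistic so a weakly driven condition cannot win with a noise
   step), clamped so L4Cb is never thicker than L4Ca; with no significant
   step the border falls at the L4C midpoint.
6. `apply_fallbacks()` fills whatever is left: L4A 50 µm thick, L4B half
   of L4C, pia 135 µm above L1/L2 (configurable within 120–150 µm; 135 is
   the midpoint of that anatomical range), L2-3A/L3B two-thirds of the way
   from L1/L2 to the top of L4A, L6A/L6B halfway from L5/L6A to L6/WM.

Every boundary carries provenance (`detected`, `fallback`, `manual`); a
manual-override table wins over everything, mirroring practice where final
delineations are human-curated. Ordering and the L4Cb ≤ L4Ca rule are
validated on construction and after every rule application. How
conflicting evidence across conditions should be weighed is genuinely
open; the ranked-evidence-plus-override design defers that judgement to
the user rather than hard-coding one.

Units are assigned to layers as half-open intervals \[bottom, top): a unit
exactly on a boundary belongs to the layer above.

## Layer template

`build_template()` averages per-layer thicknesses across penetrations;
`align_to_template()` scales each penetration layer linearly onto the
template layer, re-interpolates metric values by natural cubic spline on
the template grid, and max-normalises each per-stimulus profile before
cross-penetration averaging (z-scoring is available; the source only says
"normalized", and max-normalisation preserves sign structure in ΔCSD and
ΔP/P profiles).

## The synthetic penetration

`simulate_recording()` generates AP traces, LFP traces, a sorted-unit
table and an event table from a known layer stack, so the entire pipeline
is testable against ground truth without any recording data:

* neurons placed by an inhomogeneous Poisson process with per-layer
  relative densities ranked 4Cβ > 4A > 6A > 6B ≈ L2/3 > 4Cα > 4B > 5 > 1,
  and a white-matter zone below the cortex containing only axonal sources.
  Two populations share those densities: a sortable process (~500 sources
  per full probe, of which the higher-amplitude ones become the
  sorted-unit table) and a four-fold denser *background* population that
  is painted into the traces but never sorted. The background matters:
  AP-band voltage superposes the whole population's spikes, and with only
  the sortable few hundred sources the band power at a channel is
  dominated by a handful of loud neurons, producing seed-dependent power
  ramps inside layers that displace the edge detectors; with the denser
  population the laminar power profile converges to its density × rate
  expectation and edges sit at the boundaries;
* biphasic somatic templates (0.3 ms trough then 0.2 ms peak,
  |peak/trough| ≈ 0.4) whose amplitude decays as exp(−d/soma_spread);
  axonal sources use the amplitude-inverted template, which produces the
  white-matter signatures (negative duration, ratio < −1). Plain time
  reversal of a biphasic template would *not* push the ratio below −1,
  so inversion is the correct reading of "inverted spikes";
* Poisson spiking at a baseline rate plus a condition-dependent evoked
  rate stepping on at each layer's onset latency (4Cα 40 ms, 4Cβ 60 ms,
  4A 60 ms, 6A 50 ms, …), under four full-field conditions: achromatic
  black and white, an L/M cone-opponent color, and an S-cone color that
  selectively drives the thin 4A;
* i.i.d. gaussian noise, 10 µV RMS per sample per channel — the simplest
  model sufficient for metric testing;
* LFP built with the package's own thin-disc forward model from a
  prescribed depth-CSD movie (sinks in the LGN-recipient layers at their
  latencies, balanced to conserve current), so the inverse-CSD analysis is
  a true round trip;
* every stochastic draw flows from one seeded generator and the seed is
  recorded in the ground truth.

Defaults: 1.75 mm total cortex (configurable 1.5–2.0 mm; L1 pinned inside
120–150 µm), pia 2.2 mm above the deepest contact, 10 presentations per
condition at 1.5 s spacing (≈ 60 s), and on the full probe roughly 475
sorted units (20 % labeled multi-unit) over ~3100 background sources. No numeric per-layer density table exists to copy — published
profiles are graphical — so the default densities are rank-order-faithful
placeholders, and tests assert ranks and correlations, not absolute
densities.

What the generator does *not* emulate: biophysically detailed neuron
morphology, electrode drift, eye-dominance structure, correlated network
noise, and spike-sorting errors other than random multi-unit labels.
Passing tests therefore demonstrate that the metrics read out the
anatomical and functional structure they were designed for — not that
they are robust to every artifact of real recordings.

## Numerical choices and problem sizes

* The reference validation runs the full 384-channel probe for 60 s at
  reduced sampling rates (AP 8 kHz, LFP 1.25 kHz). The AP band ends at
  3 kHz, so 8 kHz sampling loses nothing while keeping a full-probe
  simulation comfortably in memory; `simulate_recording()` itself defaults
  to the native 30 kHz.
* Raw synthetic traces are stored as 0.1 µV integer counts (half the
  footprint of doubles, two orders of magnitude below the noise floor);
  conditioning converts to µV on the fly.
* Gaussian depth smoothing uses a reflective boundary and a 4σ kernel
  truncation, and renormalises over non-missing neighbours.
* The iCSD inversion solves the dense forward system directly
  (`solve(F, phi)`); with ≤ 384 depths this is exact and fast, and the
  round-trip error is at machine precision.
* Sliding mean-of-squares windows are forced to odd sample counts so the
  window is truly centred; edge windows renormalise over the available
  samples.
* The LFP band-pass is applied after resampling to 1 kHz: a 1 Hz corner
  is numerically far better conditioned there than at the native rate,
  and the polyphase resampler supplies the anti-alias filtering.
* `condition_ap_chain()` fuses high-pass, CAR, band-pass and resampling
  into one working buffer; the pipeline uses it so a 60 s full-probe
  recording needs only one full-size matrix beside the input. It is
  numerically identical to composing the two public steps.
* Ties in edge detection (two-sample gradient plateaus) resolve to the
  plateau midpoint.

## Known limitations

* Boundary detection quality degrades with unit yield; with few sorted
  units the WM border loses precision first (the paper's own caveat about
  cortical health applies to the synthetic world too).
* The L1/L2 edge assumes near-silent L1; a probe ending inside cortex
  (no pial crossing) requires a manual override for that anchor.
* `detect_alpha_beta()` assumes a single latency step inside L4C.
* Template alignment assumes all eleven boundaries exist in every
  penetration being averaged.
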