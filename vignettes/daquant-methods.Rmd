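---
title: "Methods: quantifying DAergic neurodegeneration with daquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DAergic neurodegeneration with daquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daquant)
```

## The measurement model

The assay quantifies DAergic neurodegeneration without counting dead
neurons, because in the toxin-induced fly model there are none to count:
neuron numbers are preserved while tyrosine hydroxylase (TH) synthesis
falls. Anti-TH immunostaining converts TH amount into fluorescence of a
labeled secondary antibody, so the fluorescence intensity (FI) integrated
over a neuron's body is a proxy for its TH content.

For one neuron, a closed polygon is drawn around the soma in pixel
coordinates and applied to an 11-slice z-window of the acquired stack
(axial spacing 1.08 µm). On each slice the pixels whose centers fall
strictly inside the polygon (even-odd rule, 0-based pixel-center
coordinates) contribute their intensities:

$$\mathrm{FI}_{neuron} = \sum_{z = z_\mathrm{first}}^{z_\mathrm{last}}
  \;\sum_{(x,y)\,\in\,\mathrm{ROI}} I(x, y, z)$$

Cluster FI is the sum over the cluster's neurons; whole-brain total FI is
the sum over the five quantifiable clusters (PAL, PPL1, PPL2, PPM1/2,
PPM3). The PAM cluster (~100 neurons) is too dense for per-neuron
contours and is only counted as flagged candidates. Maximum-intensity
projections exist for presentation; no quantification path consumes them.

Group effects are summarized as percent change **of group means**,
$(\bar{X}_{ctrl} - \bar{X}_{trt})/\bar{X}_{ctrl}\times 100$ — not the mean
of per-brain ratios, which is unstable at the small n typical of the assay
— with SEM and a two-tailed unpaired t-test (pooled variance; Welch behind
a flag). Data with more than two groups use one-way ANOVA followed by the
Newman–Keuls step-down studentized-range procedure.

### Numerical choices

- *Pixel membership*: pixel center strictly inside, even-odd rule. The
  vendor tool the assay emulates does not document its rule; a crisp
  convention makes results bit-reproducible. Points exactly on an edge are
  undefined but occur with probability zero for generic contours.
- *One polygon per z-window* by default, matching how a contour is drawn
  once and read slice by slice; per-slice polygons are accepted.
- *z-window*: the slice count (11) is authoritative. The protocol's
  printed "cumulative 11.08 µm" is arithmetically inconsistent with
  11 slices at 1.08 µm spacing (10 intervals span 10.8 µm) and is not used.
- *Degenerate inputs*: polygons with < 3 vertices, self-intersections, or
  zero enclosed pixel centers are rejected with explicit errors, as are
  z-windows that leave the stack and uncalibrated stacks.

## Background handling

`measure_roi_slice()` returns raw sums by default — the emulated workflow
subtracts nothing. However, a uniform background $b$ contributes
$b \times \mathrm{area} \times 11$ to every neuron FI, and because an ROI
cylinder holds ~740 voxels while the blob's integrated signal is
concentrated, the background term is *not* negligible: at the synthetic
defaults it is ≈ 0.6× the signal. Raw sums therefore dilute a true 32.6%
group reduction to ≈ 20%, and no realistic blob size or contour radius
brings it above ~29% (the measured reduction is
$32.55\% \cdot s/(s + b_{ROI})$). For this reason the *experiment-level*
pipeline (`run_config()`, the acceptance computation) enables the optional
`subtract_background = "median"` mode: the slice-wide median estimates the
background (blobs occupy a tiny fraction of each slice) and is subtracted
per member pixel. This removes $b$ exactly in expectation without touching
blob signal, restoring the ground-truth contrast. Users of real data can
choose either mode; the choice is echoed in the run manifest.

## The synthetic world

`generate_brain()` states, rather than tunes, the conditions the assay
assumes:

- Per hemisphere: PAL 5, PPL1 12, PPL2 7, PPM1/2 9, PPM3 7 — exactly 40
  quantifiable neurons — plus a PAM blob of 100 (unquantifiable) and a VUM
  position present in the atlas but not measured (count 0). Totals match
  the "~40"/"~140 per hemisphere" census; exact defaults make count tests
  deterministic. The published census gives only approximate totals, so
  the per-cluster split is a package convention.
- Each neuron is a 3-D Gaussian blob, isotropic in physical units
  (σ = 1.2 µm; soma-scale), amplitude 1000 on a 16-bit scale, pixel size
  0.65 µm, 40 slices at 1.08 µm. Background 5% of peak amplitude (50),
  Gaussian read noise 2% (sd 20), Poisson optional and off by default.
- Under the "treated" (PD) condition, positions and counts are identical
  to control for the same seed; amplitudes are multiplied by per-cluster
  attenuation: 0.58 for PAL/PPL1/PPL2/PPM3, 1.0 for the spared PPM1/2.
  The quantifiable total-FI reduction is then exactly
  $(31 \times 0.42)/40 = 32.55\%$ in ground truth.
- Neurons of a quantifiable cluster keep ≥ 7 µm 3-D separation (rejection
  sampling), so auto-contours at 2.5σ never overlap; the PAM blob ignores
  the separation rule — that *is* its defining property.

What the generator does **not** emulate: PSF anisotropy and axial
elongation, photobleaching across the stack, spectral bleed-through,
staining heterogeneity within a neuron, brain-to-brain intensity variation
beyond voxel noise, and tissue autofluorescence structure. A green
recovery test therefore establishes that the measurement chain is
faithful to its own model — not that the optics of a real microscope are.

The chromatogram generator emits Gaussian peaks whose areas equal the
requested amounts on a drifting baseline (defaults: 12 min at 5 Hz,
σ = 0.08 min, retention DOPAC 3.5 / DA 5.0 / HVA 8.0 min — invented but
order-correct for a C-18 column, and configurable). The densitometry
generator's `"paper_default"` fixture encodes the worked two-lane example
(50,000/1,200 vs 55,000/1,122 → 15.0% normalized TH reduction). The
mobility generator draws trial heights at 60 mm (control) with sd 5 mm
(~8% CV, a steady climbing assay), declines of 0.33 (24 h) and 0.60
(48 h), 12 flies × 3 trials; with this noise level the decline estimator's
sampling sd is ~1.3 percentage points, comfortably inside the ±3-point
recovery tolerance. Column height defaults to 70 mm; heights are clamped
to it, which at these defaults affects < 3% of control trials.

## Neuron detection

Counting uses a difference-of-Gaussians filter matched to the blob scale
(σ and 1.6σ, normalized kernels so constant background cancels exactly),
thresholded 3-D local maxima (default response ≥ 50: the expected DoG
response of an attenuated neuron is ≈ 0.205 × 580 ≈ 119, while smoothed
noise is ~1.5), greedy non-maximum suppression at 3 µm, and
nearest-centroid atlas assignment within each cluster's radius + 3σ.
Candidates assigned to PAM are counted and flagged
"unquantifiable — high neuronal density"; clusters with zero detections
trigger a damaged-brain warning. These thresholds are config defaults
tuned to the synthetic fixtures — the emulated workflow counts manually —
and are parameters, not constants.

## HPLC quantification

Peaks are local maxima above a height threshold; bounds descend from the
apex to the running-minimum valley (with a small tolerance for noise
wiggle), the baseline is the chord between bounds, and the area is the
trapezoidal integral above it. Identification is nearest-retention-time
within a tolerance (ties toward the earlier standard), with spiking
confirmation requiring a >10% area increase in the spiked run.

The V1–V8 chain converts a sample peak area into pg of catecholamine per
fly head. One step of the published chain references a quantity (V5) it
never defines; dimensional analysis admits a single reading — total
analyte in the whole extract, $V_5 = V_2 \times V_{extract}/I_{Samp}$
(extract volume 300 µL by protocol) — which makes $V_6 = V_5/N$ "per fly
head" sensible. This interpretation is flagged in the output. Turnover is
$(\mathrm{DOPAC} + \mathrm{HVA})/\mathrm{DA}$, the standard index; HIAA is
accepted as a standard label but excluded from turnover. Whether
downstream figures normalize per head (V8) or per µg protein (V4) is
ambiguous in the source; both are always reported.

## Statistics

`sem()` uses the n−1 sample SD. The default t-test is Student's pooled
form — the graphing-software default the emulated workflow used — with
Welch behind `welch = TRUE`; equal-variance vs Welch is not stated in the
source, so the choice is documented rather than silent. ANOVA reports
F = MS between / MS within; all-identical groups yield NaN/p = 1 by
convention. Newman–Keuls sorts means, tests stretches widest-first with
$q = \Delta/\sqrt{MS_w/2\,(1/n_i + 1/n_j)}$ against `qtukey` critical
values, and blocks any pair inside a non-significant enclosing stretch;
tail probabilities come from base R's studentized-range integration, and
the test suite validates them against a 10^5-draw Monte-Carlo oracle.

## Scaling of the shipped runs

The default `run_config()` simulates 2 brains per group (the test suite
additionally swaps in a reduced atlas) so smoke and determinism checks run
in seconds; the acceptance script runs the full default geometry at
12 + 12 brains (≈ 45 s on one CPU). All randomness flows from explicit seeds; generators are
bit-reproducible given (config, seed) and leave the caller's RNG state
untouched.

## Known limitations

- The TIFF layer supports the baseline subset (uncompressed little-endian
  grayscale); vendor formats (.czi, compressed OME-TIFF) must be exported
  first. Calibration is taken from arguments, never from tags.
- Whether vendor "intensity sum" readouts are background-corrected is
  unknown; both raw and median-subtracted modes are provided (see above).
- Detection assumes the brain is registered to the atlas orientation, as
  the assay itself requires ("same orientation" mounting); misoriented
  brains surface as empty-cluster warnings, not corrections.
- Co-eluting chromatographic peaks closer than 4σ are flagged, not
  deconvolved.
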