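---
title: "Methods: forward model and assay quantification for a gradient GMR spectral sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model and assay quantification for a gradient GMR spectral sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggpgmr)
```

## The measurement principle

A guided-mode resonance (GMR) filter is a subwavelength grating on a thin
waveguiding film. At normal incidence it rejects (reflects) a narrow band
around the Bragg resonance

$$\lambda_R = n_{\mathrm{eff}}\,\Lambda,$$

where $\Lambda$ is the grating period and $n_{\mathrm{eff}}$ the effective
index of the guided mode, so in transmission it is a bandstop filter. If the
period ramps along the device (here 250--550 nm in 2-nm steps, 100 cycles
per period), the rejected wavelength ramps with position: the filter
converts spectral information into spatial information. Mounted on a linear
CCD, a monochromatic input produces a transmission dip at one pixel --- the
minimum-intensity corresponding pixel (MICP) --- whose location encodes the
wavelength and whose depth scales with the intensity. A single calibration
scan then replaces a spectrometer for assays that only need a peak
wavelength and its intensity.

`ggpgmr` implements this instrument as a forward model (device layout,
transmission-efficiency matrix $T$, CCD readout $C = TI$ with noise), the
calibration procedure, a synthetic-data generator for the assay classes the
platform targets, and the quantification pipeline (dose--response
regression, sensitivity, noise, limit of detection, cross-instrument
agreement).

## Effective index and the device layout

The stack is a PET substrate, a replicated NOA 68 grating (85-nm ridges,
duty cycle 0.5) and a ~130-nm TiO~2~ waveguiding coat under air. Two
$n_{\mathrm{eff}}$ models are shipped:

* **Slab mode** (default). The corrugated region is homogenized by
  zeroth-order effective-medium theory for TE polarization,
  $n_g^2 = f\,n_{\mathrm{ridge}}^2 + (1-f)\,n_{\mathrm{groove}}^2$ with the
  NOA 68 ridge and air groove, and collapsed with the flat TiO~2~ coat into
  a single film by thickness-weighted squared index. The fundamental TE mode
  of the resulting asymmetric slab (NOA 68 below, air above) is solved by
  bracketed root finding of the standard dispersion relation. Collapsing the
  two sublayers is a deliberate zeroth-order choice: it keeps the solver a
  single-film problem while retaining the dominant dispersion, which is what
  the design-scale claims (device length, bandwidth) depend on.
* **Weighted average**. A thickness-weighted mean of the layer indices ---
  coat, duty-weighted corrugation, and nominal 50-nm evanescent tails into
  the claddings --- matching the back-of-envelope picture of
  $n_{\mathrm{eff}}$ as a weighted average of the structure's indices. It is
  kept as a sanity envelope; the two models agree within 15% over the
  operating band, and the weighted value seeds the slab solver's fixed-point
  iteration.

Material dispersion defaults are literature-typical: TiO~2~ as a two-term
Cauchy fit $n = 2.24 + 3.0\times10^4/\lambda^2$ ($\lambda$ in nm; $n \approx
2.34$ at 550 nm, appropriate for sputtered films), NOA 68 at 1.54, PET at
1.57, air at 1.0, all overridable in the configuration. Supported dispersion
range is 350--1100 nm: the long end is needed because a 550-nm period
resonates near 917 nm under this stack.

$\lambda_R(\Lambda)$ is solved as a fixed point of
$\lambda = n_{\mathrm{eff}}(\lambda)\Lambda$ by damped iteration (damping
0.5, residual tolerance $10^{-7}$ nm, at most 100 iterations); the
contraction is mild because the dispersion is weak. `build_layout()`
enumerates the periods, lays segments end to end from the smallest period,
and can restrict to a resonance band: the 500--700 nm band keeps 66 of the
151 periods and a total length of 2.211 mm, and the full period ramp spans
446.6 nm of resonance (both values are what `scripts/acceptance.R`
recomputes).

## Transmission matrix and CCD readout

The hardware's dip depth and width are only shown graphically in the source
measurements, never tabulated, so the lineshape is phenomenological: a
symmetric unit-peak Lorentzian dip, $T = 1 - d\,L(\lambda - \lambda_R)$,
with default depth $d = 0.9$ and FWHM $\Gamma = 3$ nm --- GMR dips are
near-total and a few nanometres wide. A Gaussian dip is selectable; Fano
asymmetry is not modelled.

Each CCD pixel inherits the resonance of the grating segment above it
(length-weighted when a pixel straddles a boundary); pixels only partly
covered by the device blend with unit transmission, and a margin of
uncovered unit-transmission pixels is kept so edge dips retain a baseline.
The wavelength grid is 200 bins at 1-nm pitch from 500 nm (500--699 nm):
the half-open convention keeps both the wavelength index and the paper-mode
pixel selection at exactly 200 while covering the nominal 500--700 nm band.
`paper_mode = TRUE` restricts rows to the pixel nearest each grid
wavelength, reproducing the square $200\times200$ matrix convention.

The CCD is anchored to the printed pixel numbering (MICP 2073 at 500 nm,
2361 at 700 nm) by `anchor_ccd()`: segment centres are interpolated over
resonance and clamped at the end segments, where the dip of a band-edge
input physically saturates. With the stock stack this lands a 600-nm input
on pixel 2201 --- the value actually reported for the concentrated dye
measurement. Optical magnification is 1 (contact configuration); readout is
kept in floating intensity, with an optional integer-quantization flag.

Noise is additive: dark offset, Gaussian read noise, and signal-dependent
shot noise of standard deviation `shot_noise_scale * sqrt(C)`, all seeded.
Intensities are clipped at zero after noise injection.

## Calibration

`build_calibration_curve()` reproduces the monochromator scan: a 2.5-nm-FWHM
Gaussian line stepped at 1 nm across the band, one readout per wavelength,
MICP extraction per trace. `find_micp()` smooths with a 5-pixel moving
average (about the width of one grating segment's pixel block under the
default geometry), takes the argmin, and refines sub-pixel position with a
parabola through the three neighbouring points; a flat run of equal minima
is centred, and separate equal minima resolve to the lowest run with a tie
flag. The dip must exceed a 5% depth against the median baseline, which
rejects dark frames and blanks. Raw scans are repaired by isotonic
(pool-adjacent-violators) projection before the monotone forward/inverse
lookups are stored --- the curve must be invertible --- but inversions beyond
2 pixels fail loudly rather than being silently repaired. Calibration is
amplitude-independent (the MICP does not move when the source is scaled),
which the tests verify; scan amplitude is therefore fixed at 1.

Because measurement and calibration share the same extraction procedure, a
noiseless monochromatic input at any integer scan wavelength is recovered
essentially exactly; the end-to-end recovery tests bound the error at 1 nm
across 505--695 nm.

## The synthetic assay generator

The generator emulates the study conditions of the three measured assay
classes, with ground truth and per-measurement child seeds retained
(`regenerate_trace()` rebuilds any trace bit-for-bit):

* **Dye dilution series** (`"tamra"`): Gaussian emission (40-nm FWHM) whose
  peak drifts logarithmically with concentration, anchored to the two
  reported points --- 600 nm at $10^{-3}$ M and 566 nm at $10^{-6}$ M, i.e.
  $-34/3$ nm per decade --- emulating the reabsorption blue shift of
  concentrated dye on dilution; saturating amplitude; five decades
  $10^{-3}$--$10^{-7}$ M.
* **Fluorescent albumin** (`"hsa-fluorescent"`): albumin blue 580
  conjugate, peak fixed at 610 nm (centre of the observed 608--612 nm
  band), linear amplitude over 200, 150, 100, 50, 25, 12.5, 6.25 mg/L plus
  a blank, three runs. The stray-light background defaults to 0.002 (0.2%
  of full scale): large enough that a blank is well-defined, small enough
  that the background pedestal --- which enters the two channels with
  different weights --- does not distort the cross-channel linearity.
* **Kinetic creatinine** (`"creatinine-jaffe"`): Beer--Lambert transmission
  of a 535-nm LED through a complex whose absorbance band is centred at
  510 nm (60-nm FWHM, peak absorbance 0.0016 per mg/L.cm); first-order
  colour development $c_{\mathrm{eff}}(t) = c(1 - e^{-kt})$ with $k = 0.24$
  min$^{-1}$, chosen so ~70% of the asymptote is reached at the 5-min read
  (the source notes a persistent reaction but prints no rate); reads at 0
  and 5 min; 50--500 mg/L plus blank.
* **Colorimetric albumin** (`"albumin-bcg"`): bromocresol-green complex
  absorbing at 620 nm (40-nm FWHM) under a 625-nm LED, absorbance 0.03 per
  mg/mL.cm --- strongly saturating over 5--50 mg/mL, reproducing the
  reported nonlinearity.

The reference spectrometer channel adds seeded per-bin Gaussian noise and a
run-level multiplicative gain jitter. Concentrations carry explicit unit
tags; nothing converts units silently.

What the generator does **not** emulate: Fano-asymmetric lineshapes,
wavelength-dependent CCD quantum efficiency, photobleaching and quenching,
excitation stray light, reagent-volume bookkeeping, or the urine matrix
chemistry. Passing tests therefore demonstrate the correctness and
statistical behaviour of the pipeline under the stated forward model, not
fidelity to any particular physical device.

## Quantification conventions

**Reading convention.** The dose--response intensity of the CCD channel can
be read at each trace's own MICP (`"sample"`) or at the MICP pixel of the
run's highest-concentration measurement (`"reference"`). For assays whose
peak does not move with concentration the reference convention is the
default: reading at a noisy trace's own argmin systematically selects noise
troughs, biasing intensities down and distorting replicate statistics,
whereas a fixed pixel makes the replicate noise exactly the read noise.
Assays with a concentration-dependent peak (the dye series) are read at
their own MICP. Dim traces with no detectable dip always fall back to the
reference pixel. Kinetic assays are read at a fixed location --- the LED
centre wavelength and its calibrated pixel --- as the difference between the
0- and 5-min intensities.

**Normalization** is per run, to the mean intensity at the highest
concentration; references are never mixed across runs.

**Sensitivity** is the OLS slope of normalized intensity against
concentration expressed per 10 concentration units. This convention is
forced by the reported worked numbers: the printed noise/sensitivity pairs
(0.1517, 0.037) and (0.0730, 0.042) reproduce the printed LODs 40.99 and
17.39 mg/L only when the slope is per 10 mg/L
($10 \times 0.1517/0.037 = 41.0$). It is prominent in the output and
configurable.

**Noise** is three times the pooled within-concentration standard deviation
of the normalized intensities across all levels. "The standard deviation
from all measurements" is ambiguous between pooled, global and blank-only
populations and the printed values cannot disambiguate it; the pooled
reading respects the concentration structure and is the default, with
`"global"` and `"blank"` selectable.

**LOD** = noise / sensitivity, in the table's concentration units. For the
saturating bromocresol-green assay the sensitivity entering the LOD is the
local-linear slope over the three lowest concentrations, and the report
records that convention.

**Cross-instrument agreement** regresses one channel's normalized
intensities on the other's, paired by (run, concentration); both slope and
$R^2$ approach 1 for the noiseless end-to-end chain, and the MICP/peak
wavelength correlation over a dye series recovers the local
calibration-curve slope in pixels per nm.

## Numerical choices and degenerate inputs

OLS fits use `stats::lm`; the tests hold them to a closed-form two-pass
oracle at $10^{-10}$ relative. Isotonic projection uses `stats::isoreg`;
interpolation uses `stats::approx` with no silent extrapolation --
out-of-range calibration queries are errors. A constant dose response is
returned as slope 0, $R^2 = 0$ with a degeneracy flag rather than `NaN`; a
zero kinetic reference with all-zero responses yields a table of zeros (the
no-reaction limit); fewer than three distinct concentrations, single
replicates (for pooled noise), missing per-run references, and
non-monotone calibrations all raise typed errors. All randomness flows from
one plan seed through a documented child-seed derivation, so any component
can be re-run in isolation.

## Test problem sizes

The shipped suites run the full chain at the stock geometry: the 151-period
layout, the 66-segment band-restricted device, a 200-knot calibration, a
100-trial seeded MICP robustness check at 1% read noise, and a 200-seed
parameter-recovery study (3 runs x 8 levels each) whose median recovered
LOD must fall within 25% of the injected $3\sigma/\mathrm{slope}$. These
sizes were chosen as the smallest replicates of the study conditions that
give stable medians.

## Known limitations

The effective-index model is a homogenized slab, not rigorous coupled-wave
electromagnetics; TM polarization, off-normal incidence and fabrication
tolerances are out of scope. The dip depth and width are assumptions, so
absolute trace intensities are in arbitrary units and only ratios are
meaningful. Spectral reconstruction by inverting $T$ is deliberately not
implemented --- the platform's procedure only ever maps a dip location back
through the calibration curve. Whether the liquid sample wets the grating
(changing the superstrate index) is not modelled; the default assumes an
air superstrate.
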