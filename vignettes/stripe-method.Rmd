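---
title: "Measuring CT overbeaming and overranging from a helical stripe image"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CT overbeaming and overranging from a helical stripe image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helistripe)
```

## The measurement model

A helical CT acquisition is recorded on a cylindrical computed-radiography
plate of radius $R$ wrapped around a phantom centred on the rotation axis.
Unwrapping the cylinder maps the helical trajectory of the x-ray fluence to
a family of tilted stripes, one per gantry rotation, with tilt
$\arctan\!\big(f / 2\pi R\big)$ for table feed $f = \text{pitch} \times
\text{collimation}$ per rotation.

Three relations carry the whole analysis:

* the logarithmic CR response, $E = 10^{PV/G}$, with gray level $G = 1024$
  for the system modelled here — all widths are measured on
  exposure-converted data, because measuring on the log-scaled pixel values
  would bias them;
* the magnification of a width measured on the plate (at the focus–surface
  distance FSD) to the rotation centre (at the focus–isocenter distance
  FID): $BW = \mathrm{FWHM} \times \mathrm{FID}/\mathrm{FSD}$, giving the
  actual beam width and the dose efficiency
  $DE = BW_\mathrm{nominal}/BW$;
* overranging from the longitudinal mean profile:
  $\mathrm{OR} = (\mathrm{FWTM} - d)/2$ for planned scan range $d$, the FWTM
  being the actual exposure length.

Two assumptions back the model. First, exposure is entrance-only: the beam
leaving ~500 mm of acrylic is attenuated to negligible levels, so
FSD $=$ FID $- R$ and each plate point is exposed only while it is the
beam-entrance point of the cylinder. Second, the longitudinal aperture at
the isocenter is a symmetric trapezoid: a flat umbra with linear penumbra
ramps of one-sided width $p$, FWHM equal to the actual beam width. The
penumbra default follows the focal-spot projection through the collimator,
$p = s_z (\mathrm{FID} - c)/c$ for focal-spot extent $s_z$ and
focus–collimator distance $c$ (1 mm and 200 mm by default, giving
$p = 2$ mm).

## The forward simulator

`simulate_stripe_image()` integrates entrance exposure over gantry angle
(0.5° steps, trapezoidal accumulation; configurable). At gantry angle
$\theta$ the source sits at radius FID, the beam centre at table position
$z_s$; a plate point at circumferential angle $\varphi$ receives exposure
when $\cos(\theta - \varphi) > R/\mathrm{FID}$ (it is then the entrance
point), weighted by

* inverse-square distance to the focus,
* incidence obliquity (cosine of the angle between ray and surface normal,
  floored at zero), and
* an in-plane fluence term, Gaussian in fan angle with standard deviation
  `fan_sigma_deg` (default 3°).

The third term deserves a note. Without it, source positions 20–40° away
from a point's radial pass still contribute noticeably; their beam
footprints are wider (the rays are longer) and the superposition inflates
the recorded stripe FWHM by about 2% for a 39 mm beam, while also filling
the gaps between stripes at pitch < 1. Real systems concentrate entrance
fluence near the central rays through beam-shaping filtration, and real
stripe images show cleanly separated stripes at pitch 0.83–0.87. The
single-parameter Gaussian stands in for that concentration; 3° keeps the
inter-stripe floor below 0.1% of peak and makes the recorded width
consistent with the thin-ray projection that the magnification correction
assumes. It is an effective response model, not a bowtie curve.

**Scan extent.** The planned range is $[0, d]$ at isocenter. The beam
centre travels from $-(r f + b/2)$ to $d + r f + b/2$, where $b$ is the
aperture base width and $r$ = `overtravel_rotations` (default 0.5 per end):
half-base clearance so the full aperture passes each boundary, plus the
part-rotations of extra data helical reconstruction needs. The rotation
term is what makes the exposed length — and hence overranging — grow with
pitch and collimation, as observed.

**Dynamic z-collimator.** The blade trajectory of clinical collimators is
not published; the model is constrained by two observations: the shuttered
width at the range boundaries is roughly half the set width, and the stripe
ends taper. With the collimator active, the outward blade edge is clamped
against the planned boundary, lagging the beam centre by a fraction
$\min(1, \texttt{ramp\_rotations}/0.5)$: at the default ramp of half a
rotation the aperture is exactly half open when the beam centre crosses a
boundary, opens linearly as the umbra clears it, and is fully open
mid-scan. `collimator_schedule()` exposes the blade edges directly.

**Ground truth.** Each simulation returns the configured beam width, the
FWTM of its own noiseless column-mean z-profile as the actual exposure
length (so truth and measurement share one definition of "exposure
length"), the overranging that implies, and the geometric tilt.

**Noise and encoding.** Noise is multiplicative Gaussian on exposure
(relative SD, seeded) — the CR response is log-encoded, so this is additive
on PV. `encode_pv()` quantises $G\log_{10} E$ to integers in a 16-bit
container; unexposed pixels map to PV 0 and are counted in the metadata.
Exposure images are normalised to a peak of 1000 (arbitrary units; every
reported quantity is a width or a ratio, so the scale cancels).

## Analyzer numerics

* **Width estimation** (`measure_fwhm()`/`measure_fwtm()`): background is
  the mean of the outer 10% of samples on each tail; the level is
  background $+$ 0.5 (or 0.1) of the background-corrected peak; crossings
  are found by walking outward from the global peak and interpolating
  linearly between the bracketing samples. No smoothing by default; an
  optional odd-width moving average is recorded in the report. A profile
  whose flanks never cross the level raises "peak not resolved".
* **Stripe detection** (`detect_stripes()`): threshold at 50% of the 99.5th
  percentile, connected-component labelling, intensity-weighted principal
  axis for the tilt. Components cut by the z-borders are discarded; stripes
  centred outside $[0, d]$ are flagged as taper-zone stripes, and stripes
  centred on a stitching seam are flagged. Detections closer than
  `min_separation` (1 mm) collapse to the stronger one.
* **Stripe selection**: "arbitrary stripes" is made deterministic — the
  `n_stripes` (default 3) stripes nearest mid-range, excluding taper-zone
  stripes, for reproducibility and because the taper violates the
  full-aperture assumption. With the collimator active, stripes whose ridge
  sits within half a beam base of a range boundary are blade-clipped; they
  are identified both geometrically and as near-boundary stripes measuring
  markedly narrower than the widest stripe, and dropped (flagged in the
  report). For a wide beam in a short range it can happen that *no* stripe
  is unclipped; the report then carries a flag instead of silently biased
  numbers.
* **Perpendicular profiles**: sampled at half-pixel steps through the
  centroid with bilinear interpolation, averaging five lines offset ±2
  pixels along the stripe axis. The default length is 1.1× the measured
  stripe spacing, which places the background tails in the inter-stripe gap
  — long enough for a background estimate, short enough not to climb the
  neighbouring stripe.
* **Overranging ROI**: the longitudinal mean must cover the full
  circumference (or a ROI containing entire stripes); on a narrow window
  the profile degenerates into a comb with empty rows between helix
  window-crossings and the FWTM is meaningless.
* **Overlap guard**: adjacent stripes are separable when the plate-level
  footprint (beam width plus twice the penumbra, projected by FSD/FID) is
  below the feed; merged stripes are detected as components spanning more
  than 2.2 feeds and abort the beam-width analysis with advice to raise
  pitch or plate radius.

## Validation strategy and problem sizes

The test suite exercises three layers. Estimator oracles: FWHM/FWTM against
closed forms on triangles, trapezoids and rectangles; the log-response
inversion against its algebra; tilt against the helix geometry. Property
checks: collimator schedule edge cases, split/stitch and phase-rotation
invariance, discretisation convergence under grid doubling. End-to-end
round trips at the study conditions — 32/80 mm collimation, pitches
0.83–1.48, 160 mm range, 0.2 mm/px over the full circumference, collimator
on and off — recover the configured beam width within 2% and ground-truth
overranging within a millimetre, and reproduce the qualitative trends
(overranging grows with pitch and collimation, the collimator strictly
reduces it, flat-plate and stripe modes agree within 5%). Unit tests use a
shorter 60–96 mm range and 0.4 mm pixels to keep the suite fast; those
sizes are a package choice and all tolerances are stated per test.

Passing round trips show that the *pipeline* is self-consistent under the
forward model's physics; they cannot certify effects the model omits:
scatter, detector/readout blur, plate fading, polyenergetic spectra, the
true bowtie transmission, or any vendor's actual blade trajectory. Absolute
dosimetry is out of scope throughout — exposure units are relative, and
console dose-length products are carried as pass-through metadata only,
never computed.

## Degenerate inputs and tie-breaks

Zero penumbra degenerates the trapezoid to a rectangle (widths remain exact
within a sample step). An exposure length shorter than the scan range
yields a negative overranging with a warning rather than an error. A grid
coarser than the plate-level penumbra records a warning in the image
metadata. Equal-strength overlapping detections keep the earlier (lower-z)
stripe.

## Known limitations

Raster input is 16-bit TIFF/PNG with a JSON sidecar; DICOM is not read (no
DICOM reader among the package's dependencies), so exports from a CR reader
must be converted. The beam-width measurement with the dynamic collimator
active is only as good as the set of unclipped stripes; with an 80 mm beam
and a 160 mm range that set can shrink to one stripe. The collimator blade
model is an effective description calibrated to its two observable
constraints, not vendor firmware.
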