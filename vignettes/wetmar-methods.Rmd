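---
title: "Methods: simulating, correcting and evaluating metal artifacts for proton-range calculations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, correcting and evaluating metal artifacts for proton-range calculations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Metallic hip prostheses produce severe streak and band artifacts in CT
images. When such images feed a proton treatment-planning system, corrupted
Hounsfield units (HU) map to wrong stopping powers and hence wrong proton
ranges. `wetmar` reproduces, on fully synthetic data, the standard evaluation
of a sinogram-domain metal artifact reduction (MAR) algorithm for this use
case: simulate a water phantom with chromium-cobalt implants, apply an
O-MAR-class iterative correction, convert HU to relative proton stopping
power (RSP) through a stoichiometric calibration, and compare
water-equivalent thickness (WET) along beam rays against a metal-free
reference scan, as a function of beam direction.

The package's quantitative endpoint mirrors clinical practice: for a point of
interest (POI) midway between the implants, and for beam angles every 4
degrees, the WET difference

WETdiff(angle) = WET_image(angle) - WET_reference(angle)

is evaluated for the uncorrected and the MAR-corrected image, excluding
angles whose ray intersects the implants.

# The phantom and what the simulator does (and does not) emulate

The phantom is a 30 x 30 cm water tank filled to 23 cm, a 2 cm PMMA slab on
the bottom, and one or two chromium-cobalt discs of radius 22 mm (femoral
head cross-sections) resting on the slab 20 cm apart. The two-insert
geometry, the 120 kVp-class polychromatic spectrum and the pelvic-protocol
context define the default study conditions; the unilateral variant keeps
one disc at its side position. The 3 mm slice thickness is metadata only (the
simulation is 2-D axial).

Acquisition is simulated per energy bin: the phantom is rasterized to
material labels (512 x 512 at 0.7 mm by default), each material's linear
attenuation at energy E follows the same stoichiometric parameterization as
the HU calibration (Klein-Nishina Compton term plus photoelectric
~ Z^3.62 E^-3.2 and coherent ~ Z^1.86 E^-1.9 terms anchored at an effective
energy of 70 keV), rays are forward projected (720 parallel-beam views over
180 degrees), detected counts are I = sum_E w_E N0 exp(-p_E) with Poisson
noise at N0 = 1e5 photons/ray, counts are floored at 1 (photon starvation),
and the effective line integral -ln(I/I0) is reconstructed by filtered back
projection. HU scaling uses a water-only calibration scan run through the
identical chain, so water reads 0 HU by construction.

This produces the two artifact mechanisms that matter for the study: beam
hardening (the polychromatic mean energy rises behind metal, depressing
reconstructed values along metal-crossing rays and carving the dark band
between the implants) and photon starvation (near-zero counts behind metal
yield noisy streaks tangent to the implant pair). It deliberately does not
model scatter, detector cross-talk, helical/3-D effects, partial volume in
z, or automatic exposure control. The reconstructed artifact amplitude is
therefore stronger than a modern scanner's (a real acquisition at 420 mAs
with vendor preprocessing starves far less); conclusions should be read as
properties of the correction pipeline, not as absolute artifact magnitudes
of any particular scanner.

# Projectors

Forward projection splats each pixel onto the two nearest detector bins with
linear weights (scaled by pixel area over detector spacing, making each bin
approximate a line integral in value x mm); back projection is its exact
adjoint. This pair conserves per-view mass exactly and passes an adjoint
identity test at machine precision, which the MAR loop relies on. Filtered
back projection uses the standard band-limited spatial-domain ramp kernel
(optionally sinc-apodized), FFT convolution per view, and the pi/n_angles
normalization; a smooth-phantom round trip reconstructs within 5% relative
RMS inside the reconstruction circle. Geometry is parallel-beam over 180
degrees rather than the helical fan beam of a clinical scanner: the MAR
description is geometry-agnostic and parallel beam keeps the artifact
self-contained.

# The MAR loop

Thresholds classify the input into a metal-only image (zero except metal
pixels, default threshold 2500 HU) and a tissue-classified image (pixels
"close to zero" HU replaced by their global mean; everything else kept).
The metal trace is the sinogram support of the forward-projected metal
indicator. The first pass replaces the metal-trace data of the original
sinogram by 1-D linear interpolation along the detector axis (inpainting);
each pass forms a difference sinogram between the current image's sinogram
and its tissue estimate, masks it to the metal trace, reconstructs this
"metal-only recording" by filtered back projection, and subtracts it from
the current image, which becomes the input of the next pass. Metal pixels
are restored bit-exactly from the input image, corrections are confined to
the reconstruction circle, and the loop stops when the relative L2 change of
the non-metal image drops below 1e-3 or after 8 passes.

Two design choices deserve explanation:

* **Filtered correction.** The published flow chart says "back-projection"
  of the masked difference sinogram. Plain unfiltered back projection does
  not invert the forward model, so the correction would not live on the HU
  scale of the image; the default therefore ramp-filters the masked
  difference before back projecting (the unfiltered form is available via
  `mar_config(filtered_correction = FALSE)` for fidelity to the literal
  text).

* **Tissue band.** The band of pixels flattened to the tissue mean defaults
  to [-100, 100] HU: wide enough to erase water-level noise and residual
  streaks, narrow enough not to swallow real structure such as the PMMA slab
  (~130 HU) or bone. A wide band (e.g. [-300, 300]) makes the iteration
  converge toward a prior in which the slab is replaced by the global tissue
  mean, and rays with long slab paths inherit that bias. The vendor
  algorithm's actual thresholds are proprietary; both thresholds are
  configurable and logged in the output metadata.

The "average HU value of the tissue pixels" is computed globally per image
(the simplest reading of the published description).

# HU to RSP calibration

The two-step stoichiometric procedure is implemented in full. Step one fits
the cross-section ratios k_ph and k_coh from HU measurements of known
materials (water, PMMA, CaCl2 solutions spanning effective atomic numbers);
the HU model is a ratio of terms linear in the parameters, so an exact
linearized solve seeds a bounded least-squares refinement. The package's
default parameters are the fitted pair (2.86e-5, 7.20e-4) of the pelvic
protocol it emulates; re-fitting is exercised on synthetic insert data. Step
two predicts the HU of reference tissues (ICRP/ICRU compositions embedded as
code constants) with those parameters and pairs each with its RSP at 219
MeV, computed from the first-order Bethe formula without shell, Barkas or
density-effect corrections — at 50-250 MeV in light media these corrections
are sub-percent and largely cancel in the water ratio. Compound mean
excitation energies use the Bragg-additivity log-average over electron
fractions (water is pinned at the conventional 75 eV). The 219 MeV anchor
energy is representative: the computed RSP varies by at most 0.69% for
cortical bone and 0.41% for adipose/muscle across 50-250 MeV relative to its
219 MeV value (the package's acceptance script recomputes both numbers).

Lookups interpolate linearly between anchors. Air is included as the lowest
anchor (about -1000 HU, RSP about 0.001), pinning the conversion near zero
where it belongs physically; inputs below -1000 HU (possible in strong
artifacts) are clamped to the air point, and results are floored at 0.001 so
WET integrals stay non-negative. Keeping the conversion piecewise-linear and
anchor-driven over the whole clamped range preserves the design property the
reference comparison relies on: a uniform calibration offset shifts the WET
of the test and reference images equally and cancels in WETdiff (verified as
a regression with a +0.02 offset on all anchors). Mapping HU = 0 through the
tissue curve (rather than forcing RSP = 1) reproduces the same systematic
error in test and reference scans, which is exactly why it cancels.

# WET evaluation

Rays are traced from the phantom edge to the POI with a clockwise angle
convention (0 degrees enters from the top, 90 from the right). Each ray is
divided into segments of at most half a pixel; HU is sampled by bilinear
interpolation at segment midpoints and mapped through the lookup; cumulative
WET is the running sum times the step (midpoint rule — second-order
accurate, exact for constant integrands, and within 0.03% of a 10x-refined
integration and 2% of a voxel-intersection (Siddon) integral on the study
images). Angles whose ray samples touch the implant metal map (taken from
the phantom specification on synthetic runs, from metal segmentation of the
uncorrected image otherwise) are excluded, as in the study design. Along
each kept ray the package reports the WET at the POI, WETdiff for the
uncorrected and corrected images, and the along-path maximum of the
cumulative |difference| (to detect mid-path error peaks). WET is reported in
cm.

# Problem sizes and reproducibility

The canonical study runs at 512 x 512 pixels (0.7 mm), 720 views, 1e5
photons/ray, 90 beam angles, and completes in under ten minutes on one CPU;
the test suite exercises the identical pipeline at 256 x 256 / 360 views
(and 128 x 128 / 180 views for smoke tests), where the artifact mechanisms
are unchanged. All stochastic steps are seeded: a study configuration plus
its seed reproduces every output file bit-for-bit, and `summary.json`
records the configuration hash and seed.

# Known limitations

* The worst-case beam direction on this phantom is the non-excluded angle
  closest to the implant-joining axis: such rays run lengthwise through the
  inter-prosthesis dark band and accumulate roughly twice the WET error of
  the posterior-anterior (0/180 degree) rays that cross the band
  transversally. Margins derived from a PA-only analysis would understate
  the directional worst case; the angular scan exists precisely to expose
  this.
* The corrected image retains its largest residuals at those same grazing
  angles; the correction quality criterion (worst corrected error at most
  half the uncorrected one) holds at the reduced evaluation scale used by
  the test suite, and the residual is concentrated near the exclusion cone.
* The simulator's artifact amplitude is not calibrated to any specific
  scanner; absolute WETdiff values should not be compared directly with
  measurements on clinical hardware.
* Single 2-D axial slice only; no scatter; disc/annulus implant
  cross-sections rather than full prosthesis shapes.
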