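---
title: "Quantifying FRC network mechanics: methods and design notes"
author: "frcmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FRC network mechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcmech)
```

Lymph nodes are supported by a contractile network of fibroblastic reticular
cells (FRCs) that spans the T cell zone, and the mechanical state of that
network — its tension, its mesh size, the membrane tension and proliferative
behaviour of the individual fibroblasts — shapes how the tissue accommodates
immune expansion. None of these quantities can be read off an image directly;
each is defined by a quantification procedure. `frcmech` implements those
procedures as tested, reusable functions, together with seeded synthetic-data
generators that produce every input class with exact ground truth, so each
stage can be verified end to end without any raw microscopy data.

This vignette describes each method, its assumptions, the parameters that
matter, the numerical choices made where the procedure left room, and what
the synthetic benchmarks do and do not demonstrate about real data.

## Conventions

Images are numeric matrices indexed `[row, col]` with 1-based indices and
pixel centres at integer coordinates — the native R convention. All physical
distances are Euclidean pixel distances multiplied by the pixel size in
µm (`CalibratedImage` carries the calibration; areas scale with its square).
Pixels are assumed isotropic; anisotropic calibrations are rejected rather
than silently averaged. Calibration comes from the caller or configuration,
never from TIFF metadata, because metadata dialects are too inconsistent to
trust silently.

## Gap analysis: maximal-circle packing of the network free space

The mesh size of the FRC network is summarized by greedily packing the free
space of a binarized network image with circles: at every step the largest
circle that (a) contains no network pixel strictly inside it, (b) lies
within the image bounds, and (c) does not overlap a previously fitted
circle is added, until no feasible circle of radius at least `rMinPx`
remains. The radius distribution above a reporting threshold (12 µm by
default, strictly greater) is the assay readout; a stretched network has
larger gaps and a right-shifted distribution.

Design choices worth stating explicitly:

* **Feasible radius.** The feasible radius at a pixel centre equals its
  Euclidean distance to the nearest network pixel centre, computed by an
  exact distance transform with a virtual one-pixel foreground ring outside
  the image (circles may touch, but not cross, the image border).
* **Touching is allowed.** A network pixel exactly on a circle's boundary is
  not an incursion, and two circles may touch (centre distance equal to the
  radius sum). Without this convention the supremum radius is never
  attained and no discrete packing exists; with it the distance-transform
  value is itself the feasible radius.
* **Overlap is continuous geometry.** Non-overlap between circles is
  checked on centre distances and real radii, not on rasterized discs,
  which removes raster ambiguity at tangency.
* **Tie-break.** Among equally large feasible circles the smallest
  `(row, col)` in lexicographic order wins, making the output deterministic
  and exactly reproducible by an independent brute-force implementation.
  The test suite holds the packing to *exact* equality (centres, radii,
  order) with such an oracle on hundreds of random masks.
* **Thresholded readout.** The median over *all* fitted circles is not a
  monotone measure of mesh size: coarser meshes leave more free area, which
  fills with many circles near `rMinPx`, dragging the median down. The
  assay's own readout — the distribution of radii strictly above the
  reporting threshold — is monotone, and because the greedy sequence is
  radius-ordered it is identical for any `rMinPx` at or below the
  threshold. Analyses that only need the reported distribution can
  therefore fit with `rMinPx` equal to the threshold as an exact shortcut.

Binarization defaults to Otsu's threshold on a lightly smoothed copy
(`smoothSigma = 0.5` px). The light smoothing suppresses shot noise without
widening thin fibers; heavier smoothing visibly thickens the binarized
network and degrades agreement with the generator's ground-truth mask.
A constant image has no data-driven threshold and is returned as
all-background with a degenerate flag rather than an error.

## T cell packing density

Nuclei in a single z-plane are counted after a despeckle (3×3 median) and a
Gaussian blur of sigma 2 px, segmented by Otsu thresholding followed by a
watershed on the Euclidean distance transform (`peakMinDistancePx` controls
the seed neighbourhood, roughly one expected nucleus diameter), and filtered
by a minimum area (default: a quarter of the median component area, derived
from the image itself). Detections whose centroid falls inside the stromal
(PDPN^+) mask are cleared — the centroid rule is declared, since "inside the
stain" is otherwise ambiguous — and the packing density is the kept count
per 100 µm² of ROI area. The denominator is the full ROI area by default;
subtracting the masked area instead is available (`excludeMaskFromArea`)
and the choice is recorded in the output.

## Laser-ablation recoil

Tissue tension is probed by cutting the network and watching it recoil.
The measurement is the separation between two landmarks straddling the cut,
referenced to the mean pre-cut separation (a single-frame baseline is
available), sampled on a 0.521 s frame grid over 25 s. The initial recoil
velocity — displacement at the first post-cut frame divided by the frame
interval — is the tension proxy; it is invariant to rigid translation of
both landmarks and linear in the recoil amplitude. Cohorts are summarized
by pointwise mean ± SEM curves aligned at the first post-cut frame.

A saturating exponential `d(t) = A(1 − e^{−t/τ})` may be fitted to the
post-cut displacement by nonlinear least squares. The fit is provided for
smoothing and recovery checks, not as the primary readout; a flat trace has
an unidentifiable τ and is flagged rather than fitted. The synthetic recoil
generator uses the same functional form, with default amplitude 1.372 µm
and τ = 3 s chosen so the noise-free initial recoil velocity on the
0.521 s grid is 0.42 µm/s, the steady-state tension regime of the assay the
generator emulates; lower- and higher-tension arms (0.30 and 0.71 µm/s) are
obtained by scaling the amplitude.

## Optical-trap tether force

Membrane tension is probed by pulling a tether with an optically trapped
bead. Trap stiffness is calibrated by equipartition: for a stationary
trapped bead, `k = k_B T / Var(x)` with `k_B = 0.0138065` pN·nm/K and
T defaulting to 310.15 K. Equipartition is the calibration that a 90 ms
sampling interval supports — power-spectral calibration needs sampling well
above the trap corner frequency, far beyond this grid. The calibration
window must be tether-free; at least 100 samples are required and a
constant trace is rejected.

The tether step is located by maximizing a two-sample t-like statistic over
candidate change points (binary segmentation); a guard band around the step
is excluded from both windows, a trace with no significant step is flagged
rather than forced, and when several steps are present the earliest is
used and the result flagged multi-step. The force is `F_T = kΔx` with `Δx`
the absolute difference of windowed mean positions — pN/nm × nm = pN,
exactly. The result carries `k` and `Δx` separately so any downstream
normalization can be recomputed; no normalization by tether length or bead
size is applied, since none is well defined here.

The bead generator is an Ornstein–Uhlenbeck process integrated with the
exact discrete-time update (not Euler), so its stationary variance equals
`k_B T / k` at any sampling interval; the default stiffness is
0.114 pN/nm, a typical calibration value for this instrument class.

## Osmotic swelling

Hypotonic challenge makes a rounded cell swell; the readout is the diameter
ratio `d/d0` sampled every 30 s, the interpolated ratio at 15 min, and the
trapezoidal area under the curve over the first 20 min. The AUC integrand
is `ratio − 1` by default, so an isotonic control centres at zero; the
raw-ratio mode is available and the mode is recorded in every summary,
since either convention is defensible and neither is asserted as canonical.
Osmolarity bookkeeping (isotonic recipe, the 1/6 dilution giving 50 mOsm,
the mannitol-restored 330 mOsm control) lives in condition labels, not in
computed chemistry. The generator's ratio kinetics are exponential
saturation to a plateau, so the AUC has a closed form the tests check
against.

## Contractile-fiber scoring

Hand-drawn F-actin fiber polylines are widened to a 3 px sampling band. A
fiber is *in network* when at least half its sampled pixels fall inside the
stromal mask; scoring is defined only for in-network fibers. A channel call
(pMLC positivity) is background-relative: positive when the fiber's mean
intensity exceeds the background mean by two background SDs, where the
background is taken from in-network pixels not covered by any fiber, per
image. Matrix (perlecan) *alignment* additionally requires at least half
the fiber's pixels to lie over matrix-positive pixels — "aligned" is not
operationally defined in the source assay, so both the intensity and
overlap criteria are recorded per fiber. Background-relative thresholds
make all calls invariant to uniform intensity rescaling. Percentages are
reported over in-network fibers only.

## Proliferation tracking

Nuclei detections over a 72 h movie are linked by greedy nearest-neighbour
matching (candidate pairs accepted in order of distance within
`maxDispPx`), with consecutive-frame links taking precedence over
single-frame gap closure — gap closure competes only for leftover
detections, which prevents a terminated track from stealing a live track's
detection. A division is a track that terminates while at least two new
tracks begin within `searchRadiusPx` of its last position on the next
frame (or one later), each persisting at least three frames; the two
nearest births are the daughters, each consumed by at most one event. A
birth with no terminating parent nearby is an entering cell, never a
division. Divisions per cell normalizes event counts by the starting
nucleus count, fixed at the first frame.

The movie generator encodes the observability constraints this detector
needs, as physical rules: nuclei keep a minimum pairwise separation
(excluded volume, 10 px) so track identities stay unambiguous; daughters
appear on opposite sides of the parent's last detected position at 8 px —
beyond the linking radius, so a division reads as a termination plus two
births rather than a small displacement; a cell divides only when no other
cell is within a clearance radius (28 px), and a blocked mitosis is
*postponed*, not abandoned, so the realized division count tracks the
nominal rate; daughters inherit a 10 h refractory period (cell cycle), and
no divisions occur in the last three frames, where a daughter track could
not be observed long enough to count. In the single-division regime
(refractory longer than the movie) these constraints never bind and the
event count matches the age-structured branching expectation exactly; with
re-division, postponement makes realized counts fall slightly below the
unconstrained expectation, which the tests bracket rather than ignore.

The per-substrate division rates shipped as `substrateDivisionRates`
(0.006, 0.015, 0.032, 0.080 divisions per cell per hour for 2 kPa, 12 kPa,
30 kPa and glass) encode a steep stiffness dependence — near proliferative
arrest on the softest gel versus roughly 1.3 divisions per cell over 72 h
on glass. The geometric spacing is deliberate: with 100 starting nuclei
per condition, division counts carry Poisson-scale noise, and recovering
the full four-condition ordering in at least 95% of cohort replicates
requires neighbouring conditions to differ by more than twice the counting
SD. Arithmetically spaced rates do not satisfy that at this cohort size —
no analysis could separate them reliably — so the cohort conditions were
chosen geometrically, matching the strong qualitative stiffness effect
they emulate. The ordering benchmark runs on a 1024 px field (a full ×20
camera frame), where crowding-induced postponement stays mild.

## What the synthetic benchmarks show — and what they do not

Every generator is a pure function of its truth parameters and seed, emits
its exact ground truth, and writes plain-text outputs (TIFF/CSV/JSON). The
benchmarks demonstrate that each quantification recovers known truth under
a controlled noise model: Gaussian-profile nuclei with additive Gaussian
noise, Poisson-plus-read-noise fiber rendering on a jittered square
lattice, exponential recoil with additive noise, exact OU bead dynamics,
random-walk nuclei with planted divisions. They do not emulate uneven
illumination, out-of-focus light, stain variability, touching nuclei in
dense tissue, curved fibers, photobleaching, or tracking through cell
contact — on real data the thresholds (`peakMinDistancePx`, fiber width,
`maxDispPx`, `searchRadiusPx`) must be set against the data, and the
provenance fields in every result exist so those settings travel with the
numbers.

## Numerical notes

Problem sizes in the test suite are chosen to exercise each stage
meaningfully while keeping the whole suite to a few minutes: oracle
equivalence on 200 random masks up to 64×64, 20 nuclei fields of 40 nuclei,
100-seed recoil recovery, 200 ten-thousand-sample calibration traces, 100
cohort replicates for each ordering property. Degenerate inputs follow one
rule throughout: an input that cannot carry the measurement (constant
image, flat trace, zero-area ROI, empty free space) produces an empty
result or a flagged result where that is scientifically meaningful, and an
error only where proceeding would silently fabricate a number.
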