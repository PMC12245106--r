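---
title: "Methods: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidscreen)
```

# The platform in one paragraph

An inverted colloidal crystal (iCC) scaffold is the negative replica of a
close-packed assembly of soft microgels: spherical voids where the gels sat,
circular channels where neighbouring gels pressed into each other. Seeded
tumour cells condense into one spheroid per void, so a single hydrogel disc
carries thousands of uniform spheroids in a hexagonal-close-packed (HCP)
array. Drug response is read out either at high throughput (a plate reader
scanning a grid of points per well) or at high content (three-channel
two-photon volumes — scaffold, live, dead — processed into per-spheroid
viabilities). This package implements the quantitative machinery of that
platform: the contact-mechanics model that links gel stiffness to channel
diameter, the packing arithmetic behind the throughput numbers, both
readout pipelines, Hill dose-response fitting, and a synthetic-data
generator that provides ground truth for all of it.

# Microgel contact mechanics

Soft elastic microgels settling under gravity flatten at their contacts.
The force balance between gravity, buoyancy and the elastic contact
stress reduces to a quartic in the half centre-to-centre distance
$x = D_i/2$, with $a = R/2$ (R the microgel diameter):

$$x^4 - a x^3 - 3a^2x^2 + 5a^3x - 2a^4(1-\lambda) = 0,$$

where the load group is $\lambda = \rho_w C_{alg} g / E_c$ up to a
variant-dependent prefactor ($2\rho_w C_{alg} g/E_c$ or
$\rho_w C_{alg} g/(3E_c)$; both printed variants are implemented, and which
applies to which assembly configuration is left to the user). Two facts
anchor the implementation:

* at $\lambda = 0$ the quartic factors exactly as $(x-a)^3(x+2a)$ — rigid
  spheres touch at $D_i = R$; the physical root is the perturbation of the
  triple root, $D_i/R \approx 1 - (2\lambda/3)^{1/3}$;
* the contact disc (the future channel) has diameter
  $R_{cap} = \sqrt{R^2 - D_i^2}$, so $R_{cap}^2 + D_i^2 = R^2$ always.

**Numerical choices.** The root is found by bracketed `uniroot` on
$[a(1 - 2(2\lambda)^{1/3}),\, a]$ — the perturbation expansion guarantees a
sign change there — followed by one Newton polish; the residual contract is
$|q(x)| < 10^{-10}a^4$. A load too large for a root in $(0, a]$ raises a
model-domain error rather than returning the unphysical $-2a$ root.

**A units caveat, prominently.** The printed load group
$\rho_w C_{alg} g / E_c$ carries units of 1/m in SI; the derivation that
nondimensionalises it is not part of the model as stated. The package
evaluates the printed expression with SI base values inserted literally and
treats the number as $\lambda$. `solve_contact_distance()` accepts a bare
`lambda` so any alternative nondimensionalisation can be applied upstream.
With that convention, the predicted cap diameter for the stiffest batch
(3.0% w/v, $E_c$ = 2.156 MPa, R = 253.3 um) lands in the measured
45 ± 17 um per-pair band, but a point model cannot be expected to match a
per-pair average more closely — the cap transform is nonlinear, and
`hcp_lattice_metrics()` reports both the mean of per-pair caps and the cap
of the mean distance to make that gap visible.

The compressive modulus feeding $\lambda$ is the ordinary-least-squares
slope (with intercept, slope reported) of the first 11 points of the
stress-strain curve — the small-strain linear regime.

# Packing arithmetic

Void counts use explicit hexagonal-lattice enumeration: positions with
pitch equal to the void diameter, keeping circles entirely inside the
container (centres within radius $(D-d)/2$, because a void cannot breach
the dish wall). The default registration places one void at the container
centre with rows along x — deterministic and reproducible. Because the
registration of a real assembly is not controlled, a
`best-of-translations` mode maximises the count over a grid of lattice
offsets; for 250 um voids in a 15 mm dish the two registrations differ by
well under 1%. Successive layers alternate the A/B in-plane offset of HCP
with spacing $p\sqrt{2/3}$. The ideal packing fraction $\pi/(3\sqrt2)
\approx 0.7405$ (the familiar "74% porosity" once inverted) and the number
density $\sqrt2/d^3$ are reported as closed forms, not estimated.

# The synthetic-data generator

The generator is the package's ground-truth instrument; its defaults are
the platform's study conditions, chosen once:

* void diameter 250 um, five layers, channels ~40-45 um;
* spheroid diameters normal with cell-line means/SDs (HepG2
  179.2 ± 9.76 um is the default);
* doses {0, 10, 20, 50, 100, 200} uM; viability follows a Hill curve in
  dose, with the platform-reported (IC50, n) pairs as defaults;
* intensities 12-bit-like (plateau ~3000 a.u.) so the conventional
  ">2000 a.u." scaffold gate is meaningful; noise is Poisson shot noise
  (gain 1) plus additive Gaussian (SD 50 a.u.);
* voxels 5 um isotropic: 50 voxels across a void, volumes well under a
  gigabyte at the sizes used here;
* well-scans are 6x6 grids, 4 wells per dose; the scaffold punch covers
  all but the four grid corners, so 32 of 36 points are in-framework.

Dead voxels are placed uniformly at random inside each spheroid (the
scoring is count-based, not spatially weighted), each voxel dead with
probability $1 - v(\text{dose})$; the realised binomial dead fraction is
recorded alongside the expected one, so closure tests can separate
measurement error from sampling noise. Everything is bit-reproducible
given (parameters, seed).

What the generator does *not* emulate — and therefore what passing closure
tests do not establish about real data: optical point-spread blur and
depth-dependent attenuation, bleed-through between channels, core/rim
death structure (a `rim-death`-style geometry can be approximated by
supplying per-spheroid viabilities directly), irregular spheroid shapes,
partially filled voids, and autofluorescence. The pipeline's accuracy on
real two-photon volumes is bounded below by its accuracy here.

# High-content pipeline design

**Void detection** is smoothed-minimum peak finding, not Hough spheres:
voids are dark, quasi-periodic, and their diameter is known a priori. The
green channel is stride-subsampled so a void spans ~16 voxels, Gaussian
smoothed (sigma of a tenth of a void), and local minima within a box of
~0.7 void radii are kept if darker than the Otsu split of the smoothed
channel, then greedily deduplicated at half the expected diameter (darkest
first — the tie-break). Centre precision of a few coarse voxels is ample:
all downstream steps tolerate offsets up to half a void radius.

**Segmentation** merges red and blue with a voxelwise OR (their maximum)
and thresholds, so the contour is independent of the live/dead split; the
largest 6-connected component inside the spherical ROI is kept. Masks
smaller than ~33 voxels (a 4-voxel-diameter sphere) are flagged
`"no spheroid"` — a flag, never an exception, so one empty void cannot
abort a run.

**Thresholding.** Standalone `segment_spheroid()` defaults to Otsu on its
own subvolume, which is correct whenever a spheroid is present (the
histogram is bimodal). The composed pipeline instead computes one global
Otsu threshold on the OR-merged channel of the whole volume and applies it
to every ROI. The reason is a failure mode found during development: an
*empty* void's subvolume contains only the noise floor, Otsu then splits
the noise itself, marks about half the voxels as foreground, and at that
occupancy the 6-connected noise percolates into a single giant component
that masquerades as a spheroid. A volume-wide histogram always contains
both true classes, so the global threshold is stable. The same threshold
is reused for the dead call (`red > threshold`), for the same reason: red
within an all-live mask is unimodal noise. A fixed numeric threshold can
be supplied to both functions to bypass Otsu entirely.

**Viability** is $1 - \text{dead voxels}/\text{contour voxels}$ — a
voxel-based, not cell-based, quantity, which is the documented convention
throughout.

**Diameter** is the maximum over z of the per-slice equivalent-circle
diameter $2\sqrt{A_z/\pi}$ — the equatorial slice of a sphere —
which is robust to ragged slice boundaries in a way a caliper diameter is
not. Expected digitisation bias at 5 um voxels is below one voxel.

# High-throughput pipeline design

Scan points are retained only if their scaffold intensity is *strictly*
greater than the gate (default 2000 a.u.); the strictness is a documented
boundary convention. The raw per-point $FI_{red}/FI_{blue}$ ratio
accumulates over the scanned *volume*, while the natural response scale is
an *area*; the correction maps one to the other through the sphere
volume-to-great-circle identity

$$\left(\frac{FI_{red}}{FI_{blue}}\right)_{corr}
  = \pi\left(\frac{3\,r_{raw}}{4\pi}\right)^{2/3},$$

which is monotone, concave, exactly 0 at 0 and exactly $\pi$ at $4\pi/3$.
Corrected ratios are histogrammed (Freedman-Diaconis bin width with a
10-bin floor; the histogramming choice is not prescribed anywhere, so a
robust default was chosen) and fitted with a Gaussian by nonlinear least
squares; if the fit fails the sample moments are used and flagged, and a
converged fit explaining under 90% of the count variance is flagged
`poor-fit` (bimodal inputs land here). For the Hill fit the per-dose means
are inverted back to a viability estimate,
$v = 1/(1 + r_{raw})$ with $r_{raw}$ from the inverse correction,
normalised to the zero-dose level, and fitted with the two-parameter Hill
model. Fitting the corrected-ratio means directly with the four-parameter
model is available (`normalize = FALSE`); the normalised mode is the
default because it maps onto the same [0, 1] response scale as the
high-content path, making the two routes directly comparable.

# Hill fitting

The model is $b + (t-b)/(1 + (d/IC_{50})^n)$, evaluated in the power form
so dose 0 gives the top asymptote exactly (no log-dose transform, no
log(0)). Hill least-squares surfaces are multimodal at small n, so the fit
multi-starts over a geometric grid of seven IC50 seeds spanning
[min positive dose/3, 3 x max dose] crossed with $n \in \{0.5, 1, 2, 4\}$,
keeps the lowest converged SSE, and bounds $IC_{50} > 0$, $n > 0$. The
four-parameter fit (free asymptotes) is the default; the two-parameter
mode (top 1, bottom 0) is for responses already normalised to dose 0. R²
is reported against total variance, an IC50 outside the dose range is
flagged extrapolated, and constant responses are rejected as degenerate
rather than fitted. Fits are scale-equivariant: scaling doses by c scales
the fitted IC50 by c and leaves n unchanged (tested at c = 10).

ROC AUC uses the rank (Mann-Whitney) formulation with ties counted half,
verified against brute-force pair counting.

# Histology

Stain separation is standard optical-density unmixing:
$OD = -\log((I+\varepsilon)/\text{white})$ with $\varepsilon = 1/255$ and
a per-channel image-maximum white point unless supplied, projected through
the stain basis by least squares and clipped at zero. The default basis is
the package's aniline-blue / acid-fuchsin pair for Masson's trichrome;
no vector set is canonical for this protocol, so the basis is overridable
and results on real slides are explicitly vector-dependent. The
correlation readout is plain Pearson's R between the two concentration
channels, with a zero-variance guard, plus a joint histogram whose
count-weighted bin-centre correlation reproduces R up to discretisation.

# Problem sizes and test design

The suite's simulation sizes are chosen so closure is tight but cheap:
seven-void single-layer volumes (~160^2 x 62 voxels) for unit closure,
~50-void volumes for detection precision/recall, a 100-spheroid volume
(~580^2 x 62 voxels, 5 um voxels) for diameter-distribution recovery, ten
replicate seeds of 250 spheroids per dose for Hill parameter recovery, and
4 wells x 36 points for the plate-reader route. The whole suite runs in
about a minute; the acceptance script in about half a minute.

# Known limitations

* The nondimensionalisation of the contact load is conventional (see
  above); absolute $D_i/R$ predictions inherit that convention.
* Registration of a real assembly against the dish is uncontrolled; the
  enumeration brackets it with the two registration modes rather than
  resolving it.
* The imaging model omits PSF, attenuation and bleed-through; thresholds
  tuned on synthetic volumes (global Otsu) should be re-examined on real
  stacks, and a fixed-threshold override is provided for exactly that.
* The plate-reader inverse mapping assumes blue ~ live volume and red ~
  dead volume with a common proportionality; instrument-specific gains
  break the absolute ratio but not the normalised dose-response shape.
* Abort-level disagreements in the platform's own throughput bookkeeping
  (e.g. per-uL density vs per-well counts) are documented where they
  arise rather than reconciled; the package reports the geometric
  quantities it can compute.
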