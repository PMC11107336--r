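---
title: "Simulating scanning darkfield fiber-bundle microendoscopy"
author: "fiberScopeSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating scanning darkfield fiber-bundle microendoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the physics it simulates, the
choices behind its defaults, and what its tests do and do not establish.

## The imaging problem

A coherent fiber bundle pressed against stained epithelium relays a
microscopic image of the tissue surface. Two stains are modeled: an
absorbing nuclear dye (methylene blue; nuclei dark in reflectance) and a
fluorescent nuclear dye (proflavine; nuclei bright in emission). The
band-limited optics are reduced to scalar effective coefficients — there
is no per-wavelength rendering.

Reflectance imaging through a bundle suffers from specular reflection at
the fiber's proximal and distal surfaces. In non-scanning widefield mode
the illuminated and detected regions coincide, so this reflection lands
directly on the detector and adds a large offset to every pixel. Weber
contrast `C = |μ_bg − μ_fg|/μ_bg` is offset-sensitive, so the specular
floor directly erodes the visibility of dark nuclei. Scanning darkfield
mode steps a pair of illumination lines down the field in sync with the
sensor's rolling-shutter detection band, keeping illumination and
detection disjoint at every instant; the mirror-like (non-spreading)
specular component then never reaches the detection band, while light
scattered laterally inside the tissue does.

## Forward model

### Phantom

Nucleus centres follow a Matérn-style hard-core process: a Poisson number
of candidates (`density_per_mm2`, default 820/mm²) is placed by dart
throwing, rejecting candidates closer than `min_spacing_um` (default
18 μm) to an accepted centre. This emulates the regular spacing of
healthy epithelial nuclei; with `min_spacing_um = 0` the process reduces
to plain Poisson, which the tests exploit as a statistical oracle. Sizes
are lognormal (mean radius 4 μm, CV 0.1), shapes are ellipses with
eccentricity ≤ 0.3 and uniform orientation, and per-nucleus stain uptake
is drawn near 0.9 so nuclei are bright/dark to slightly varying degrees.
The defaults put roughly 350–450 nuclei inside the 790 μm FOV; they are
conventions of this package, chosen to be plausible for flat epithelium,
not measurements.

Maps are rendered at 1 μm pitch with 4×4 supersampling of the ellipse
indicator, so edge pixels carry fractional coverage and the integrated
stain mass matches the analytic ellipse areas to well under 1%.
Absorption is stored as single-pass optical depth; the epi-illumination
double pass is applied at acquisition time (`exp(-2τ)`), keeping the
phantom itself physics-agnostic.

### Fiber bundle

Cores form a hexagonal lattice (pitch 4.5 μm, core radius 1.6 μm)
clipped to the circular FOV — about 28k cores at 790 μm, consistent with
the probe family the geometry is modeled after; the true pitch and
cladding transmission of any specific probe are not public, so all
asserted properties are parameter-relative. Each core integrates the
tissue-side field over its disk; rasterization assigns core pixels the
core value and inter-core pixels `cladding_level` (default 0.15) times
the nearest core's value, which creates the honeycomb pattern with its
spectral power concentrated at the lattice fundamental `2/(√3·pitch)`
cycles/μm. Inter-core crosstalk and per-core throughput heterogeneity
are not modeled (a single scalar `fill_transmission` is the hook).

One deliberate artifact of pixel-centre rasterization: where the lattice
row phase aligns with the pixel grid, faint horizontal moiré bands
appear. They are handled on the analysis side (below) rather than hidden
by smoothing, because real bundle images contain comparable structured
residue.

### Acquisition

Per-pixel signal before noise, at illumination level `L` (counts per
unit return):

- widefield reflectance: `L·(ε·R_spec + tissue + b₀)`
- darkfield, detection-band rows: `L·(tissue·e(row) + b₀·ε)`
- fluorescence: `L·fluorescence_map` (the emission filter blocks both
  the specular term and the stray reflection `b₀`)

with `tissue = ρ·exp(-2τ)` for reflectance. The specular term is
strictly local to illuminated rows, so in darkfield it can only appear
on illumination∩detection overlap — which the `ScanSequence` validator
precludes; rejection is therefore *exact*, an identity the tests assert
for `R_spec` spanning four orders of magnitude.

`e(row)` is the effective illumination reaching a row from the step's
line pair: the line indicator convolved along rows with a
boundary-renormalized Gaussian of width `scatterSigma` (default 30 μm,
the isotropic subsurface-scattering spread), then divided by the
indicator's sensor mean. The normalization is chosen so that the
infinite-width limit gives exactly uniform unit illumination for every
step — including edge steps that carry a single flanking line — making
"darkfield with infinite scatter width equals widefield with
`R_spec = 0`" an exact identity rather than an approximation. This is
the package's convention; the physical instrument does not calibrate its
line intensity this way, and the finite-width default produces a few
percent of smooth intra-band scalloping, which is retained as a
realistic nuisance.

Line geometry follows the schematic interpretation of two lines flanking
the detection band symmetrically (band 16 rows, offset 4, line width 8
by default); the real system's line width, step count and offset are not
published, so all are configuration. Time is abstracted to the scan-step
index — no wall-clock shutter simulation.

Defaults for the specular path are set from the qualitative regime the
instrument was built to escape: `R_spec = 20` with polarization leakage
`ε = 0.1` puts the leaked specular background (`ε·R_spec = 2`) about
three times above the diffuse tissue return (`ρ = 0.6`), so widefield
images are visibly flooded while staying just inside the 12-bit range at
`L = 1500`. Noise is Poisson shot noise (gain 1 e⁻/count) plus Gaussian
read noise (3 counts), then clipping and half-up rounding.

### Restoration

The chain — Gaussian honeycomb removal, linear brightness adjustment to
a common mean, contrast-limited adaptive histogram equalization — is
applied with byte-identical parameters to all three modes, and the
processing log proves it (`params` column identical across modes;
measured per-image factors live in a separate `applied` column).

Numerical choices:

- The Gaussian filter runs as normalized convolution inside the circular
  FOV so the dark exterior cannot bleed inward; the kernel is truncated
  at 5σ because at the lattice fundamental the attenuation is ≈ −57 dB
  and a 3σ truncation misses that by several dB.
- Default σ = pitch/2 (2.25 μm): suppresses the lattice fundamental by
  ~57 dB while preserving ≥ 5 μm structures. Brightness target 0.4.
- Equalization uses EBImage's CLAHE parameterization (`limit = 2`,
  8×8 tiles); out-of-FOV pixels are filled with the in-FOV mean before
  equalization and re-zeroed after, so edge tiles are not dominated by
  the exterior.
- Processing is float in [0, 1]; quantization only at export.

### Detection and metrics

Nuclei are detected by multiscale scale-normalized Laplacian of Gaussian
(5 log-spaced radii over 2.5–6.5 μm), on the inverted image for dark
polarity so one detector serves both stains, with greedy non-maximum
suppression at one radius. The candidate mask is eroded by the maximum
radius: the FOV rim is a huge intensity step whose response would
otherwise dominate, and a blob centre closer than a radius to the rim is
not measurable anyway.

Equalization deliberately stretches local contrast, and shot noise
through the bundle is correlated at the core scale (one noisy value per
core disk), so noise bumps in dim background reach blob scale. Peak
picking on the equalized image therefore cannot separate modes at one
threshold, and each candidate is confirmed photometrically on the
*linear* restored image: the blob core must differ from its annulus in
the requested polarity by an absolute floor (0.02) and by at least 5
local noise standard deviations. The noise estimate removes a
quadratic-in-row trend first (the scan's smooth intra-band scalloping is
deterministic structure, not noise), and the contrast is taken as the
weaker of the same-row and same-column directional contrasts, which
cancels stripe-shaped raster artifacts (scalloping, lattice moiré) while
leaving isotropic nuclei untouched.

Weber contrast and SNR are computed on the linear restored image
(honeycomb-removed, brightness-normalized, *before* equalization):
equalization is a nonlinear local remap that would destroy the
offset-sensitivity that makes Weber contrast the right metric for
specular degradation, and brightness normalization is a pure scale that
leaves Weber contrast invariant. Detection runs on the fully processed
image; metrics run on the linear one. Both are carried in the
`ProcessedImage` object.

Counting uses a centred 5×5 grid of 25 identical 100 μm ROIs (half-open
rectangles, so shared edges count once) with mean and sample (n−1) sd.
Precision is scored against the complete truth list; recall against
nuclei at least 13 μm (twice the maximum detection radius) inside the
FOV, the population whose blob and local annulus are fully measurable.

## What the tests show — and what they do not

The phantoms are flat fields of well-separated, nearly uniform nuclei:
the regime of healthy epithelium. Passing tests show the instrument
model is self-consistent (exact rejection, cross-mode oracles, coverage
audits), that its statistical components match their stated
distributions, and that on such phantoms darkfield counting agrees with
fluorescence counting within a few percent while widefield fails — the
qualitative behaviour the real instrument exhibits on tissue. They do
not show performance on real tissue: no nuclear pleomorphism or crowding,
no depth structure, no motion, no staining heterogeneity beyond a scalar
uptake, no per-core throughput variation, no speckle. Problem sizes in
the test suite (full 790 μm FOV at 1 μm pitch for acceptance properties;
smaller 120–256 μm fields for unit tests; 3–10 seeds per statistical
property) were chosen to make each property resolvable with comfortable
margin on a single CPU.

## Known limitations

- The line-pair interpretation (two symmetric flanks) and the
  illumination normalization are modeling conventions; the published
  system description does not specify them.
- `b₀` enters widefield unattenuated but darkfield through the leakage
  factor, mirroring the asymmetric physical paths (direct stray vs
  leaked stray); with background subtraction configured the distinction
  disappears.
- Fluorescence and reflectance share one illumination level; a real
  operator would expose each mode separately.
- The moiré bands of pixel-centre rasterization are an artifact of the
  renderer, not of real bundles, though real bundles show analogous
  structured residue from core irregularity (which is not modeled).
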