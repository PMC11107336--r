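# fiberScopeSim

A digital twin of a scanning darkfield fiber-bundle microendoscope, for
developing and validating image restoration and nuclei-quantification
pipelines without access to the physical instrument or tissue.

## The problem

High-resolution fiber-optic microendoscopes image epithelial cell nuclei
*in vivo* by pressing a coherent fiber bundle against stained tissue.
With an absorbing nuclear stain (methylene blue), nuclei should appear as
dark dots in reflectance — but the fiber surfaces reflect a large
specular background straight into the detector, flooding widefield
reflectance images. Scanning darkfield imaging fixes this digitally: a
sequence of illumination **line pairs** is projected while the sensor's
**rolling shutter** acts as a moving detection band kept spatially
disjoint from the illuminated lines, so mirror-like reflections never
reach the detector and only light scattered inside the tissue is
collected.

This package simulates that instrument end to end on synthetic phantoms
with known ground truth:

- **phantom** — stained-epithelium phantoms: a hard-core point process of
  elliptical nuclei with co-registered absorption (optical depth),
  fluorescence-yield and diffuse-reflectance maps on a micrometre grid.
- **fiber bundle** — hexagonal core lattice clipped to a circular FOV
  (790 μm default, ~28k cores), per-core signal integration, and the
  honeycomb raster of relayed images.
- **acquisition** — frame formation in three modes (widefield
  reflectance, scanning darkfield, fluorescence) with double-pass
  Beer–Lambert stain contrast `exp(-2τ)`, specular reflection `R_spec`,
  polarization leakage `ε`, stray background `b₀`, Poisson shot noise and
  Gaussian read noise, 12-bit quantization. Darkfield frames are
  assembled band by band from a validated `ScanSequence`; for disjoint
  apertures the specular term is rejected *exactly*.
- **restore** — the matched restoration chain applied identically to all
  modes: Gaussian honeycomb removal (normalized convolution inside the
  FOV), linear brightness normalization, contrast-limited adaptive
  histogram equalization.
- **analyze** — multiscale Laplacian-of-Gaussian nuclei detection (dark
  or bright polarity), a 5×5 grid of 25 identical ROIs with mean ± sd
  counts, Weber contrast `C = |μ_bg − μ_fg| / μ_bg` and
  `SNR = |μ_bg − μ_fg| / σ_bg` against ground-truth masks, and one-to-one
  greedy matching for precision/recall.

## Worked example

```r
library(fiberScopeSim)

bundle  <- buildBundle()          # 790 um FOV, 4.5 um pitch
phantom <- makePhantom(seed = 7)  # ~400 nuclei inside the FOV
report  <- compareModes(phantom, bundle, seed = 7)
report
```

```
AnalysisReport
  widefield_reflectance  count   0.2 +/-  0.5 | Weber 0.088 | SNR   1.54
  darkfield              count   8.7 +/-  1.9 | Weber 0.260 | SNR   6.13
  fluorescence           count   8.8 +/-  2.1 | Weber 2.809 | SNR  19.51
  darkfield vs fluorescence count rel. diff: 0.909%
```

Reading the numbers: per-ROI nuclei counts (mean ± sd over the 25 ROIs)
in darkfield agree with fluorescence on the same phantom to within ~1%,
while the widefield image — identical tissue, identical processing — is
so flooded by the specular background (Weber contrast 0.09 vs 0.26) that
almost no nuclei survive detection. That is the ordering the scanning
darkfield design exists to produce.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/fiberscope.R simulate --seed 7 --out out/
Rscript inst/cli/fiberscope.R process  --input out/darkfield.tif --out out/
Rscript inst/cli/fiberscope.R compare  --seed 7 --out out/
```

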