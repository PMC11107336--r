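#' @import methods
#' @importFrom stats rnorm rpois runif sd convolve quantile
#' @importFrom utils write.csv read.csv
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' FiberBundle: coherent imaging fiber bundle geometry
#'
#' Hexagonal lattice of fiber cores clipped to a circular field of view
#' (FOV). The bundle defines how a continuous tissue-side field is sampled
#' into discrete per-core signals and how those signals are rasterized back
#' into the familiar honeycomb image. All lengths are tissue-referred
#' micrometres; the FOV is centred at the origin.
#'
#' @slot fovDiameter circular FOV diameter (um)
#' @slot corePitch   centre-to-centre spacing of adjacent cores (um)
#' @slot coreRadius  radius of a single core's collection disk (um)
#' @slot coreCenters n x 2 matrix of core centre coordinates (um)
#' @slot coreLattice n x 2 integer matrix of hexagonal lattice indices (i, j)
#'   used for fast nearest-core inversion
#' @slot fillTransmission relative throughput of the core area, in (0, 1]
#' @slot claddingLevel residual signal level between cores, in [0, 1]
#'
#' @exportClass FiberBundle
setClass("FiberBundle",
  representation(
    fovDiameter = "numeric",
    corePitch = "numeric",
    coreRadius = "numeric",
    coreCenters = "matrix",
    coreLattice = "matrix",
    fillTransmission = "numeric",
    claddingLevel = "numeric"
  )
)

setValidity("FiberBundle", function(object) {
  msg <- character()
  if (object@corePitch <= 0 || object@coreRadius <= 0)
    msg <- c(msg, "corePitch and coreRadius must be positive")
  if (2 * object@coreRadius >= object@corePitch)
    msg <- c(msg, "core diameter must be smaller than core pitch")
  if (object@fillTransmission <= 0 || object@fillTransmission > 1)
    msg <- c(msg, "fillTransmission must be in (0, 1]")
  if (object@claddingLevel < 0 || object@claddingLevel > 1)
    msg <- c(msg, "claddingLevel must be in [0, 1]")
  if (nrow(object@coreCenters) > 0) {
    r <- sqrt(rowSums(object@coreCenters^2))
    if (any(r > object@fovDiameter / 2 - object@coreRadius + 1e-9))
      msg <- c(msg, "all core centres must lie within fovDiameter/2 - coreRadius")
  }
  if (length(msg)) msg else TRUE
})

#' Phantom: synthetic stained-epithelium ground truth
#'
#' Co-registered scalar fields on a common micrometre grid plus the exact
#' generative list of nuclei. The absorption map holds single-pass optical
#' depth (dimensionless); the fluorescence map holds relative emission
#' yield; the diffuse reflectance map is the stain-free tissue albedo in
#' [0, 1]. Grids are row-major with pixel centres at (k - 0.5) * pitch
#' offsets from the field corner; the origin sits at the field centre.
#'
#' @slot nuclei data.frame with columns x_um, y_um, a_um, b_um, theta_rad,
#'   uptake -- one row per nucleus (the generative ground truth)
#' @slot absorptionMap single-pass optical depth per pixel (>= 0)
#' @slot fluorescenceMap relative fluorescence emission yield per pixel
#' @slot reflectanceMap diffuse reflectance per pixel, in [0, 1]
#' @slot pixelPitch grid pixel pitch (um)
#' @slot fieldExtent square field side length (um)
#' @slot seed RNG seed used to generate the nuclei
#'
#' @exportClass Phantom
setClass("Phantom",
  representation(
    nuclei = "data.frame",
    absorptionMap = "matrix",
    fluorescenceMap = "matrix",
    reflectanceMap = "matrix",
    pixelPitch = "numeric",
    fieldExtent = "numeric",
    seed = "numeric"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  d <- dim(object@absorptionMap)
  if (!identical(d, dim(object@fluorescenceMap)) ||
      !identical(d, dim(object@reflectanceMap)))
    msg <- c(msg, "all maps must share one grid shape")
  if (any(object@absorptionMap < 0))
    msg <- c(msg, "absorptionMap must be non-negative")
  if (any(object@reflectanceMap < 0) || any(object@reflectanceMap > 1))
    msg <- c(msg, "reflectanceMap must be in [0, 1]")
  if (object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be positive")
  need <- c("x_um", "y_um", "a_um", "b_um", "theta_rad", "uptake")
  if (!all(need %in% names(object@nuclei)))
    msg <- c(msg, paste("nuclei must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ScanSequence: line-pair illumination / rolling-shutter detection schedule
#'
#' One row per scan step. Row coordinates are 0-based, half-open bands
#' [start, end) in sensor rows. Each step has one detection band and up to
#' two illumination lines flanking it (NA marks a line dropped at a sensor
#' edge). Valid sequences tile the sensor with detection bands exactly once
#' and keep every illumination line at least \code{offsetRows} away from the
#' step's detection band.
#'
#' @slot steps data.frame: step, det_start, det_end, ill1_start, ill1_end,
#'   ill2_start, ill2_end
#' @slot nRows sensor height (rows)
#' @slot bandHeight nominal detection band height (rows)
#' @slot offsetRows minimum guard gap between illumination and detection
#' @slot lineWidth illumination line width (rows)
#'
#' @exportClass ScanSequence
setClass("ScanSequence",
  representation(
    steps = "data.frame",
    nRows = "integer",
    bandHeight = "integer",
    offsetRows = "integer",
    lineWidth = "integer"
  )
)

setValidity("ScanSequence", function(object) {
  a <- auditScanSequence(object)
  if (a$ok) TRUE else a$message
})

#' AcquisitionConfig: frame-formation parameters for one imaging mode
#'
#' @slot mode one of "widefield_reflectance", "darkfield", "fluorescence"
#' @slot rSpec combined proximal+distal fiber-surface specular reflectance
#'   (dimensionless, relative to unit tissue illumination)
#' @slot leakage polarization leakage in [0, 1] multiplying specular/stray terms
#' @slot background residual post-polarizer stray level (same units as
#'   tissue reflectance)
#' @slot illumination illumination level L (detector counts per unit return)
#' @slot doublePass if TRUE, reflectance passes the absorbing stain twice
#'   (epi-illumination Beer-Lambert, exp(-2 tau))
#' @slot shotNoise enable Poisson shot noise
#' @slot readNoiseSd additive Gaussian read noise sd (counts)
#' @slot gain photoelectrons per detector count (shot-noise scaling)
#' @slot bitDepth ADC bit depth (linear, rounding half-up)
#' @slot scatterSigma width (um) of the isotropic subsurface-scattering
#'   kernel that spreads line illumination into the detection band
#'   (darkfield only); Inf means uniform spread
#' @slot seed RNG seed for the noise model
#'
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    mode = "character",
    rSpec = "numeric",
    leakage = "numeric",
    background = "numeric",
    illumination = "numeric",
    doublePass = "logical",
    shotNoise = "logical",
    readNoiseSd = "numeric",
    gain = "numeric",
    bitDepth = "integer",
    scatterSigma = "numeric",
    seed = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("widefield_reflectance", "darkfield", "fluorescence"))
    msg <- c(msg, "unknown mode")
  if (object@rSpec < 0) msg <- c(msg, "rSpec must be >= 0")
  if (object@leakage < 0 || object@leakage > 1)
    msg <- c(msg, "leakage must be in [0, 1]")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@bitDepth < 1L || object@bitDepth > 16L)
    msg <- c(msg, "bitDepth must be in 1..16")
  if (length(msg)) msg else TRUE
})

#' RawFrame: acquired sensor frame before restoration
#'
#' @slot pixels integer matrix of linear ADC counts in [0, 2^bitDepth - 1]
#' @slot mode imaging mode tag
#' @slot config the AcquisitionConfig snapshot that produced the frame
#' @slot pixelPitch tissue-referred pixel pitch (um)
#' @slot background optional paired background frame (counts) or NULL
#'
#' @exportClass RawFrame
setClass("RawFrame",
  representation(
    pixels = "matrix",
    mode = "character",
    config = "AcquisitionConfig",
    pixelPitch = "numeric",
    background = "matrixOrNULL"
  )
)

setValidity("RawFrame", function(object) {
  msg <- character()
  top <- 2^object@config@bitDepth - 1
  if (any(object@pixels < 0) || any(object@pixels > top))
    msg <- c(msg, "pixel values must lie in [0, 2^bitDepth - 1]")
  if (length(msg)) msg else TRUE
})

#' ProcessedImage: restored image with its processing log
#'
#' @slot pixels float raster in [0, 1]
#' @slot linear the restored image before adaptive histogram equalization
#'   (honeycomb removed, brightness normalized); photometric metrics such as
#'   Weber contrast are computed here because equalization is a nonlinear
#'   local remap
#' @slot log data.frame of applied operations (op, params), in order
#' @slot mode source imaging mode
#' @slot pixelPitch pixel pitch (um)
#' @slot mask logical in-FOV mask
#'
#' @exportClass ProcessedImage
setClass("ProcessedImage",
  representation(
    pixels = "matrix",
    linear = "matrix",
    log = "data.frame",
    mode = "character",
    pixelPitch = "numeric",
    mask = "matrix"
  )
)

setValidity("ProcessedImage", function(object) {
  msg <- character()
  if (any(object@pixels < -1e-9) || any(object@pixels > 1 + 1e-9))
    msg <- c(msg, "pixels must be in [0, 1]")
  if (nrow(object@log) < 1) msg <- c(msg, "processing log must be non-empty")
  if (!identical(dim(object@pixels), dim(object@mask)))
    msg <- c(msg, "mask shape must match pixels")
  if (length(msg)) msg else TRUE
})

#' RoiGrid: congruent disjoint regions of interest inside the FOV
#'
#' Rectangles are half-open: a point belongs to an ROI iff
#' xmin <= x < xmax and ymin <= y < ymax, so shared edges are counted once.
#'
#' @slot rects data.frame with xmin, ymin, xmax, ymax (um, FOV-centred)
#' @slot roiSize side length of each square ROI (um)
#'
#' @exportClass RoiGrid
setClass("RoiGrid",
  representation(rects = "data.frame", roiSize = "numeric")
)

setValidity("RoiGrid", function(object) {
  r <- object@rects
  msg <- character()
  if (!all(c("xmin", "ymin", "xmax", "ymax") %in% names(r)))
    return("rects must have xmin, ymin, xmax, ymax")
  if (any(r$xmax <= r$xmin) || any(r$ymax <= r$ymin))
    msg <- c(msg, "degenerate ROI rectangle")
  if (nrow(r) > 1) {
    for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
      if (r$xmin[i] < r$xmax[j] && r$xmin[j] < r$xmax[i] &&
          r$ymin[i] < r$ymax[j] && r$ymin[j] < r$ymax[i])
        msg <- c(msg, "ROIs must be pairwise disjoint")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' AnalysisReport: cross-mode comparison results
#'
#' @slot modes named list (per imaging mode) of detection tables, per-ROI
#'   counts, count mean and sd, Weber contrast, SNR, and optional
#'   precision/recall against ground truth
#' @slot agreement list with the darkfield-vs-fluorescence relative
#'   difference of ROI-count means and related summaries
#' @slot params list of the shared processing/analysis parameters
#'
#' @exportClass AnalysisReport
setClass("AnalysisReport",
  representation(modes = "list", agreement = "list", params = "list")
)
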