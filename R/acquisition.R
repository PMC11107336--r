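#' Acquisition configuration constructor
#'
#' Frame-formation parameters for one imaging mode. Defaults describe the
#' reference operating point: illumination scaled to 1500 detector counts
#' per unit tissue return at 12 bits, specular fiber-surface reflectance
#' well above the diffuse tissue signal (the regime in which widefield
#' reflectance images are flooded by specular background), 10% polarization
#' leakage and a small residual stray level.
#'
#' @param mode "widefield_reflectance", "darkfield" or "fluorescence"
#' @param rSpec combined fiber-surface specular reflectance (unitless)
#' @param leakage polarization leakage in [0, 1]
#' @param background residual post-polarizer stray level
#' @param illumination illumination level L (counts per unit return)
#' @param doublePass reflectance passes the absorbing stain twice
#' @param shotNoise enable Poisson shot noise
#' @param readNoiseSd Gaussian read noise sd (counts)
#' @param gain photoelectrons per count
#' @param bitDepth linear ADC bit depth
#' @param scatterSigma subsurface-scattering kernel width (um), darkfield
#'   spread of line illumination; Inf = uniform spread
#' @param seed RNG seed for the noise model
#' @return an [AcquisitionConfig-class] object
#' @export
acquisitionConfig <- function(mode = "darkfield", rSpec = 20, leakage = 0.1,
                              background = 0.02, illumination = 1500,
                              doublePass = TRUE, shotNoise = TRUE,
                              readNoiseSd = 3, gain = 1, bitDepth = 12L,
                              scatterSigma = 30, seed = 1) {
  new("AcquisitionConfig", mode = mode, rSpec = rSpec, leakage = leakage,
      background = background, illumination = illumination,
      doublePass = doublePass, shotNoise = shotNoise,
      readNoiseSd = readNoiseSd, gain = gain,
      bitDepth = as.integer(bitDepth), scatterSigma = scatterSigma,
      seed = seed)
}

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(paste0("AcquisitionConfig[%s]: L=%g R_spec=%g leak=%g b0=%g ",
                     "%d-bit shot=%s read_sd=%g scatter=%g um seed=%s\n"),
              object@mode, object@illumination, object@rSpec,
              object@leakage, object@background, object@bitDepth,
              object@shotNoise, object@readNoiseSd, object@scatterSigma,
              format(object@seed)))
})

# --- scan sequence --------------------------------------------------------

#' Build a line-pair / rolling-shutter scan sequence
#'
#' Detection bands of \code{bandHeight} rows tile the sensor top to bottom
#' (the last band may be shorter). Each step pairs its detection band with
#' two illumination lines of \code{lineWidth} rows flanking the band at a
#' guard gap of \code{offsetRows}; a flank that would fall off the sensor
#' is dropped, so edge steps carry a single line. Row coordinates are
#' 0-based half-open bands [start, end).
#'
#' @param nRows sensor height in rows
#' @param bandHeight detection band height (rows)
#' @param offsetRows guard gap between illumination and detection (>= 1)
#' @param lineWidth illumination line width (rows, >= 1)
#' @return a [ScanSequence-class] object
#' @export
makeScanSequence <- function(nRows, bandHeight = 16L, offsetRows = 4L,
                             lineWidth = 8L) {
  nRows <- as.integer(nRows); bandHeight <- as.integer(bandHeight)
  offsetRows <- as.integer(offsetRows); lineWidth <- as.integer(lineWidth)
  stopifnot(nRows >= 1, bandHeight >= 1, offsetRows >= 1, lineWidth >= 1)
  if (bandHeight + 2L * (offsetRows + lineWidth) > nRows)
    stop(sprintf(paste0("infeasible scan geometry: band %d + 2*(offset %d + ",
                        "line %d) exceeds %d sensor rows"),
                 bandHeight, offsetRows, lineWidth, nRows))
  starts <- seq(0L, nRows - 1L, by = bandHeight)
  steps <- data.frame(
    step = seq_along(starts),
    det_start = starts,
    det_end = pmin(starts + bandHeight, nRows)
  )
  # upper flank [det_start - offset - width, det_start - offset)
  u_end <- steps$det_start - offsetRows
  u_start <- u_end - lineWidth
  # lower flank [det_end + offset, det_end + offset + width)
  l_start <- steps$det_end + offsetRows
  l_end <- l_start + lineWidth
  drop_u <- u_start < 0L
  drop_l <- l_end > nRows
  steps$ill1_start <- ifelse(drop_u, NA_integer_, u_start)
  steps$ill1_end <- ifelse(drop_u, NA_integer_, u_end)
  steps$ill2_start <- ifelse(drop_l, NA_integer_, l_start)
  steps$ill2_end <- ifelse(drop_l, NA_integer_, l_end)
  if (any(drop_u & drop_l))
    stop("infeasible scan geometry: a step has no in-sensor illumination line")
  new("ScanSequence", steps = steps, nRows = nRows,
      bandHeight = bandHeight, offsetRows = offsetRows,
      lineWidth = lineWidth)
}

#' Audit a scan sequence row by row
#'
#' Exhaustive per-row check of the two structural invariants: every sensor
#' row is covered by exactly one detection band over the sequence, and in
#' every step each illumination line is disjoint from the detection band
#' with a gap of at least \code{offsetRows}.
#'
#' @param seq a [ScanSequence-class] object
#' @return list(ok, coverage, overlapRows, minGap, message); coverage is
#'   the per-row count of detection bands containing the row
#' @export
auditScanSequence <- function(seq) {
  st <- seq@steps
  n <- seq@nRows
  coverage <- integer(n)
  overlap <- 0L
  minGap <- Inf
  for (k in seq_len(nrow(st))) {
    det <- seq(st$det_start[k], st$det_end[k] - 1L)
    coverage[det + 1L] <- coverage[det + 1L] + 1L
    for (side in c("ill1", "ill2")) {
      s <- st[[paste0(side, "_start")]][k]
      e <- st[[paste0(side, "_end")]][k]
      if (is.na(s)) next
      ill <- seq(s, e - 1L)
      overlap <- overlap + length(intersect(det, ill))
      gap <- if (e <= st$det_start[k]) st$det_start[k] - e
             else if (s >= st$det_end[k]) s - st$det_end[k]
             else 0L
      minGap <- min(minGap, gap)
    }
  }
  ok <- all(coverage == 1L) && overlap == 0L && minGap >= seq@offsetRows
  msg <- if (ok) "valid" else paste0(
    "invalid scan sequence: ",
    if (!all(coverage == 1L)) sprintf("%d rows not covered exactly once; ",
                                      sum(coverage != 1L)) else "",
    if (overlap > 0L) sprintf("%d illumination/detection overlap rows; ",
                              overlap) else "",
    if (minGap < seq@offsetRows) sprintf("min gap %s < offset %d",
                                         format(minGap), seq@offsetRows)
    else "")
  list(ok = ok, coverage = coverage, overlapRows = overlap,
       minGap = minGap, message = msg)
}

setMethod("show", "ScanSequence", function(object) {
  cat(sprintf(paste0("ScanSequence: %d steps | %d rows | band %d | ",
                     "offset %d | line width %d\n"),
              nrow(object@steps), object@nRows, object@bandHeight,
              object@offsetRows, object@lineWidth))
})

#' Export a scan sequence as CSV
#' @param seq a [ScanSequence-class] object
#' @param file output CSV path
#' @return invisibly, the file path
#' @export
writeScanSequence <- function(seq, file) {
  write.csv(seq@steps, file, row.names = FALSE)
  invisible(file)
}

# --- tissue interaction ---------------------------------------------------

#' Tissue return field and per-core signals for a mode
#'
#' Reflectance modes: return = diffuse_reflectance * exp(-2 * tau)
#' (double-pass Beer-Lambert through the absorbing stain under
#' epi-illumination; single pass if doublePass is FALSE), so stained nuclei
#' appear as dark dots. Fluorescence: return = fluorescence yield map
#' (nuclei bright). The field is then integrated through the bundle cores.
#'
#' @param phantom a [Phantom-class] object
#' @param bundle a [FiberBundle-class] object
#' @param mode imaging mode string
#' @param doublePass logical, reflectance double pass
#' @return list(field = matrix on the phantom grid, cores = per-core signals)
#' @export
tissueReturn <- function(phantom, bundle, mode, doublePass = TRUE) {
  field <- switch(mode,
    widefield_reflectance = ,
    darkfield = phantom@reflectanceMap *
      exp(-(if (doublePass) 2 else 1) * phantom@absorptionMap),
    fluorescence = phantom@fluorescenceMap,
    stop(sprintf("unknown mode '%s'", mode))
  )
  list(field = field,
       cores = sampleThroughBundle(field, bundle, phantom@pixelPitch))
}

# shared: render per-core tissue signals and the unit fill pattern
.renderedComponents <- function(phantom, bundle, config) {
  tr <- tissueReturn(phantom, bundle, config@mode, config@doublePass)
  npx <- nrow(phantom@absorptionMap)
  tissueImg <- renderBundleImage(tr$cores, bundle, phantom@pixelPitch, npx)
  unitImg <- renderBundleImage(rep(1, nCores(bundle)), bundle,
                               phantom@pixelPitch, npx)
  list(tissue = tissueImg, unit = unitImg, npx = npx)
}

#' Apply the sensor noise model and quantize
#'
#' Shot noise: Poisson with mean equal to the pixel value in photoelectrons
#' (value * gain), converted back to counts. Read noise: additive Gaussian
#' with sd \code{readNoiseSd} counts. The result is clipped to the ADC range
#' and quantized by rounding half-up. Deterministic given config@seed.
#'
#' @param frame numeric matrix of linear counts (>= 0)
#' @param config an [AcquisitionConfig-class] object
#' @return integer matrix in [0, 2^bitDepth - 1]
#' @export
addSensorNoise <- function(frame, config) {
  if (any(frame < 0)) stop("negative input to the noise model")
  set.seed(as.integer(config@seed %% .Machine$integer.max))
  x <- frame
  if (config@shotNoise)
    x[] <- rpois(length(x), as.vector(x) * config@gain) / config@gain
  if (config@readNoiseSd > 0)
    x <- x + rnorm(length(x), 0, config@readNoiseSd)
  top <- 2^config@bitDepth - 1
  x <- pmin(pmax(x, 0), top)
  matrix(as.integer(floor(x + 0.5)), nrow(frame), ncol(frame))
}

.asRawFrame <- function(counts, config, pixelPitch, background = NULL) {
  new("RawFrame", pixels = counts, mode = config@mode, config = config,
      pixelPitch = pixelPitch, background = background)
}

#' Acquire a non-scanning widefield frame
#'
#' The whole FOV is illuminated and detected at once, so the detection
#' aperture collects the specular reflection generated at the fiber
#' surfaces everywhere. Pixel signal before noise:
#' L * (leakage * R_spec + tissue_return + b0) for reflectance. In
#' fluorescence mode the emission filter blocks reflected light, so both
#' the specular term and the stray background b0 vanish (spectral
#' separation). All terms are rendered through the bundle honeycomb.
#'
#' @param phantom a [Phantom-class] object
#' @param bundle a [FiberBundle-class] object
#' @param config an [AcquisitionConfig-class] object (mode
#'   widefield_reflectance or fluorescence)
#' @return a [RawFrame-class] object
#' @export
acquireWidefield <- function(phantom, bundle, config) {
  rc <- .renderedComponents(phantom, bundle, config)
  reflected <- if (config@mode == "fluorescence") 0
               else config@leakage * config@rSpec + config@background
  linear <- config@illumination * (rc$tissue + reflected * rc$unit)
  .asRawFrame(addSensorNoise(linear, config), config, phantom@pixelPitch)
}

#' Acquire a scanning darkfield frame
#'
#' The frame is assembled band by band. For each scan step, the rows of the
#' detection band receive L * (tissue_return * e(row) + b0 * leakage),
#' where e(row) is the effective illumination reaching the row from the
#' step's line pair: the line indicator convolved along rows with a
#' boundary-renormalized Gaussian of width \code{scatterSigma} (the
#' isotropic subsurface-scattering spread), normalized by the indicator's
#' sensor mean so that the infinite-width limit is exactly uniform unit
#' illumination. The specular term is strictly local to illuminated rows,
#' so it contributes to the detection band only on illumination/detection
#' overlap -- which a valid sequence precludes: specular rejection is exact
#' by construction.
#'
#' @param phantom a [Phantom-class] object
#' @param bundle a [FiberBundle-class] object
#' @param config an [AcquisitionConfig-class] object, mode "darkfield"
#' @param scanSeq a [ScanSequence-class] object for the frame's row count
#' @return a [RawFrame-class] object
#' @export
acquireDarkfield <- function(phantom, bundle, config, scanSeq) {
  rc <- .renderedComponents(phantom, bundle, config)
  n <- rc$npx
  if (scanSeq@nRows != n)
    stop(sprintf("scan sequence rows (%d) do not match frame rows (%d)",
                 scanSeq@nRows, n))
  sigmaRows <- config@scatterSigma / phantom@pixelPitch
  linear <- matrix(0, n, n)
  st <- scanSeq@steps
  specLevel <- config@leakage * config@rSpec
  for (k in seq_len(nrow(st))) {
    ind <- numeric(n)
    for (side in c("ill1", "ill2")) {
      s <- st[[paste0(side, "_start")]][k]
      e <- st[[paste0(side, "_end")]][k]
      if (!is.na(s) && e > s) ind[(s + 1L):e] <- 1
    }
    eRow <- .spreadRows(ind, sigmaRows) / mean(ind)
    det <- (st$det_start[k] + 1L):st$det_end[k]
    band <- config@illumination *
      (rc$tissue[det, , drop = FALSE] * eRow[det] +
       config@background * config@leakage * rc$unit[det, , drop = FALSE])
    # specular is local to illuminated rows: contributes only on overlap
    ovl <- det[ind[det] > 0]
    if (length(ovl))
      band[match(ovl, det), ] <- band[match(ovl, det), ] +
        config@illumination * specLevel * rc$unit[ovl, , drop = FALSE]
    linear[det, ] <- band
  }
  .asRawFrame(addSensorNoise(linear, config), config, phantom@pixelPitch)
}

# boundary-renormalized Gaussian convolution of a row profile
.spreadRows <- function(profile, sigmaRows) {
  n <- length(profile)
  if (!is.finite(sigmaRows)) return(rep(mean(profile), n))
  if (sigmaRows <= 0) return(profile)
  r <- ceiling(4 * sigmaRows)
  k <- exp(-0.5 * ((-r:r) / sigmaRows)^2)
  num <- .conv1(profile, k)
  den <- .conv1(rep(1, n), k)
  num / den
}

# 'same' linear (zero-padded) 1-D convolution with an odd symmetric kernel
.conv1 <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  xp <- c(numeric(r), x, numeric(r))
  out <- numeric(length(x))
  for (t in seq_along(k)) out <- out + k[t] * xp[seq_along(x) + (t - 1L)]
  out
}

#' Acquire one frame in any mode
#'
#' Dispatches to [acquireWidefield()] or [acquireDarkfield()] based on
#' \code{config@mode}.
#'
#' @inheritParams acquireDarkfield
#' @return a [RawFrame-class] object
#' @export
acquireFrame <- function(phantom, bundle, config, scanSeq = NULL) {
  if (config@mode == "darkfield") {
    if (is.null(scanSeq))
      scanSeq <- makeScanSequence(nrow(phantom@absorptionMap))
    acquireDarkfield(phantom, bundle, config, scanSeq)
  } else {
    acquireWidefield(phantom, bundle, config)
  }
}

#' Subtract a paired background frame
#'
#' Pixelwise difference clipped at 0, recording provenance in the returned
#' frame's background slot.
#'
#' @param frame a [RawFrame-class] object
#' @param backgroundFrame a [RawFrame-class] of identical shape and mode
#' @return a [RawFrame-class] with the difference in pixels
#' @export
subtractBackground <- function(frame, backgroundFrame) {
  if (!identical(dim(frame@pixels), dim(backgroundFrame@pixels)))
    stop("background frame shape mismatch")
  if (!identical(frame@mode, backgroundFrame@mode))
    stop("background frame mode mismatch")
  out <- pmax(frame@pixels - backgroundFrame@pixels, 0L)
  new("RawFrame", pixels = out, mode = frame@mode, config = frame@config,
      pixelPitch = frame@pixelPitch, background = backgroundFrame@pixels)
}

setMethod("show", "RawFrame", function(object) {
  cat(sprintf("RawFrame[%s]: %d x %d px @ %g um | counts [%d, %d]\n",
              object@mode, nrow(object@pixels), ncol(object@pixels),
              object@pixelPitch, min(object@pixels), max(object@pixels)))
})

#' Write a raw frame as 16-bit TIFF with a JSON sidecar
#'
#' @param frame a [RawFrame-class] object
#' @param file output TIFF path (sidecar gets the same stem + .json)
#' @return invisibly, files written
#' @export
writeRawFrame <- function(frame, file) {
  tiff::writeTIFF(frame@pixels / 65535, file, bits.per.sample = 16)
  side <- sub("\\.tiff?$", ".json", file)
  if (identical(side, file)) side <- paste0(file, ".json")
  cfg <- frame@config
  jsonlite::write_json(list(
    mode = frame@mode, pixel_pitch_um = frame@pixelPitch,
    bit_depth = cfg@bitDepth, illumination = cfg@illumination,
    r_spec = cfg@rSpec, leakage = cfg@leakage, background = cfg@background,
    double_pass = cfg@doublePass, shot_noise = cfg@shotNoise,
    read_noise_sd = cfg@readNoiseSd, scatter_sigma_um = cfg@scatterSigma,
    rng_seed = cfg@seed), side, auto_unbox = TRUE, digits = NA)
  invisible(c(file, side))
}

#' Read a raw frame written by [writeRawFrame()]
#' @param file TIFF path
#' @return a [RawFrame-class] object
#' @export
readRawFrame <- function(file) {
  px <- tiff::readTIFF(file)
  if (length(dim(px)) == 3) stop("expected single-channel grayscale TIFF")
  side <- sub("\\.tiff?$", ".json", file)
  if (!file.exists(side)) side <- paste0(file, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  cfg <- acquisitionConfig(
    mode = meta$mode %||% "widefield_reflectance",
    rSpec = meta$r_spec %||% 0, leakage = meta$leakage %||% 0,
    background = meta$background %||% 0,
    illumination = meta$illumination %||% 1,
    doublePass = meta$double_pass %||% TRUE,
    shotNoise = meta$shot_noise %||% FALSE,
    readNoiseSd = meta$read_noise_sd %||% 0,
    bitDepth = meta$bit_depth %||% 16L,
    scatterSigma = meta$scatter_sigma_um %||% 30,
    seed = meta$rng_seed %||% 0)
  counts <- matrix(as.integer(round(px * 65535)), nrow(px), ncol(px))
  top <- 2^cfg@bitDepth - 1
  counts[counts > top] <- as.integer(top)
  .asRawFrame(counts, cfg, meta$pixel_pitch_um %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
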