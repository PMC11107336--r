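# Nuclei detection and cross-mode quantification. The detector is a
# multiscale scale-normalized Laplacian-of-Gaussian blob detector with
# greedy non-maximum suppression; dark nuclei (reflectance modes) are
# handled by inverting the image, so one detector serves both polarities.

.logStack <- function(img, mask, sigmasPx) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lapply(sigmasPx, function(s) {
    sm <- .maskedGblur(img, s, mask)
    # scale-normalized response; negative Laplacian is positive on bright blobs
    -s^2 * EBImage::filter2(sm, lap)
  })
}

# local maxima of a 2-D matrix against its 8 neighbours
.isLocalMax <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- m
  res <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    res <- res & m >= pad[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)]
  }
  res
}

#' Detect nuclei as dark or bright blobs
#'
#' Multiscale Laplacian-of-Gaussian detection on the polarity-corrected
#' image (inverted for dark nuclei). Candidate blobs are local maxima of
#' the scale-normalized response across position and scale, above
#' \code{responseThreshold}; greedy non-maximum suppression then removes
#' any detection within one radius of a stronger one. Detections are
#' returned in micrometre coordinates (FOV-centred), sorted by score.
#'
#' @param pimg a [ProcessedImage-class] object (or a plain matrix together
#'   with \code{pixelPitch} and optional \code{mask})
#' @param polarity "dark" (reflectance: stained nuclei absorb) or "bright"
#'   (fluorescence)
#' @param minRadius,maxRadius radius search band (um)
#' @param responseThreshold minimum scale-normalized LoG response
#' @param nScales number of logarithmically spaced scales across the band
#' @param pixelPitch,mask used when \code{pimg} is a plain matrix
#' @param confirmImage image used for the photometric confirmation stage;
#'   defaults to the linear restored image of a [ProcessedImage-class]
#'   input, or the input matrix itself
#' @param minBlobContrast minimum signed centre-vs-annulus intensity
#'   difference on \code{confirmImage} (in its own units; restored images
#'   are normalized to a common mean, so this is an absolute floor);
#'   0 disables confirmation
#' @param minBlobSnr minimum ratio of that centre-vs-annulus difference to
#'   the annulus pixel standard deviation (a local detection SNR);
#'   0 disables the check
#'
#' @details The candidate mask is eroded by \code{maxRadius} before peak
#'   picking: the FOV edge is a large intensity step whose LoG response
#'   would otherwise dominate the score range, and a blob centre closer
#'   than one radius to the boundary is not measurable anyway. Candidates
#'   are then confirmed photometrically: the mean over the blob core must
#'   differ from the mean over a surrounding annulus by at least
#'   \code{minBlobContrast} in the direction of the requested polarity.
#'   Adaptive equalization stretches local noise by design, so the LoG
#'   score alone does not separate dim-background noise bumps from real
#'   nuclei at one threshold across modes; the confirmation stage restores
#'   that separation on the photometrically linear image. Because shot
#'   noise through the bundle is correlated at the core scale (one noisy
#'   value per core disk), noise bumps can reach blob scale with nonzero
#'   absolute contrast; the SNR criterion compares each blob against the
#'   locally measured background fluctuation, which adapts across modes
#'   and illumination levels without per-mode tuning.
#' @return data.frame: x_um, y_um, r_um, score, polarity (sorted by score)
#' @export
detectNuclei <- function(pimg, polarity = c("dark", "bright"),
                         minRadius = 2.5, maxRadius = 6.5,
                         responseThreshold = 0.04, nScales = 5,
                         pixelPitch = NULL, mask = NULL,
                         confirmImage = NULL, minBlobContrast = 0.02,
                         minBlobSnr = 5) {
  polarity <- match.arg(polarity)
  if (is(pimg, "ProcessedImage")) {
    img <- pimg@pixels; pitch <- pimg@pixelPitch; mask <- pimg@mask
    if (is.null(confirmImage)) confirmImage <- pimg@linear
  } else {
    img <- pimg
    pitch <- if (is.null(pixelPitch)) 1 else pixelPitch
    if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
    if (is.null(confirmImage)) confirmImage <- img
  }
  stopifnot(minRadius > 0, maxRadius > minRadius)
  if (nScales < 2) stop("radius band narrower than one scale step")
  radii <- exp(seq(log(minRadius), log(maxRadius), length.out = nScales))
  sigmasPx <- radii / sqrt(2) / pitch

  work <- img
  if (polarity == "dark") {
    work <- max(img[mask]) - img
    work[!mask] <- 0
  }
  rpx <- ceiling(maxRadius / pitch)
  inner <- EBImage::erode(matrix(as.numeric(mask), nrow(img), ncol(img)),
                          EBImage::makeBrush(2L * rpx + 1L, "disc")) > 0.5
  stack <- .logStack(work, mask, sigmasPx)
  cand <- NULL
  for (si in seq_along(stack)) {
    resp <- stack[[si]]
    lm <- .isLocalMax(resp) & resp > responseThreshold & inner
    if (si > 1) lm <- lm & resp >= stack[[si - 1]]
    if (si < length(stack)) lm <- lm & resp >= stack[[si + 1]]
    if (!any(lm)) next
    w <- which(lm, arr.ind = TRUE)
    cand <- rbind(cand, data.frame(
      row = w[, 1], col = w[, 2], r_um = radii[si],
      score = resp[lm]))
  }
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      r_um = numeric(0), score = numeric(0),
                      polarity = character(0)))
  half <- nrow(img) * pitch / 2
  cand$x_um <- (cand$col - 0.5) * pitch - half
  cand$y_um <- (cand$row - 0.5) * pitch - half
  cand <- cand[order(-cand$score), ]

  # greedy NMS at one radius
  keep <- logical(nrow(cand))
  kx <- ky <- kr <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kx)) {
      d2 <- (kx - cand$x_um[i])^2 + (ky - cand$y_um[i])^2
      if (any(d2 < pmax(kr, cand$r_um[i])^2)) next
    }
    keep[i] <- TRUE
    kx <- c(kx, cand$x_um[i]); ky <- c(ky, cand$y_um[i])
    kr <- c(kr, cand$r_um[i])
  }
  out <- cand[keep, c("x_um", "y_um", "r_um", "score", "row", "col")]

  if ((minBlobContrast > 0 || minBlobSnr > 0) && nrow(out) > 0) {
    bc <- .blobContrast(confirmImage, mask, out$row, out$col, out$r_um / pitch)
    dc <- if (polarity == "dark") -bc$diff else bc$diff
    z <- ifelse(bc$sd > 0, dc / bc$sd, ifelse(dc > 0, Inf, -Inf))
    out <- out[dc >= minBlobContrast & z >= minBlobSnr, , drop = FALSE]
  }
  out <- out[, c("x_um", "y_um", "r_um", "score")]
  out$polarity <- rep(polarity, nrow(out))
  rownames(out) <- NULL
  out
}

# Signed centre-minus-annulus mean difference and annulus sd per blob.
# The sd is computed after removing a quadratic-in-row trend from the
# annulus: the scanned illumination leaves a smooth deterministic row
# profile (band scalloping) that would otherwise dominate the local
# fluctuation estimate, whereas genuine noise through the bundle is
# correlated only at the core scale and survives this coarse detrending.
.blobContrast <- function(img, mask, rows, cols, radiiPx) {
  n1 <- nrow(img); n2 <- ncol(img)
  diff <- sdv <- numeric(length(rows))
  for (k in seq_along(rows)) {
    r <- radiiPx[k]
    w <- ceiling(2.2 * r)
    ri <- max(1, rows[k] - w):min(n1, rows[k] + w)
    ci <- max(1, cols[k] - w):min(n2, cols[k] + w)
    D2 <- outer((ri - rows[k])^2, (ci - cols[k])^2, "+")
    M <- mask[ri, ci, drop = FALSE]
    core <- D2 <= (0.7 * r)^2 & M
    ann <- D2 >= (1.3 * r)^2 & D2 <= (2.2 * r)^2 & M
    if (!any(core) || sum(ann) < 6) { diff[k] <- 0; sdv[k] <- Inf; next }
    sub <- img[ri, ci, drop = FALSE]
    cm <- mean(sub[core])
    # directional contrasts: a genuine blob stands out against both the
    # same-row and the same-column parts of its annulus; stripe-shaped
    # raster artifacts (illumination scalloping, lattice/pixel-grid moire)
    # vanish in one of the two directions
    dy <- row(ann) + min(ri) - 1 - rows[k]
    dx <- col(ann) + min(ci) - 1 - cols[k]
    sameRow <- ann & abs(dy) <= 0.7 * r
    sameCol <- ann & abs(dx) <= 0.7 * r
    dH <- if (any(sameRow)) cm - mean(sub[sameRow]) else cm - mean(sub[ann])
    dV <- if (any(sameCol)) cm - mean(sub[sameCol]) else cm - mean(sub[ann])
    diff[k] <- if (abs(dH) < abs(dV)) dH else dV
    y <- dy[ann]
    vals <- sub[ann]
    X <- cbind(1, y, y^2)
    fit <- stats::lm.fit(X, vals)
    dof <- length(vals) - 3L
    sdv[k] <- if (dof > 0) sqrt(sum(fit$residuals^2) / dof) else Inf
  }
  list(diff = diff, sd = sdv)
}

#' Ground-truth nuclei fully measurable inside the FOV
#'
#' Filters a phantom's nuclei list to centres at least \code{margin}
#' micrometres inside the circular FOV. The default margin (twice the
#' detector's maximum radius) keeps a nucleus together with its local
#' background annulus inside the FOV, the population recall can fairly be
#' scored against; precision should be scored against the complete list.
#'
#' @param phantom a [Phantom-class] object
#' @param bundle a [FiberBundle-class] object (defines the FOV)
#' @param margin distance from the FOV boundary (um)
#' @return nuclei data.frame subset
#' @export
nucleiInFov <- function(phantom, bundle, margin = 13) {
  nuc <- phantom@nuclei
  r <- bundle@fovDiameter / 2 - margin
  nuc[nuc$x_um^2 + nuc$y_um^2 <= r^2, , drop = FALSE]
}

#' Match detections to ground-truth nuclei
#'
#' Greedy one-to-one nearest-neighbour assignment: detections are visited
#' in decreasing score order and claim the nearest unmatched true nucleus
#' within \code{tolerance} micrometres.
#'
#' @param detections data.frame from [detectNuclei()]
#' @param truth nuclei data.frame (x_um, y_um columns)
#' @param tolerance maximum match distance (um); a natural choice is the
#'   mean nuclear radius
#' @return list(nMatched, precision, recall, matches)
#' @export
matchDetections <- function(detections, truth, tolerance) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(nMatched = 0L,
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                matches = data.frame(det = integer(0), truth = integer(0))))
  ord <- order(-detections$score)
  free <- rep(TRUE, nt)
  md <- mt <- integer(0)
  for (i in ord) {
    d2 <- (truth$x_um - detections$x_um[i])^2 +
          (truth$y_um - detections$y_um[i])^2
    d2[!free] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tolerance^2) {
      free[j] <- FALSE
      md <- c(md, i); mt <- c(mt, j)
    }
  }
  list(nMatched = length(md),
       precision = length(md) / nd,
       recall = length(md) / nt,
       matches = data.frame(det = md, truth = mt))
}

#' Build a centred grid of congruent square ROIs
#'
#' Deterministic g x g tiling (g = sqrt(nRois), which must be a perfect
#' square) centred in the FOV; the grid must fit inside the square
#' inscribed in the circular FOV. Rectangles are half-open.
#'
#' @param fovDiameter circular FOV diameter (um)
#' @param nRois number of ROIs (perfect square; default 25)
#' @param roiSize ROI side (um)
#' @return a [RoiGrid-class] object
#' @export
makeRoiGrid <- function(fovDiameter = 790, nRois = 25, roiSize = 100) {
  g <- round(sqrt(nRois))
  if (g * g != nRois)
    stop("nRois must be a perfect square for a deterministic grid tiling")
  span <- g * roiSize
  if (span > fovDiameter / sqrt(2) + 1e-9)
    stop(sprintf("ROI grid span %g um exceeds the FOV's inscribed square (%g um)",
                 span, fovDiameter / sqrt(2)))
  lo <- -span / 2
  idx <- expand.grid(ix = seq_len(g) - 1, iy = seq_len(g) - 1)
  rects <- data.frame(
    xmin = lo + idx$ix * roiSize, ymin = lo + idx$iy * roiSize,
    xmax = lo + (idx$ix + 1) * roiSize, ymax = lo + (idx$iy + 1) * roiSize)
  new("RoiGrid", rects = rects, roiSize = roiSize)
}

setMethod("show", "RoiGrid", function(object) {
  cat(sprintf("RoiGrid: %d ROIs of %g x %g um\n", nrow(object@rects),
              object@roiSize, object@roiSize))
})

#' Count detections per ROI
#'
#' A detection belongs to an ROI iff its centre lies inside the half-open
#' rectangle (left/top edge in, right/bottom out), so detections on shared
#' edges are counted exactly once. Reports per-ROI counts with their mean
#' and sample (n-1) standard deviation.
#'
#' @param detections data.frame with x_um, y_um
#' @param roiGrid a [RoiGrid-class] object
#' @return list(counts, mean, sd)
#' @export
countInRois <- function(detections, roiGrid) {
  r <- roiGrid@rects
  if (nrow(r) == 0) stop("empty ROI grid")
  counts <- vapply(seq_len(nrow(r)), function(k) {
    sum(detections$x_um >= r$xmin[k] & detections$x_um < r$xmax[k] &
        detections$y_um >= r$ymin[k] & detections$y_um < r$ymax[k])
  }, integer(1))
  list(counts = counts, mean = mean(counts),
       sd = if (length(counts) > 1) sd(counts) else 0)
}

#' Weber contrast and SNR between truth-masked regions
#'
#' Weber contrast C = |mean_bg - mean_fg| / mean_bg and
#' SNR = |mean_bg - mean_fg| / sd_bg, computed over disjoint non-empty
#' foreground (nuclei) and background masks. Weber contrast is sensitive
#' to additive offsets, which is exactly why a specular background floor
#' degrades the visibility of stained nuclei.
#'
#' @param image numeric matrix (typically a linear restored image)
#' @param fgMask,bgMask disjoint logical masks
#' @return list(weber, snr, meanFg, meanBg, sdBg)
#' @export
contrastMetrics <- function(image, fgMask, bgMask) {
  if (!any(fgMask) || !any(bgMask)) stop("empty contrast mask")
  if (any(fgMask & bgMask)) stop("contrast masks must be disjoint")
  mf <- mean(image[fgMask]); mb <- mean(image[bgMask])
  sb <- sd(image[bgMask])
  if (mb == 0) stop("zero background mean")
  list(weber = abs(mb - mf) / mb,
       snr = if (sb > 0) abs(mb - mf) / sb else Inf,
       meanFg = mf, meanBg = mb, sdBg = sb)
}

#' Simulate, restore and analyze all three modes on one phantom
#'
#' Acquires widefield reflectance, scanning darkfield and fluorescence
#' frames of the same phantom through the same bundle, runs the identical
#' restoration pipeline on each, detects nuclei (dark polarity for
#' reflectance, bright for fluorescence), counts them in the ROI grid and
#' computes Weber contrast and SNR against the phantom's truth masks.
#' Contrast metrics use the linear restored image (before adaptive
#' equalization); detection uses the fully processed image.
#'
#' @param phantom a [Phantom-class] object
#' @param bundle a [FiberBundle-class] object
#' @param configs named list of [AcquisitionConfig-class] objects for
#'   modes "widefield_reflectance", "darkfield", "fluorescence"; defaults
#'   built from \code{acquisitionConfig()} with the given seed
#' @param scanSeq a [ScanSequence-class]; default [makeScanSequence()] on
#'   the phantom grid
#' @param roiGrid a [RoiGrid-class]; default 25 ROIs of 100 um
#' @param seed seed used for default configs
#' @param sigmaUm,targetMean,clipLimit,tileGrid restoration parameters
#'   (identical across modes)
#' @param minRadius,maxRadius,responseThreshold detector parameters
#' @return an [AnalysisReport-class] object
#' @export
compareModes <- function(phantom, bundle, configs = NULL, scanSeq = NULL,
                         roiGrid = NULL, seed = 1,
                         sigmaUm = NULL, targetMean = 0.4, clipLimit = 2,
                         tileGrid = 8, minRadius = 2.5, maxRadius = 6.5,
                         responseThreshold = 0.04) {
  modes <- c("widefield_reflectance", "darkfield", "fluorescence")
  if (is.null(configs))
    configs <- stats::setNames(lapply(seq_along(modes), function(k)
      acquisitionConfig(mode = modes[k], seed = seed * 17 + k)), modes)
  if (is.null(scanSeq))
    scanSeq <- makeScanSequence(nrow(phantom@absorptionMap))
  if (is.null(roiGrid)) roiGrid <- makeRoiGrid(bundle@fovDiameter)
  masks <- truthMasks(phantom)
  fov <- fovMask(bundle, phantom@pixelPitch, nrow(phantom@absorptionMap))
  fg <- masks$fg & fov
  bg <- masks$bg & fov
  meanR <- if (nrow(phantom@nuclei)) mean(sqrt(phantom@nuclei$a_um *
                                               phantom@nuclei$b_um)) else 4
  # precision vs all nuclei; recall vs nuclei fully measurable in the FOV
  r2int <- (bundle@fovDiameter / 2 - 2 * maxRadius)^2
  interior <- which(phantom@nuclei$x_um^2 + phantom@nuclei$y_um^2 <= r2int)

  out <- list()
  for (m in modes) {
    frame <- acquireFrame(phantom, bundle, configs[[m]], scanSeq)
    pimg <- processPipeline(frame, bundle, sigmaUm = sigmaUm,
                            targetMean = targetMean, clipLimit = clipLimit,
                            tileGrid = tileGrid)
    pol <- if (m == "fluorescence") "bright" else "dark"
    det <- detectNuclei(pimg, pol, minRadius, maxRadius, responseThreshold)
    cnt <- countInRois(det, roiGrid)
    cm <- contrastMetrics(pimg@linear, fg, bg)
    gt <- matchDetections(det, phantom@nuclei, meanR)
    recall <- if (length(interior))
      length(intersect(gt$matches$truth, interior)) / length(interior)
    else NA_real_
    out[[m]] <- list(detections = det, roiCounts = cnt$counts,
                     countMean = cnt$mean, countSd = cnt$sd,
                     weber = cm$weber, snr = cm$snr,
                     precision = gt$precision, recall = recall,
                     log = pimg@log)
  }
  cfgCols <- c("op", "params")
  logsEqual <- identical(out$darkfield$log[cfgCols],
                         out$fluorescence$log[cfgCols]) &&
    identical(out$darkfield$log[cfgCols],
              out$widefield_reflectance$log[cfgCols])
  mdf <- out$darkfield$countMean
  mfl <- out$fluorescence$countMean
  agreement <- list(
    countMeanDarkfield = mdf, countMeanFluorescence = mfl,
    relDiff = if (mfl > 0) abs(mdf - mfl) / mfl else NA_real_,
    processingLogsIdentical = logsEqual)
  new("AnalysisReport", modes = out, agreement = agreement,
      params = list(seed = seed, sigmaUm = sigmaUm, targetMean = targetMean,
                    clipLimit = clipLimit, tileGrid = tileGrid,
                    minRadius = minRadius, maxRadius = maxRadius,
                    responseThreshold = responseThreshold,
                    matchTolerance = meanR))
}

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  for (m in names(object@modes)) {
    r <- object@modes[[m]]
    cat(sprintf("  %-22s count %5.1f +/- %4.1f | Weber %5.3f | SNR %6.2f\n",
                m, r$countMean, r$countSd, r$weber, r$snr))
  }
  a <- object@agreement
  cat(sprintf("  darkfield vs fluorescence count rel. diff: %.3f%%\n",
              100 * a$relDiff))
})

#' Write an analysis report to disk
#'
#' JSON report, per-mode detection CSVs, ROI-count CSV and a detection
#' overlay PNG for the darkfield mode.
#'
#' @param report an [AnalysisReport-class] object
#' @param dir output directory
#' @param overlayImage optional [ProcessedImage-class] for the overlay
#' @return invisibly, files written
#' @export
writeAnalysisReport <- function(report, dir, overlayImage = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  js <- list(agreement = report@agreement, params = report@params,
             modes = lapply(report@modes, function(r)
               r[c("countMean", "countSd", "weber", "snr",
                   "precision", "recall", "roiCounts")]))
  fj <- file.path(dir, "analysis_report.json")
  jsonlite::write_json(js, fj, auto_unbox = TRUE, digits = NA)
  files <- c(files, fj)
  for (m in names(report@modes)) {
    fc <- file.path(dir, paste0("detections_", m, ".csv"))
    write.csv(report@modes[[m]]$detections, fc, row.names = FALSE)
    files <- c(files, fc)
  }
  cnts <- do.call(cbind, lapply(report@modes, function(r) r$roiCounts))
  fr <- file.path(dir, "roi_counts.csv")
  write.csv(as.data.frame(cnts), fr, row.names = FALSE)
  files <- c(files, fr)
  if (!is.null(overlayImage)) {
    fp <- file.path(dir, "overlay_darkfield.png")
    det <- report@modes$darkfield$detections
    npx <- nrow(overlayImage@pixels)
    half <- npx * overlayImage@pixelPitch / 2
    grDevices::png(fp, width = npx, height = npx)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(-half, half), ylim = c(half, -half),
                          asp = 1, xaxs = "i", yaxs = "i")
    graphics::rasterImage(overlayImage@pixels, -half, half, half, -half)
    if (nrow(det))
      graphics::symbols(det$x_um, det$y_um, circles = det$r_um,
                        inches = FALSE, add = TRUE, fg = "red")
    grDevices::dev.off()
    files <- c(files, fp)
  }
  invisible(files)
}
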