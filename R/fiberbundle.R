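# Hexagonal lattice convention: row j at y = j * pitch * sqrt(3)/2,
# x = (i + (j mod 2)/2) * pitch, origin on a core. All coordinates um,
# FOV centred at the origin.

#' Build a coherent fiber-bundle geometry
#'
#' Enumerates the hexagonal core lattice clipped to the circular FOV
#' (centres kept within fovDiameter/2 - coreRadius). Deterministic.
#'
#' @param fovDiameter circular field of view diameter (um); the probe used
#'   as reference has a 790 um FOV
#' @param corePitch centre-to-centre core spacing (um)
#' @param coreRadius core collection-disk radius (um)
#' @param fillTransmission relative throughput of the core area, (0, 1]
#' @param claddingLevel residual inter-core signal level, [0, 1)
#' @return a [FiberBundle-class] object
#' @export
buildBundle <- function(fovDiameter = 790, corePitch = 4.5,
                        coreRadius = 1.6, fillTransmission = 1,
                        claddingLevel = 0.15) {
  if (!(0 < 2 * coreRadius && 2 * coreRadius < corePitch &&
        corePitch <= fovDiameter))
    stop("require 0 < 2*coreRadius < corePitch <= fovDiameter")
  rmax <- fovDiameter / 2 - coreRadius
  dy <- corePitch * sqrt(3) / 2
  jr <- floor(rmax / dy)
  js <- seq(-jr, jr)
  centers <- NULL
  lattice <- NULL
  for (j in js) {
    off <- (abs(j) %% 2) / 2  # same offset for +/- j keeps lattice symmetric
    y <- j * dy
    xr <- sqrt(max(rmax^2 - y^2, 0))
    ilo <- ceiling((-xr) / corePitch - off)
    ihi <- floor(xr / corePitch - off)
    if (ihi < ilo) next
    is <- seq(ilo, ihi)
    x <- (is + off) * corePitch
    keep <- x^2 + y^2 <= rmax^2 + 1e-9
    if (!any(keep)) next
    centers <- rbind(centers, cbind(x[keep], rep(y, sum(keep))))
    lattice <- rbind(lattice, cbind(is[keep], rep(j, sum(keep))))
  }
  if (is.null(centers)) centers <- matrix(numeric(0), 0, 2)
  if (is.null(lattice)) lattice <- matrix(integer(0), 0, 2)
  colnames(centers) <- c("x_um", "y_um")
  colnames(lattice) <- c("i", "j")
  new("FiberBundle", fovDiameter = fovDiameter, corePitch = corePitch,
      coreRadius = coreRadius, coreCenters = centers,
      coreLattice = lattice, fillTransmission = fillTransmission,
      claddingLevel = claddingLevel)
}

#' Number of cores in a bundle
#' @param bundle a [FiberBundle-class] object
#' @return integer core count
#' @export
nCores <- function(bundle) nrow(bundle@coreCenters)

#' Core centre coordinates
#' @param bundle a [FiberBundle-class] object
#' @return n x 2 matrix of (x_um, y_um)
#' @export
coreCenters <- function(bundle) bundle@coreCenters

setMethod("show", "FiberBundle", function(object) {
  cat(sprintf(paste0("FiberBundle: %d cores | FOV %g um | pitch %g um | ",
                     "core radius %g um\n"),
              nCores(object), object@fovDiameter, object@corePitch,
              object@coreRadius))
})

#' Fundamental spatial frequency of the core lattice
#'
#' Magnitude of the first reciprocal-lattice vector of the hexagonal core
#' lattice, 2 / (sqrt(3) * pitch) cycles per um -- the frequency at which
#' the honeycomb pattern concentrates its power.
#'
#' @param bundle a [FiberBundle-class] object
#' @return frequency in cycles/um
#' @export
latticeFrequency <- function(bundle) 2 / (sqrt(3) * bundle@corePitch)

#' Spectral power at a single spatial frequency
#'
#' Hann-windowed complex projection of a mean-subtracted image region onto
#' exp(-2 pi i (fx x + fy y)); a narrowband power estimate at an exact
#' frequency, free of FFT bin quantization. Used to quantify honeycomb
#' suppression at the core-lattice fundamental.
#'
#' @param image numeric matrix
#' @param fx,fy frequency components (cycles/um)
#' @param pixelPitch pixel pitch (um)
#' @param rows,cols index ranges of the measurement window (default: the
#'   central half of the image, which should lie well inside the FOV)
#' @return scalar power (squared projection magnitude)
#' @export
latticePeakPower <- function(image, fx, fy, pixelPitch = 1,
                             rows = NULL, cols = NULL) {
  n1 <- nrow(image); n2 <- ncol(image)
  if (is.null(rows)) rows <- seq(floor(n1 / 4) + 1, floor(3 * n1 / 4))
  if (is.null(cols)) cols <- seq(floor(n2 / 4) + 1, floor(3 * n2 / 4))
  sub <- image[rows, cols, drop = FALSE]
  sub <- sub - mean(sub)
  hann <- function(m) 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
  W <- outer(hann(length(rows)), hann(length(cols)))
  y <- (rows - 0.5) * pixelPitch
  x <- (cols - 0.5) * pixelPitch
  E <- exp(-2i * pi * outer(fy * y, rep(1, length(x)))) *
       exp(-2i * pi * outer(rep(1, length(y)), fx * x))
  Mod(sum(sub * W * E))^2
}

# --- pixel <-> core assignment -------------------------------------------

# nearest lattice core for arbitrary (x, y), vectorized; returns core index
# (row into coreCenters) or 0 when the nearest lattice site carries no core
.nearestCore <- function(bundle, x, y) {
  p <- bundle@corePitch
  dy <- p * sqrt(3) / 2
  lat <- bundle@coreLattice
  if (nrow(lat) == 0) return(integer(length(x)))
  imin <- min(lat[, 1]); imax <- max(lat[, 1])
  jmin <- min(lat[, 2]); jmax <- max(lat[, 2])
  ni <- imax - imin + 1L
  lut <- integer(ni * (jmax - jmin + 1L))
  key <- (lat[, 1] - imin) + ni * (lat[, 2] - jmin) + 1L
  lut[key] <- seq_len(nrow(lat))

  n <- length(x)
  bestIdx <- integer(n)
  bestD2 <- rep(Inf, n)
  j0 <- round(y / dy)
  # +/- 2 rows: near the clipped FOV rim the nearest existing core can sit
  # beyond the immediately adjacent lattice row
  for (dj in -2:2) {
    j <- j0 + dj
    off <- (abs(j) %% 2) / 2
    i <- round(x / p - off)
    cx <- (i + off) * p
    cy <- j * dy
    d2 <- (x - cx)^2 + (y - cy)^2
    ok <- i >= imin & i <= imax & j >= jmin & j <= jmax
    idx <- integer(n)
    kk <- (i[ok] - imin) + ni * (j[ok] - jmin) + 1L
    idx[ok] <- lut[kk]
    upd <- idx > 0L & d2 < bestD2
    bestIdx[upd] <- idx[upd]
    bestD2[upd] <- d2[upd]
  }
  attr(bestIdx, "d2") <- bestD2
  bestIdx
}

# cached per-(bundle geometry, grid) pixel maps: core membership and
# nearest-core Voronoi assignment inside the FOV
.bundleCache <- new.env(parent = emptyenv())

.coreMaps <- function(bundle, pixelPitch, npx) {
  key <- paste(bundle@fovDiameter, bundle@corePitch, bundle@coreRadius,
               nCores(bundle), pixelPitch, npx, sep = "|")
  hit <- .bundleCache[[key]]
  if (!is.null(hit)) return(hit)
  half <- npx * pixelPitch / 2
  cc <- (seq_len(npx) - 0.5) * pixelPitch - half
  X <- matrix(cc, npx, npx, byrow = TRUE)
  Y <- matrix(cc, npx, npx)
  idx <- .nearestCore(bundle, as.vector(X), as.vector(Y))
  d2 <- attr(idx, "d2")
  inFov <- as.vector(X)^2 + as.vector(Y)^2 <= (bundle@fovDiameter / 2)^2
  core <- idx
  core[!(d2 <= bundle@coreRadius^2)] <- 0L
  near <- idx
  near[!inFov] <- 0L
  res <- list(
    core = matrix(core, npx, npx),
    near = matrix(near, npx, npx),
    fov = matrix(inFov, npx, npx)
  )
  .bundleCache[[key]] <- res
  res
}

#' In-FOV logical mask on a pixel grid
#'
#' @param bundle a [FiberBundle-class] object
#' @param pixelPitch grid pitch (um)
#' @param npx grid side length (pixels); the grid is centred on the FOV
#' @return logical matrix, TRUE inside the circular FOV
#' @export
fovMask <- function(bundle, pixelPitch, npx) {
  .coreMaps(bundle, pixelPitch, npx)$fov
}

#' Sample a continuous field through the fiber bundle
#'
#' Integrates the field over each core's collection disk (mean over the
#' pixels whose centres fall inside the disk) and scales by the bundle's
#' fill transmission. The field grid must cover the bundle FOV and be
#' centred on it.
#'
#' @param field numeric matrix on a square micrometre grid (rows = y)
#' @param bundle a [FiberBundle-class] object
#' @param pixelPitch grid pitch of \code{field} (um)
#' @return numeric vector of per-core signals aligned with
#'   \code{coreCenters(bundle)}
#' @export
sampleThroughBundle <- function(field, bundle, pixelPitch = 1) {
  npx <- nrow(field)
  if (npx != ncol(field)) stop("field must be square")
  if (npx * pixelPitch < bundle@fovDiameter - 1e-9)
    stop("field grid smaller than the bundle FOV")
  maps <- .coreMaps(bundle, pixelPitch, npx)
  idx <- as.vector(maps$core)
  sel <- idx > 0L
  sums <- rowsum(as.vector(field)[sel], idx[sel])
  cnts <- rowsum(rep(1, sum(sel)), idx[sel])
  out <- numeric(nCores(bundle))
  out[as.integer(rownames(sums))] <- sums / cnts
  out * bundle@fillTransmission
}

#' Rasterize per-core signals into a honeycomb image
#'
#' Pixels whose centres lie inside a core disk take that core's value;
#' in-FOV pixels between cores take claddingLevel times the nearest core's
#' value; pixels outside the circular FOV are 0. This is the forward model
#' of the honeycomb pattern intrinsic to bundle-relayed images.
#'
#' @param signals per-core signal vector (length \code{nCores(bundle)})
#' @param bundle a [FiberBundle-class] object
#' @param pixelPitch output grid pitch (um); warns when the cores are not
#'   resolved by at least 2 pixels per core diameter
#' @param npx output grid side (pixels); defaults to covering the FOV
#' @return numeric matrix (rows = y)
#' @export
renderBundleImage <- function(signals, bundle, pixelPitch = 1, npx = NULL) {
  if (length(signals) != nCores(bundle))
    stop("signals length must equal the number of cores")
  if (2 * bundle@coreRadius / pixelPitch < 2)
    warning("pixel pitch does not resolve the cores (< 2 px per core diameter)")
  if (is.null(npx)) npx <- as.integer(ceiling(bundle@fovDiameter / pixelPitch))
  maps <- .coreMaps(bundle, pixelPitch, npx)
  img <- matrix(0, npx, npx)
  sel <- maps$near > 0L
  img[sel] <- bundle@claddingLevel * signals[maps$near[sel]]
  sel <- maps$core > 0L
  img[sel] <- signals[maps$core[sel]]
  img
}

#' Export bundle geometry
#'
#' Core centres as CSV and parameters as a JSON sidecar.
#' @param bundle a [FiberBundle-class] object
#' @param dir output directory
#' @param prefix file name prefix
#' @return invisibly, files written
#' @export
writeBundle <- function(bundle, dir, prefix = "bundle") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fcsv <- file.path(dir, paste0(prefix, "_cores.csv"))
  write.csv(as.data.frame(bundle@coreCenters), fcsv, row.names = FALSE)
  fjson <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(fov_diameter_um = bundle@fovDiameter,
                            core_pitch_um = bundle@corePitch,
                            core_radius_um = bundle@coreRadius,
                            n_cores = nCores(bundle),
                            fill_transmission = bundle@fillTransmission,
                            cladding_level = bundle@claddingLevel),
                       fjson, auto_unbox = TRUE, digits = NA)
  invisible(c(fcsv, fjson))
}
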