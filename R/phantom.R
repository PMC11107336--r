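#' Generate a hard-core field of elliptical nuclei
#'
#' Draws nucleus centres from a Matern-style hard-core process (Poisson dart
#' throwing with rejection of candidates closer than \code{minSpacing} to an
#' accepted centre), emulating the regular spacing of healthy epithelial
#' nuclei. Sizes are lognormal around \code{meanRadius} with coefficient of
#' variation \code{radiusCv}; each nucleus is an ellipse with eccentricity
#' drawn uniformly in [0, eccentricityMax] and uniform orientation.
#'
#' With \code{minSpacing = 0} the process is plain Poisson: the number of
#' nuclei is Poisson(density * area) and centres are uniform. With a hard
#' core the target count is still Poisson but candidates violating the
#' spacing are discarded; if the requested density is infeasible under the
#' spacing the function fails naming achieved vs requested count.
#'
#' @param fieldExtent side of the square field (um); centres lie in
#'   (-fieldExtent/2, fieldExtent/2)^2
#' @param density expected nuclei per mm^2 (before hard-core thinning)
#' @param meanRadius mean semi-major-ish nuclear radius (um)
#' @param radiusCv coefficient of variation of the radius
#' @param eccentricityMax maximum ellipse eccentricity in [0, 1)
#' @param minSpacing minimum pairwise centre distance (um)
#' @param seed RNG seed (reproducible for identical parameters)
#' @param maxAttempts dart-throwing attempts per requested nucleus before
#'   declaring the density infeasible
#'
#' @return data.frame with one row per nucleus: x_um, y_um, a_um (semi-major),
#'   b_um (semi-minor), theta_rad, uptake
#' @export
generateNucleiField <- function(fieldExtent, density = 820,
                                meanRadius = 4, radiusCv = 0.1,
                                eccentricityMax = 0.3, minSpacing = 18,
                                seed = 1, maxAttempts = 200) {
  stopifnot(density >= 0, minSpacing >= 0, meanRadius > 0, fieldExtent > 0,
            radiusCv >= 0, eccentricityMax >= 0, eccentricityMax < 1)
  set.seed(as.integer(seed %% .Machine$integer.max))
  areaMm2 <- (fieldExtent / 1000)^2
  n <- rpois(1, density * areaMm2)
  half <- fieldExtent / 2
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), a_um = numeric(0),
                      b_um = numeric(0), theta_rad = numeric(0),
                      uptake = numeric(0))
  if (n == 0) return(empty)

  if (minSpacing == 0) {
    xs <- runif(n, -half, half)
    ys <- runif(n, -half, half)
  } else {
    xs <- ys <- numeric(0)
    attempts <- 0L
    budget <- n * maxAttempts
    while (length(xs) < n && attempts < budget) {
      attempts <- attempts + 1L
      cx <- runif(1, -half, half)
      cy <- runif(1, -half, half)
      if (length(xs) == 0 ||
          min((xs - cx)^2 + (ys - cy)^2) >= minSpacing^2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    if (length(xs) < n)
      stop(sprintf(paste0("hard-core placement infeasible: placed %d of %d ",
                          "requested nuclei at minSpacing = %g um"),
                   length(xs), n, minSpacing))
  }

  # lognormal radii, cv on the natural scale, truncated > 0 by construction
  if (radiusCv > 0) {
    sl <- sqrt(log(1 + radiusCv^2))
    radii <- exp(rnorm(n, log(meanRadius) - sl^2 / 2, sl))
  } else radii <- rep(meanRadius, n)
  ecc <- runif(n, 0, eccentricityMax)
  # keep area pi*r^2: a = r/sqrt(ratio), b = r*sqrt(ratio), ratio = b/a
  ratio <- sqrt(1 - ecc^2)
  a <- radii / sqrt(ratio)
  b <- radii * sqrt(ratio)
  data.frame(
    x_um = xs, y_um = ys, a_um = a, b_um = b,
    theta_rad = runif(n, 0, pi),
    uptake = pmin(1, pmax(0, rnorm(n, 0.9, 0.05)))
  )
}

#' Render a phantom from a nuclei list
#'
#' Rasterizes the ellipse field into co-registered absorption (single-pass
#' optical depth), fluorescence (relative emission yield) and diffuse
#' reflectance maps on a common micrometre grid. Inside each ellipse the
#' absorption is background + uptake * (nuclear - background); the
#' fluorescence map is built analogously from the fluorescence yields.
#' Ellipse edges are anti-aliased by 4x4 supersampling of the indicator.
#'
#' @param nuclei data.frame as returned by [generateNucleiField()]
#' @param fieldExtent square field side (um)
#' @param pixelPitch grid pitch (um)
#' @param nuclearOpticalDepth single-pass optical depth of a fully stained
#'   nucleus (methylene-blue absorption)
#' @param backgroundOpticalDepth optical depth of unstained background
#' @param nuclearFluorYield relative fluorescence emission of a fully
#'   stained nucleus (proflavine)
#' @param backgroundFluorYield background fluorescence level
#' @param diffuseReflectance stain-free diffuse tissue reflectance in [0, 1]
#' @param seed recorded provenance seed
#'
#' @return a [Phantom-class] object
#' @export
renderPhantom <- function(nuclei, fieldExtent = 800, pixelPitch = 1,
                          nuclearOpticalDepth = 0.8,
                          backgroundOpticalDepth = 0.05,
                          nuclearFluorYield = 0.8,
                          backgroundFluorYield = 0.05,
                          diffuseReflectance = 0.6,
                          seed = NA_real_) {
  stopifnot(nuclearOpticalDepth >= backgroundOpticalDepth,
            backgroundOpticalDepth >= 0, pixelPitch > 0,
            diffuseReflectance >= 0, diffuseReflectance <= 1)
  npx <- as.integer(round(fieldExtent / pixelPitch))
  if (npx < 1) stop("non-positive grid dimensions")
  cov <- .renderCoverage(nuclei, npx, pixelPitch, fieldExtent,
                         weight = nuclei$uptake)
  absMap <- backgroundOpticalDepth +
    cov * (nuclearOpticalDepth - backgroundOpticalDepth)
  fluMap <- backgroundFluorYield +
    cov * (nuclearFluorYield - backgroundFluorYield)
  refMap <- matrix(diffuseReflectance, npx, npx)
  new("Phantom", nuclei = nuclei, absorptionMap = absMap,
      fluorescenceMap = fluMap, reflectanceMap = refMap,
      pixelPitch = pixelPitch, fieldExtent = fieldExtent, seed = seed)
}

# weighted anti-aliased coverage raster: sum over nuclei of
# weight_i * (supersampled ellipse indicator), clamped to [0, max weight]
.renderCoverage <- function(nuclei, npx, pitch, extent, weight = NULL) {
  cov <- matrix(0, npx, npx)
  if (nrow(nuclei) == 0) return(cov)
  if (is.null(weight)) weight <- rep(1, nrow(nuclei))
  half <- extent / 2
  sub <- (seq_len(4) - 2.5) / 4 * pitch
  for (k in seq_len(nrow(nuclei))) {
    cx <- nuclei$x_um[k]; cy <- nuclei$y_um[k]
    a <- nuclei$a_um[k]; b <- nuclei$b_um[k]
    th <- nuclei$theta_rad[k]
    rmax <- a + pitch
    # window of pixel indices (rows = y, cols = x)
    jlo <- max(1L, floor((cx - rmax + half) / pitch) + 1L)
    jhi <- min(npx, ceiling((cx + rmax + half) / pitch))
    ilo <- max(1L, floor((cy - rmax + half) / pitch) + 1L)
    ihi <- min(npx, ceiling((cy + rmax + half) / pitch))
    if (jlo > jhi || ilo > ihi) next
    xs <- (seq(jlo, jhi) - 0.5) * pitch - half
    ys <- (seq(ilo, ihi) - 0.5) * pitch - half
    ct <- cos(th); st <- sin(th)
    acc <- matrix(0, length(ys), length(xs))
    for (dx in sub) for (dy in sub) {
      X <- matrix(xs + dx, length(ys), length(xs), byrow = TRUE) - cx
      Y <- matrix(ys + dy, length(ys), length(xs)) - cy
      u <- X * ct + Y * st
      v <- -X * st + Y * ct
      acc <- acc + ((u / a)^2 + (v / b)^2 <= 1)
    }
    cov[ilo:ihi, jlo:jhi] <- cov[ilo:ihi, jlo:jhi] + weight[k] * acc / 16
  }
  pmin(cov, max(weight))
}

#' Convenience phantom constructor with study defaults
#'
#' Generates nuclei and renders all channels in one call. Defaults place
#' roughly 350-450 nuclei inside a 790 um circular FOV.
#'
#' @inheritParams generateNucleiField
#' @inheritParams renderPhantom
#' @param ... passed on to [renderPhantom()]
#' @return a [Phantom-class] object
#' @export
makePhantom <- function(fieldExtent = 800, density = 820, meanRadius = 4,
                        radiusCv = 0.1, eccentricityMax = 0.3,
                        minSpacing = 18, seed = 1, pixelPitch = 1, ...) {
  nuc <- generateNucleiField(fieldExtent, density, meanRadius, radiusCv,
                             eccentricityMax, minSpacing, seed)
  renderPhantom(nuc, fieldExtent = fieldExtent, pixelPitch = pixelPitch,
                seed = seed, ...)
}

#' Binary masks of nucleus interiors and clean background
#'
#' Foreground = pixels well inside a nucleus (supersampled coverage above
#' \code{fgThreshold}); background = pixels farther than \code{margin} um
#' from every ellipse. Used as ground-truth masks for contrast metrics.
#'
#' @param phantom a [Phantom-class] object
#' @param fgThreshold minimum ellipse coverage for foreground membership
#' @param margin background guard distance from any nucleus (um)
#' @return list(fg, bg) of logical matrices on the phantom grid
#' @export
truthMasks <- function(phantom, fgThreshold = 0.99, margin = 3) {
  npx <- nrow(phantom@absorptionMap)
  cov <- .renderCoverage(phantom@nuclei, npx, phantom@pixelPitch,
                         phantom@fieldExtent)
  grown <- phantom@nuclei
  if (nrow(grown) > 0) {
    grown$a_um <- grown$a_um + margin
    grown$b_um <- grown$b_um + margin
  }
  covGrown <- .renderCoverage(grown, npx, phantom@pixelPitch,
                              phantom@fieldExtent)
  list(fg = cov >= fgThreshold, bg = covGrown == 0)
}

#' Nuclei ground truth accessor
#' @param object a [Phantom-class] object
#' @return data.frame of nucleus records
#' @export
nuclei <- function(object) object@nuclei

#' Map accessors
#' @param object a [Phantom-class] object
#' @return numeric matrix on the phantom grid
#' @export
absorptionMap <- function(object) object@absorptionMap

#' @rdname absorptionMap
#' @export
fluorescenceMap <- function(object) object@fluorescenceMap

#' @rdname absorptionMap
#' @export
reflectanceMap <- function(object) object@reflectanceMap

setMethod("show", "Phantom", function(object) {
  d <- dim(object@absorptionMap)
  cat(sprintf(paste0("Phantom: %d nuclei | %d x %d grid @ %g um | ",
                     "field %g um | seed %s\n"),
              nrow(object@nuclei), d[1], d[2], object@pixelPitch,
              object@fieldExtent, format(object@seed)))
})

#' Write phantom ground truth and maps to disk
#'
#' Nuclei as CSV, each map as 32-bit float TIFF, parameters in a JSON
#' sidecar.
#'
#' @param phantom a [Phantom-class] object
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return invisibly, the vector of files written
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fcsv <- file.path(dir, paste0(prefix, "_nuclei.csv"))
  write.csv(phantom@nuclei, fcsv, row.names = FALSE)
  maps <- list(absorption = phantom@absorptionMap,
               fluorescence = phantom@fluorescenceMap,
               reflectance = phantom@reflectanceMap)
  files <- fcsv
  for (nm in names(maps)) {
    f <- file.path(dir, paste0(prefix, "_", nm, ".tif"))
    m <- maps[[nm]]
    tiff::writeTIFF(m / max(max(m), 1), f, bits.per.sample = 32)
    files <- c(files, f)
  }
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(pixel_pitch_um = phantom@pixelPitch,
                            field_extent_um = phantom@fieldExtent,
                            n_nuclei = nrow(phantom@nuclei),
                            rng_seed = phantom@seed),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(files, side))
}
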