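# Run configuration: one serializable list drives phantom generation,
# bundle geometry, per-mode acquisition, scan sequence, restoration and
# analysis. YAML and JSON are both accepted; flags override file values,
# which override built-in defaults.

#' Default run configuration
#'
#' Nested list of every tunable parameter with the package defaults, the
#' same defaults the individual constructors use.
#'
#' @param seed global seed; per-stage substream seeds are derived from it
#'   with [deriveSeed()]
#' @return named nested list
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    phantom = list(field_extent_um = 800, pixel_pitch_um = 1,
                   density_per_mm2 = 820, mean_radius_um = 4,
                   radius_cv = 0.1, eccentricity_max = 0.3,
                   min_spacing_um = 18,
                   nuclear_optical_depth = 0.8,
                   background_optical_depth = 0.05,
                   nuclear_fluor_yield = 0.8,
                   background_fluor_yield = 0.05,
                   diffuse_reflectance = 0.6,
                   # staining metadata (recorded, not simulated spectrally)
                   stain_reflectance = "methylene blue 0.3% w/v in deionized water",
                   stain_fluorescence = "proflavine 0.01% w/v in PBS"),
    bundle = list(fov_diameter_um = 790, core_pitch_um = 4.5,
                  core_radius_um = 1.6, fill_transmission = 1,
                  cladding_level = 0.15),
    scan = list(band_height_rows = 16, offset_rows = 4, line_width_rows = 8),
    acquisition = list(r_spec = 20, leakage = 0.1, background = 0.02,
                       illumination = 1500, double_pass = TRUE,
                       shot_noise = TRUE, read_noise_sd = 3, gain = 1,
                       bit_depth = 12, scatter_sigma_um = 30),
    processing = list(sigma_um = NA, target_mean = 0.4, clip_limit = 2,
                      tile_grid = 8),
    analysis = list(n_rois = 25, roi_size_um = 100, min_radius_um = 2.5,
                    max_radius_um = 6.5, response_threshold = 0.04)
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults; anything omitted
#' keeps its default. Unknown keys raise an error naming the field.
#'
#' @param path file ending in .yaml/.yml or .json
#' @param seed optional seed overriding both file and default (CLI
#'   precedence: flag > file > default)
#' @return merged configuration list
#' @export
loadRunConfig <- function(path = NULL, seed = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- .mergeConfig(cfg, user, "")
  }
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

.mergeConfig <- function(base, user, prefix) {
  for (nm in names(user)) {
    full <- paste0(prefix, nm)
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration field '%s'", full))
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]], paste0(full, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Derive a deterministic per-stage substream seed
#'
#' Splits one global seed into independent small-integer substreams so
#' stages (phantom generation, each acquisition mode, ...) can be rerun
#' in isolation. The derivation is seed * 1009 + stream index, folded into
#' the 31-bit integer range.
#'
#' @param seed global integer seed
#' @param stream stage name (one of the fixed stream labels) or an integer
#' @return integer seed
#' @export
deriveSeed <- function(seed, stream) {
  streams <- c(phantom = 1, widefield_reflectance = 2, darkfield = 3,
               fluorescence = 4, noise = 5, analysis = 6)
  k <- if (is.character(stream)) {
    if (!stream %in% names(streams))
      stop(sprintf("unknown seed stream '%s'", stream))
    streams[[stream]]
  } else as.integer(stream)
  as.integer((as.numeric(seed) * 1009 + k) %% (2^31 - 1))
}

#' Run the full simulation described by a configuration
#'
#' Builds the phantom and bundle, acquires the three modes and returns all
#' intermediate objects; the workhorse behind the CLI's `simulate`.
#'
#' @param cfg configuration list from [defaultRunConfig()] /
#'   [loadRunConfig()]
#' @return list(phantom, bundle, scanSeq, frames, configs)
#' @export
simulateRun <- function(cfg = defaultRunConfig()) {
  p <- cfg$phantom
  phantom <- makePhantom(
    fieldExtent = p$field_extent_um, density = p$density_per_mm2,
    meanRadius = p$mean_radius_um, radiusCv = p$radius_cv,
    eccentricityMax = p$eccentricity_max, minSpacing = p$min_spacing_um,
    seed = deriveSeed(cfg$seed, "phantom"), pixelPitch = p$pixel_pitch_um,
    nuclearOpticalDepth = p$nuclear_optical_depth,
    backgroundOpticalDepth = p$background_optical_depth,
    nuclearFluorYield = p$nuclear_fluor_yield,
    backgroundFluorYield = p$background_fluor_yield,
    diffuseReflectance = p$diffuse_reflectance)
  b <- cfg$bundle
  bundle <- buildBundle(b$fov_diameter_um, b$core_pitch_um, b$core_radius_um,
                        b$fill_transmission, b$cladding_level)
  s <- cfg$scan
  scanSeq <- makeScanSequence(nrow(phantom@absorptionMap),
                              s$band_height_rows, s$offset_rows,
                              s$line_width_rows)
  a <- cfg$acquisition
  modes <- c("widefield_reflectance", "darkfield", "fluorescence")
  configs <- stats::setNames(lapply(modes, function(m)
    acquisitionConfig(mode = m, rSpec = a$r_spec, leakage = a$leakage,
                      background = a$background, illumination = a$illumination,
                      doublePass = a$double_pass, shotNoise = a$shot_noise,
                      readNoiseSd = a$read_noise_sd, gain = a$gain,
                      bitDepth = a$bit_depth, scatterSigma = a$scatter_sigma_um,
                      seed = deriveSeed(cfg$seed, m))), modes)
  frames <- stats::setNames(lapply(modes, function(m)
    acquireFrame(phantom, bundle, configs[[m]], scanSeq)), modes)
  list(phantom = phantom, bundle = bundle, scanSeq = scanSeq,
       frames = frames, configs = configs)
}
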