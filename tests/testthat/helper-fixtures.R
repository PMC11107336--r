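# Shared fixtures, built in code. Small geometries keep unit tests fast;
# acceptance tests use the full study defaults.

tinyBundle <- function(fov = 120, pitch = 4.5, radius = 1.6, ...) {
  buildBundle(fov, pitch, radius, ...)
}

# ~20-30 nuclei in a 128 um field, denser than the study default so small
# fields still carry enough blobs to detect
tinyPhantom <- function(seed = 1, extent = 128, density = 2000,
                        minSpacing = 14, ...) {
  makePhantom(fieldExtent = extent, density = density,
              minSpacing = minSpacing, seed = seed, ...)
}

noiseFree <- function(mode, ...) {
  acquisitionConfig(mode = mode, shotNoise = FALSE, readNoiseSd = 0, ...)
}

# memoised full-scale three-mode reports for the multi-seed acceptance
# properties (shared between the contrast-ordering and count-agreement
# checks so the 10-seed simulation runs once)
.reportCache <- new.env(parent = emptyenv())

acceptanceReports <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.reportCache[[key]])) return(.reportCache[[key]])
  bundle <- buildBundle()
  reports <- lapply(seeds, function(s)
    compareModes(makePhantom(seed = s), bundle, seed = s))
  .reportCache[[key]] <- reports
  reports
}
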