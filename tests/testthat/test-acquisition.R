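# absorbing void phantom: no diffuse return, no stain, no fluorescence --
# only fiber-surface specular reflection can reach the sensor
voidPhantom <- function(extent = 128) {
  renderPhantom(generateNucleiField(extent, density = 0),
                fieldExtent = extent, pixelPitch = 1,
                nuclearOpticalDepth = 0, backgroundOpticalDepth = 0,
                nuclearFluorYield = 0, backgroundFluorYield = 0,
                diffuseReflectance = 0)
}

test_that("scan sequence tiles the sensor and respects the guard gap", {
  sq <- makeScanSequence(12, bandHeight = 4, offsetRows = 1, lineWidth = 2)
  expect_equal(nrow(sq@steps), 3)
  a <- auditScanSequence(sq)
  expect_true(a$ok)
  expect_true(all(a$coverage == 1))
  expect_equal(a$overlapRows, 0)
  # tiling conservation
  expect_equal(sum(sq@steps$det_end - sq@steps$det_start), 12)
})

test_that("infeasible scan geometry is rejected", {
  expect_error(makeScanSequence(32, bandHeight = 32), "infeasible")
  expect_error(makeScanSequence(16, bandHeight = 8, offsetRows = 3,
                                lineWidth = 2), "infeasible")
})

test_that("randomized valid geometries always pass the per-row audit", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(48:400, 1)
    band <- sample(4:24, 1)
    off <- sample(1:6, 1)
    lw <- sample(1:10, 1)
    if (band + 2 * (off + lw) > n) next
    sq <- makeScanSequence(n, band, off, lw)
    a <- auditScanSequence(sq)
    expect_true(a$ok)
    expect_true(all(a$coverage == 1))
    expect_gte(a$minGap, off)
  }
})

test_that("unstained tissue returns the diffuse reflectance everywhere", {
  ph <- renderPhantom(generateNucleiField(128, density = 0),
                      fieldExtent = 128, pixelPitch = 1,
                      nuclearOpticalDepth = 0, backgroundOpticalDepth = 0,
                      diffuseReflectance = 0.6)
  b <- tinyBundle()
  tr <- tissueReturn(ph, b, "widefield_reflectance")
  expect_true(all(abs(tr$field - 0.6) < 1e-12))
})

test_that("double-pass Beer-Lambert sets the nucleus-to-background ratio", {
  nuc <- data.frame(x_um = 0, y_um = 0, a_um = 6, b_um = 6,
                    theta_rad = 0, uptake = 1)
  ph <- renderPhantom(nuc, fieldExtent = 129, pixelPitch = 1,
                      nuclearOpticalDepth = 0.7,
                      backgroundOpticalDepth = 0,
                      diffuseReflectance = 0.5)
  b <- tinyBundle()
  tr <- tissueReturn(ph, b, "darkfield")
  centre <- tr$field[65, 65]
  corner <- tr$field[5, 5]
  expect_equal(centre / corner, exp(-2 * 0.7), tolerance = 1e-9)
  single <- tissueReturn(ph, b, "darkfield", doublePass = FALSE)
  expect_equal(single$field[65, 65] / corner, exp(-0.7), tolerance = 1e-9)
})

test_that("fluorescence of an unstained void phantom is all zero", {
  ph <- voidPhantom()
  b <- tinyBundle()
  f <- acquireWidefield(ph, b, noiseFree("fluorescence"))
  expect_true(all(f@pixels == 0))
})

test_that("unknown mode errors", {
  expect_error(tissueReturn(tinyPhantom(), tinyBundle(), "brightfield"),
               "unknown mode")
})

test_that("zero illumination gives an exactly zero noise-free frame", {
  f <- acquireWidefield(tinyPhantom(), tinyBundle(),
                        noiseFree("widefield_reflectance", illumination = 0))
  expect_true(all(f@pixels == 0))
})

test_that("void phantom widefield is the specular fill pattern, linear in R_spec", {
  ph <- voidPhantom()
  b <- tinyBundle()
  # L*eps*R integer-valued so quantization is exact
  f1 <- acquireWidefield(ph, b, noiseFree("widefield_reflectance",
                                          rSpec = 0.3, leakage = 0.1,
                                          background = 0, illumination = 1500))
  f2 <- acquireWidefield(ph, b, noiseFree("widefield_reflectance",
                                          rSpec = 0.6, leakage = 0.1,
                                          background = 0, illumination = 1500))
  mask <- fovMask(b, 1, 128)
  # exact doubling on core pixels (cladding pixels can differ by one count
  # when quantization ties fall either side of half)
  corePx <- f1@pixels == 45L  # 1500 * 0.1 * 0.3
  expect_gt(sum(corePx), 1000)
  expect_true(all(f2@pixels[corePx] == 90L))
  expect_lte(max(abs(f2@pixels[mask] - 2 * f1@pixels[mask])), 1)
  expect_true(all(f1@pixels[!mask] == 0))
})

test_that("specular rejection is exact for any R_spec with zero leakage", {
  ph <- voidPhantom()
  b <- tinyBundle()
  sq <- makeScanSequence(128)
  for (R in c(0.01, 1, 100, 10000)) {
    f <- acquireDarkfield(ph, b, noiseFree("darkfield", rSpec = R,
                                           leakage = 0), sq)
    expect_true(all(f@pixels == 0))
  }
})

test_that("darkfield equals specular-free widefield in the uniform-spread limit", {
  ph <- tinyPhantom(seed = 8)
  b <- tinyBundle()
  sq <- makeScanSequence(128)
  fw <- acquireWidefield(ph, b, noiseFree("widefield_reflectance",
                                          rSpec = 0, background = 0))
  fd <- acquireDarkfield(ph, b, noiseFree("darkfield", rSpec = 7,
                                          background = 0,
                                          scatterSigma = Inf), sq)
  expect_identical(fw@pixels, fd@pixels)
})

test_that("aperture overlap reintroduces specular signal", {
  ph <- voidPhantom()
  b <- tinyBundle()
  sq <- makeScanSequence(128)
  # force the illumination lines onto the detection band, bypassing the
  # constructor's validator
  bad <- sq
  bad@steps$ill1_start <- bad@steps$det_start
  bad@steps$ill1_end <- bad@steps$det_end
  expect_false(auditScanSequence(bad)$ok)
  f <- acquireDarkfield(ph, b, noiseFree("darkfield", rSpec = 10,
                                         leakage = 0.1), bad)
  expect_gt(max(f@pixels), 0)
})

test_that("noise model is the identity when both sources are off", {
  frame <- matrix(as.numeric(0:99), 10, 10)
  out <- addSensorNoise(frame, noiseFree("darkfield"))
  expect_equal(out, matrix(as.integer(frame), 10, 10))
})

test_that("noise model rejects negative input", {
  expect_error(addSensorNoise(matrix(-1, 2, 2), noiseFree("darkfield")),
               "negative")
})

test_that("shot noise is Poisson: variance over mean near one", {
  cfg <- acquisitionConfig(shotNoise = TRUE, readNoiseSd = 0,
                           bitDepth = 16, seed = 21)
  fr <- addSensorNoise(matrix(10000, 350, 350), cfg)
  fano <- var(as.numeric(fr)) / mean(fr)
  expect_gt(fano, 0.9); expect_lt(fano, 1.1)
})

test_that("read noise sd matches the configured value within 5%", {
  cfg <- acquisitionConfig(shotNoise = FALSE, readNoiseSd = 12,
                           bitDepth = 16, seed = 22)
  fr <- addSensorNoise(matrix(2000, 350, 350), cfg)
  expect_lt(abs(sd(as.numeric(fr)) - 12) / 12, 0.05)
})

test_that("acquisition is deterministic given one seed and config", {
  ph <- tinyPhantom(seed = 2)
  b <- tinyBundle()
  sq <- makeScanSequence(128)
  cfg <- acquisitionConfig("darkfield", seed = 77)
  f1 <- acquireDarkfield(ph, b, cfg, sq)
  f2 <- acquireDarkfield(ph, b, cfg, sq)
  expect_identical(f1@pixels, f2@pixels)
})

test_that("background subtraction removes the stray term and clips at zero", {
  ph <- voidPhantom()
  b <- tinyBundle()
  cfg <- noiseFree("widefield_reflectance", rSpec = 0, background = 0.02)
  stray <- acquireWidefield(ph, b, cfg)
  expect_gt(max(stray@pixels), 0)
  diffF <- subtractBackground(stray, stray)
  expect_true(all(diffF@pixels == 0))
  # subtracting a brighter frame clips to zero rather than going negative
  brighter <- stray
  brighter@pixels <- stray@pixels + 5L
  expect_true(all(subtractBackground(stray, brighter)@pixels == 0))
  # with tissue present the stray pattern cancels to within quantization
  ph2 <- tinyPhantom(seed = 3)
  tissue <- acquireWidefield(ph2, b, cfg)
  resid <- subtractBackground(tissue, stray)
  clean <- acquireWidefield(ph2, b, noiseFree("widefield_reflectance",
                                              rSpec = 0, background = 0))
  expect_lte(max(abs(resid@pixels - clean@pixels)), 1)
})

test_that("background subtraction requires matching shapes", {
  ph <- tinyPhantom(seed = 2)
  b <- tinyBundle()
  f <- acquireWidefield(ph, b, noiseFree("widefield_reflectance"))
  small <- acquireWidefield(voidPhantom(64), buildBundle(60, 4.5, 1.6),
                            noiseFree("widefield_reflectance"))
  expect_error(subtractBackground(f, small), "shape")
})

test_that("raw frames round-trip through TIFF with config sidecar", {
  ph <- tinyPhantom(seed = 2)
  b <- tinyBundle()
  f <- acquireWidefield(ph, b, noiseFree("widefield_reflectance", seed = 4))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "frame.tif")
  writeRawFrame(f, path)
  back <- readRawFrame(path)
  expect_identical(back@pixels, f@pixels)
  expect_equal(back@mode, f@mode)
  expect_equal(back@config@bitDepth, f@config@bitDepth)
})
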