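# brute-force hexagonal lattice enumeration, independent of the package's
# constructor: row j at y = j*pitch*sqrt(3)/2, x offset half a pitch on
# alternate rows (mirrored across j = 0)
enumerateHexCores <- function(fov, pitch, radius) {
  rmax <- fov / 2 - radius
  dy <- pitch * sqrt(3) / 2
  count <- 0L
  for (j in seq(-ceiling(rmax / dy), ceiling(rmax / dy))) {
    off <- (abs(j) %% 2) / 2
    for (i in seq(-ceiling(rmax / pitch) - 1, ceiling(rmax / pitch) + 1)) {
      x <- (i + off) * pitch; y <- j * dy
      if (x^2 + y^2 <= rmax^2 + 1e-9) count <- count + 1L
    }
  }
  count
}

test_that("degenerate bundle has exactly one core at the centre", {
  b <- buildBundle(fovDiameter = 4.5, corePitch = 4.5, coreRadius = 4.5 / 4)
  expect_equal(nCores(b), 1)
  expect_equal(as.numeric(coreCenters(b)), c(0, 0))
})

test_that("core count matches exhaustive lattice enumeration", {
  b <- buildBundle(790, 4.5, 1.6)
  expect_equal(nCores(b), enumerateHexCores(790, 4.5, 1.6))
  expect_gt(nCores(b), 2.7e4)
  expect_lt(nCores(b), 3.1e4)
})

test_that("doubling the pitch divides the core count by about four", {
  n1 <- nCores(buildBundle(790, 4.5, 1.6))
  n2 <- nCores(buildBundle(790, 9.0, 1.6))
  expect_lt(abs(n1 / n2 - 4), 0.2)
})

test_that("interior cores have six nearest neighbours at one pitch", {
  b <- buildBundle(100, 4.5, 1.6)
  cc <- coreCenters(b)
  interior <- which(sqrt(rowSums(cc^2)) < 100 / 2 - 3 * 4.5)
  for (k in interior[c(1, floor(length(interior) / 2), length(interior))]) {
    d <- sqrt((cc[, 1] - cc[k, 1])^2 + (cc[, 2] - cc[k, 2])^2)
    nn <- sort(d)[2:7]
    expect_equal(nn, rep(4.5, 6), tolerance = 1e-9)
  }
})

test_that("parameter ordering violations are rejected", {
  expect_error(buildBundle(790, 4.5, 3), "corePitch")
  expect_error(buildBundle(4, 4.5, 1.6), "fovDiameter")
})

test_that("a constant field samples to fill-transmission-scaled constants", {
  b <- tinyBundle(fillTransmission = 0.8)
  field <- matrix(2.5, 128, 128)
  s <- sampleThroughBundle(field, b, 1)
  expect_equal(s, rep(2.5 * 0.8, nCores(b)))
})

test_that("a single bright pixel lights exactly one core", {
  b <- tinyBundle()
  cc <- coreCenters(b)
  field <- matrix(0, 128, 128)
  # pixel centred on the first core's centre
  i <- round(cc[1, 2] + 64 + 0.5); j <- round(cc[1, 1] + 64 + 0.5)
  field[i, j] <- 1
  s <- sampleThroughBundle(field, b, 1)
  expect_equal(sum(s > 0), 1)
  expect_gt(s[1], 0)
})

test_that("per-core means match a naive disk-membership average", {
  b <- tinyBundle(fov = 40)
  set.seed(11)
  field <- matrix(runif(48 * 48), 48, 48)
  s <- sampleThroughBundle(field, b, 1)
  cc <- coreCenters(b)
  for (k in seq_len(nCores(b))) {
    acc <- c(); n <- 0
    for (i in 1:48) for (j in 1:48) {
      x <- j - 0.5 - 24; y <- i - 0.5 - 24
      if ((x - cc[k, 1])^2 + (y - cc[k, 2])^2 <= 1.6^2)
        acc <- c(acc, field[i, j])
    }
    expect_equal(s[k], mean(acc), tolerance = 1e-12)
  }
})

test_that("uniform signals render a honeycomb with lattice-frequency power", {
  b <- buildBundle(200, 4.5, 1.6, claddingLevel = 0.15)
  img <- renderBundleImage(rep(1, nCores(b)), b, 1, 200)
  f0 <- latticeFrequency(b)
  pPeak <- latticePeakPower(img, 0, f0)
  pOff <- latticePeakPower(img, 0, f0 * 0.62)
  expect_gt(pPeak / pOff, 100)
})

test_that("full cladding with uniform signals erases the honeycomb", {
  b <- tinyBundle(claddingLevel = 1)
  img <- renderBundleImage(rep(3, nCores(b)), b, 1, 128)
  mask <- fovMask(b, 1, 128)
  # constant over the core-covered disk (inside the outermost core ring)
  cc <- (seq_len(128) - 0.5) - 64
  interior <- outer(cc^2, cc^2, "+") <= (60 - 4.5)^2
  expect_true(all(img[interior] == 3))
  expect_true(all(img[!mask] == 0))
})

test_that("a single nonzero core renders only inside its own disk", {
  b <- tinyBundle(claddingLevel = 0)
  s <- rep(0, nCores(b)); s[5] <- 1
  img <- renderBundleImage(s, b, 1, 128)
  cc <- coreCenters(b)
  on <- which(img > 0, arr.ind = TRUE)
  x <- on[, 2] - 0.5 - 64; y <- on[, 1] - 0.5 - 64
  expect_true(all((x - cc[5, 1])^2 + (y - cc[5, 2])^2 <= 1.6^2))
  expect_gt(nrow(on), 0)
})

test_that("rendered image is bounded by the core signals", {
  b <- tinyBundle()
  set.seed(3)
  s <- runif(nCores(b))
  img <- renderBundleImage(s, b, 1, 128)
  expect_lte(max(img), max(s))
  expect_gte(min(img), 0)
})

test_that("sample-render round trip recovers smooth core signals", {
  b <- tinyBundle()
  cc <- coreCenters(b)
  s <- 1 + 0.3 * sin(cc[, 1] / 30) + 0.3 * cos(cc[, 2] / 40)
  img <- renderBundleImage(s, b, 1, 128)
  s2 <- sampleThroughBundle(img, b, 1)
  expect_lt(max(abs(s2 - s) / s), 0.02)
})
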