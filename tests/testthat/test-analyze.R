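# noise-free darkfield image of a sparse phantom: every nucleus should be
# recoverable
cleanScene <- function(seed = 1, extent = 256, density = 450,
                       minSpacing = 30) {
  ph <- makePhantom(fieldExtent = extent, density = density,
                    minSpacing = minSpacing, seed = seed)
  b <- buildBundle(extent - 10, 4.5, 1.6)
  f <- acquireFrame(ph, b, noiseFree("darkfield"), makeScanSequence(extent))
  list(phantom = ph, bundle = b, pimg = processPipeline(f, b))
}

test_that("a blank image yields zero detections", {
  det <- detectNuclei(matrix(0.5, 96, 96), "dark")
  expect_equal(nrow(det), 0)
})

test_that("well-separated nuclei are recovered with high precision and recall", {
  sc <- cleanScene(seed = 31)
  all <- nuclei(sc$phantom)
  interiorIdx <- as.integer(rownames(nucleiInFov(sc$phantom, sc$bundle)))
  det <- detectNuclei(sc$pimg, "dark")
  m <- matchDetections(det, all, mean(sqrt(all$a_um * all$b_um)))
  expect_gte(m$precision, 0.95)
  recall <- length(intersect(m$matches$truth, interiorIdx)) /
    length(interiorIdx)
  expect_gte(recall, 0.95)
})

test_that("inverting the image and flipping polarity gives identical detections", {
  sc <- cleanScene(seed = 32)
  d1 <- detectNuclei(sc$pimg, "dark")
  inv <- sc$pimg
  inv@pixels <- 1 - inv@pixels
  inv@linear <- 1 - inv@linear
  d2 <- detectNuclei(inv, "bright")
  expect_equal(d1[, c("x_um", "y_um", "r_um")], d2[, c("x_um", "y_um", "r_um")])
  expect_equal(d1$score, d2$score, tolerance = 1e-9)
})

test_that("a too-narrow radius band errors", {
  expect_error(detectNuclei(matrix(0.5, 32, 32), "dark", nScales = 1),
               "scale step")
  expect_error(detectNuclei(matrix(0.5, 32, 32), "dark", minRadius = 5,
                            maxRadius = 4))
})

test_that("the default ROI grid is a 5x5 disjoint tiling inside the FOV", {
  g <- makeRoiGrid(790, 25, 100)
  r <- g@rects
  expect_equal(nrow(r), 25)
  # all inside the circular FOV: corners within radius
  corners <- rbind(cbind(r$xmin, r$ymin), cbind(r$xmin, r$ymax),
                   cbind(r$xmax, r$ymin), cbind(r$xmax, r$ymax))
  expect_true(all(sqrt(rowSums(corners^2)) <= 395 + 1e-9))
  # exhaustive pairwise disjointness
  for (i in 1:24) for (j in (i + 1):25) {
    overlap <- r$xmin[i] < r$xmax[j] && r$xmin[j] < r$xmax[i] &&
               r$ymin[i] < r$ymax[j] && r$ymin[j] < r$ymax[i]
    expect_false(overlap)
  }
})

test_that("single-ROI grids and infeasible packings behave as specified", {
  g1 <- makeRoiGrid(790, 1, 100)
  expect_equal(as.numeric(g1@rects[1, ]), c(-50, -50, 50, 50))
  expect_error(makeRoiGrid(790, 25, 150), "inscribed")
  expect_error(makeRoiGrid(790, 24, 100), "perfect square")
})

test_that("ROI counting uses half-open rectangles and n-1 sd", {
  g <- makeRoiGrid(400, 4, 100)
  # a detection exactly on the shared internal edge belongs to one ROI only
  det <- data.frame(x_um = 0, y_um = -30, score = 1)
  cnt <- countInRois(det, g)
  expect_equal(sum(cnt$counts), 1)
  # empty detections
  cnt0 <- countInRois(det[0, ], g)
  expect_equal(cnt0$mean, 0); expect_equal(cnt0$sd, 0)
  # hand-checked mean/sd
  det2 <- data.frame(x_um = c(-50, -50, 50), y_um = c(-50, -50, 50),
                     score = 1)
  cnt2 <- countInRois(det2, g)
  expect_equal(cnt2$mean, 0.75)
  expect_equal(cnt2$sd, sd(c(2, 1, 0, 0)))
})

test_that("ROI count grand mean tracks the point-process intensity", {
  # homogeneous Poisson truth counted directly: E[count] = lambda * area
  g <- makeRoiGrid(790, 25, 100)
  lambda <- 600 / 1e6  # per um^2
  means <- vapply(1:20, function(s) {
    nuc <- generateNucleiField(800, density = 600, minSpacing = 0, seed = s)
    countInRois(nuc, g)$mean
  }, numeric(1))
  expected <- lambda * 100^2
  se <- sqrt(expected / (25 * 20))  # Poisson counts, 500 ROIs total
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("Weber contrast matches hand arithmetic and offset sensitivity", {
  img <- matrix(c(0.8, 0.8, 0.4, 0.4), 2, 2)
  fg <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  bg <- !fg
  cm <- contrastMetrics(img, fg, bg)
  expect_equal(cm$weber, 0.5)
  # additive offset strictly decreases Weber contrast
  cm2 <- contrastMetrics(img + 0.3, fg, bg)
  expect_lt(cm2$weber, cm$weber)
  # degenerate inputs
  expect_equal(contrastMetrics(matrix(0.5, 2, 2), fg, bg)$weber, 0)
  expect_error(contrastMetrics(img, fg & FALSE, bg), "empty")
  expect_error(contrastMetrics(img, fg, fg), "disjoint")
})

test_that("noise-free zero-leakage darkfield and fluorescence counts agree exactly", {
  ph <- makePhantom(fieldExtent = 256, density = 450, minSpacing = 30,
                    seed = 33)
  b <- buildBundle(246, 4.5, 1.6)
  cfgs <- list(
    widefield_reflectance = noiseFree("widefield_reflectance", rSpec = 0,
                                      leakage = 0),
    darkfield = noiseFree("darkfield", leakage = 0),
    fluorescence = noiseFree("fluorescence"))
  rep <- compareModes(ph, b, cfgs, makeScanSequence(256),
                      roiGrid = makeRoiGrid(246, 4, 80))
  expect_equal(rep@agreement$countMeanDarkfield,
               rep@agreement$countMeanFluorescence)
  expect_true(rep@agreement$processingLogsIdentical)
})

test_that("detection recall does not improve with stronger read noise", {
  # full-scale phantoms so the ~400-nucleus sample resolves sub-percent
  # recall changes; read noise is white, so the honeycomb filter averages
  # much of it away and only large sd values bite
  b <- buildBundle()
  sq <- makeScanSequence(800)
  recalls <- vapply(c(0, 150, 400), function(ns) {
    mean(vapply(1:3, function(s) {
      ph <- makePhantom(seed = 40 + s)
      cfg <- acquisitionConfig("darkfield", readNoiseSd = ns,
                               seed = 300 + s)
      f <- acquireDarkfield(ph, b, cfg, sq)
      det <- detectNuclei(processPipeline(f, b), "dark")
      allNuc <- nuclei(ph)
      interiorIdx <- as.integer(rownames(nucleiInFov(ph, b)))
      m <- matchDetections(det, allNuc, 4)
      length(intersect(m$matches$truth, interiorIdx)) / length(interiorIdx)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0.005))
  expect_lt(recalls[3], recalls[1])
})

test_that("analysis reports serialize with all summary fields", {
  ph <- makePhantom(fieldExtent = 256, density = 450, minSpacing = 30,
                    seed = 34)
  b <- buildBundle(246, 4.5, 1.6)
  rep <- compareModes(ph, b, scanSeq = makeScanSequence(256),
                      roiGrid = makeRoiGrid(246, 4, 80), seed = 34)
  dir <- withr::local_tempdir()
  files <- writeAnalysisReport(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "analysis_report.json"))
  for (m in c("widefield_reflectance", "darkfield", "fluorescence")) {
    expect_true(all(c("countMean", "countSd", "weber", "snr", "precision",
                      "recall", "roiCounts") %in% names(js$modes[[m]])))
  }
  expect_true("relDiff" %in% names(js$agreement))
})
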