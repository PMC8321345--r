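test_that("section detection separates tissue blobs from bright background", {
  blank <- array(1, c(64, 64, 3))
  expect_equal(nrow(detectSections(blank)), 0)
  img <- array(0.95, c(120, 200, 3))
  img[10:50, 10:60, ] <- 0.6          # blob 1
  img[70:110, 120:190, ] <- 0.6       # blob 2
  boxes <- detectSections(img)
  expect_equal(nrow(boxes), 2)
  expect_equal(boxes$x0, c(9, 119))   # half-open 0-based boxes
  expect_equal(boxes$y0, c(9, 69))
  expect_equal(boxes$width, c(51, 71))
  # a blob touching the edge is clipped to the image bounds
  img2 <- array(0.95, c(40, 40, 3))
  img2[1:10, 1:10, ] <- 0.5
  b2 <- detectSections(img2)
  expect_equal(unlist(b2[1, ]), c(x0 = 0, y0 = 0, width = 10, height = 10))
})

test_that("tile plans match the overlap formula on the printed examples", {
  p <- planTiles(c(1024, 1024))
  expect_equal(sort(unique(p$x0)), c(0, 256, 512))
  p2 <- planTiles(c(700, 700))
  expect_equal(sort(unique(p2$x0)), c(0, 188))
  expect_gte(512 - 188, 256)
  expect_equal(planTiles(c(512, 512))$x0, 0L)
  expect_equal(planTiles(c(100, 100))$x0, 0L)   # smaller than the patch: padded
  expect_error(planTiles(c(0, 100)), "non-positive")
  expect_error(planTiles(c(100, 100), patchSize = 64, minOverlap = 64))
})

test_that("tile plans cover every pixel with the minimum overlap for all sizes", {
  for (setup in list(c(512L, 256L), c(64L, 32L))) {
    patch <- setup[1]; ov <- setup[2]
    bad <- 0L
    for (L in 1:4096) {
      o <- sort(unique(planTiles(c(L, 8L), patch, ov)$x0))
      okStart <- o[1] == 0L
      okEnd <- L <= patch || o[length(o)] == L - patch
      okOverlap <- length(o) < 2 || all(diff(o) <= patch - ov)
      if (!(okStart && okEnd && okOverlap)) bad <- bad + 1L
    }
    expect_identical(bad, 0L)
  }
})

test_that("stitching averages overlapping tiles and ignores padding", {
  # all tiles constant -> constant heatmap
  p <- planTiles(c(96, 96), 64, 32)
  tiles <- replicate(nrow(p), matrix(0.3, 64, 64), simplify = FALSE)
  hm <- stitchHeatmap(tiles, p, c(96, 96), mpp = 1)
  expect_true(all(abs(probMatrix(hm) - 0.3) < 1e-12))
  # two tiles overlapping on a strip, values 0 and 1 -> strip value 0.5
  org <- data.frame(x0 = c(0L, 32L), y0 = c(0L, 0L))
  hm2 <- stitchHeatmap(list(matrix(0, 64, 64), matrix(1, 64, 64)),
                       org, c(96, 64), mpp = 1)
  pm <- probMatrix(hm2)
  expect_true(all(pm[, 1:32] == 0))
  expect_true(all(pm[, 33:64] == 0.5))
  expect_true(all(pm[, 65:96] == 1))
  # a single tile covering the section is returned unchanged
  tile <- matrix(runif(64 * 64), 64, 64)
  hm3 <- stitchHeatmap(list(tile), data.frame(x0 = 0L, y0 = 0L), c(64, 64), 1)
  expect_equal(probMatrix(hm3), tile)
  # padded parts of an oversized tile are discarded
  hm4 <- stitchHeatmap(list(matrix(0.7, 64, 64)), data.frame(x0 = 0L, y0 = 0L),
                       c(40, 30), 1)
  expect_equal(dim(probMatrix(hm4)), c(30, 40))
  expect_error(stitchHeatmap(list(tile), data.frame(x0 = 70L, y0 = 0L),
                             c(64, 64), 1), "outside")
})

test_that("stitched heatmaps are invariant to tile ordering", {
  set.seed(61)
  p <- planTiles(c(150, 130), 64, 32)
  tiles <- replicate(nrow(p), matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  hm <- stitchHeatmap(tiles, p, c(150, 130), 1)
  ord <- rev(seq_len(nrow(p)))
  hm2 <- stitchHeatmap(tiles[ord], p[ord, ], c(150, 130), 1)
  expect_identical(probMatrix(hm), probMatrix(hm2))
})

test_that("region extraction matches a flood-fill oracle on random heatmaps", {
  set.seed(62)
  for (i in 1:300) {
    h <- sample(4:24, 1); w <- sample(4:24, 1)
    prob <- matrix(runif(h * w), h, w)
    hm <- heatmap2d(prob, mpp = 1)
    thr <- runif(1, 0.3, 0.7)
    conn <- sample(c(4L, 8L), 1)
    regions <- extractRegions(hm, thr, connectivity = conn)
    labels <- attr(regions, "labels")
    oracle <- floodFillOracle(prob >= thr, conn)
    expect_identical(labels, oracle)
    if (nrow(regions)) {
      expect_equal(sort(regions$n_pixels),
                   sort(as.integer(table(oracle[oracle > 0]))))
      # area bookkeeping: total region area equals supra-threshold pixel count
      expect_equal(sum(regions$n_pixels), sum(prob >= thr))
    }
  }
})

test_that("region extraction honours connectivity and physical areas", {
  hm <- heatmap2d(matrix(0.5, 8, 8), 1)
  expect_equal(nrow(extractRegions(hm, 0.60)), 0)
  # one 10x10 block at 0.9, mpp 1: one region of 100 um2
  prob <- matrix(0, 20, 20); prob[3:12, 5:14] <- 0.9
  r <- extractRegions(heatmap2d(prob, 1), 0.60)
  expect_equal(nrow(r), 1)
  expect_equal(r$area_um2, 100)
  expect_equal(r$peak_prob, 0.9)
  # mpp scales areas quadratically
  r2 <- extractRegions(heatmap2d(prob, 2.5), 0.60)
  expect_equal(r2$area_um2, 100 * 2.5^2)
  # diagonal touch: one region under 8-connectivity, two under 4
  dg <- matrix(0, 6, 6); dg[1:2, 1:2] <- 1; dg[3:4, 3:4] <- 1
  expect_equal(nrow(extractRegions(heatmap2d(dg, 1), 0.5, connectivity = 8L)), 1)
  expect_equal(nrow(extractRegions(heatmap2d(dg, 1), 0.5, connectivity = 4L)), 2)
})

test_that("sectionwise calls apply the area filter at reference scale", {
  mk <- function(areas) data.frame(region_id = seq_along(areas),
                                   n_pixels = as.integer(areas),
                                   area_um2 = areas,
                                   peak_prob = rep(0.9, length(areas)))
  # a 63,744 um2 nest survives the 5120 um2 threshold
  expect_equal(sectionLabel(classifySection(mk(63744), 5120)), "Tumor")
  # a 544 um2 remnant does not
  expect_equal(sectionLabel(classifySection(mk(544), 5120)), "Normal")
  expect_equal(sectionLabel(classifySection(mk(numeric(0)), 5120)), "Normal")
  expect_equal(sectionLabel(classifySection(mk(5120), 5120)), "Tumor")  # >= keeps
  expect_error(classifySection(mk(100), -1), "negative")
})

test_that("raising either threshold never converts Normal to Tumor", {
  set.seed(63)
  for (i in 1:30) {
    prob <- matrix(runif(30 * 30), 30, 30)
    prob[5:14, 5:14] <- runif(1, 0.5, 1)
    hm <- heatmap2d(prob, 2)
    pts <- sort(runif(3, 0.2, 0.9))
    ats <- sort(runif(3, 0, 800))
    call <- function(pt, at)
      sectionLabel(classifySection(extractRegions(hm, pt), at))
    labs <- outer(pts, ats, Vectorize(call))
    tumor <- labs == "Tumor"
    # monotone non-increasing along both axes
    expect_true(all(tumor[-1, ] <= tumor[-3, ]))
    expect_true(all(tumor[, -1] <= tumor[, -3]))
  }
})

test_that("sections and heatmaps round-trip through PNG with sidecars", {
  img <- array(runif(32 * 40 * 3), c(32, 40, 3))
  f <- tempfile(fileext = ".png")
  writeSection(img, 2.0, f, sectionId = "s7")
  back <- readSection(f)
  expect_equal(back$mpp, 2.0)
  expect_equal(back$sectionId, "s7")
  expect_equal(back$image, img, tolerance = 1 / 255)
  hm <- heatmap2d(matrix(runif(16 * 16), 16, 16), 2.0, "s7")
  fh <- tempfile(fileext = ".png")
  writeHeatmap(hm, fh, thresholds = list(prediction_threshold = 0.6))
  hb <- readHeatmap(fh)
  expect_equal(probMatrix(hb), probMatrix(hm), tolerance = 1 / 255)
  expect_equal(mpp(hb), 2.0)
})

test_that("inference requires mpp and composes into section results", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 4,
                                   seed = 64))
  img <- array(0.9, c(80, 80, 3))
  expect_error(runInference(net, img, mpp = NULL, 0.5, 100), "mpp")
  r <- runInference(net, img, mpp = 2, predictionThreshold = 0.5,
                    areaThresholdUm2 = 1e7)
  expect_s4_class(r$result, "SectionResult")
  expect_equal(sectionLabel(r$result), "Normal")  # nothing can beat 10^7 um2
  expect_s4_class(r$heatmap, "Heatmap")
  expect_equal(dim(probMatrix(r$heatmap)), c(80, 80))
})
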