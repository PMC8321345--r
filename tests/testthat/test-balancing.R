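test_that("coverage matches containment and rectangle arithmetic", {
  big <- list(class = "Tumornest",
              coords = cbind(c(-10, 600, 600, -10), c(-10, -10, 600, 600)))
  expect_equal(unname(computeCoverage(c(0, 0), 64, list(big))), c(1, 0, 0))
  expect_equal(unname(computeCoverage(c(0, 0), 64, list())), c(0, 0, 0))
  # 512 tile, axis-aligned 256x512 rectangle over the left half
  rect <- list(class = "Tumornest",
               coords = cbind(c(0, 256, 256, 0), c(0, 0, 512, 512)))
  cov <- computeCoverage(c(0, 0), 512, list(rect))
  expect_equal(unname(cov[["T"]]), 0.5)
  # rasterization equals the per-pixel count
  m <- wsiseg:::rasterizeClass(list(rect), "Tumornest", c(0, 0), 512)
  expect_equal(sum(m), 256 * 512)
})

test_that("rasterization agrees exactly with a point-in-polygon oracle", {
  set.seed(51)
  for (i in 1:12) {
    sz <- sample(8:48, 1)
    polys <- lapply(seq_len(sample(1:3, 1)), function(j)
      randomBlob(runif(1, 0, sz), runif(1, 0, sz), runif(1, 2, sz / 2)))
    got <- wsiseg:::cpp_rasterize_polygons(polys, sz, sz)
    want <- pointInPolygonOracle(polys, sz, sz)
    expect_identical(got, want)
  }
})

test_that("invalid polygons are rejected with a diagnostic", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(computeCoverage(c(0, 0), 16,
                               list(list(class = "Tumornest", coords = bowtie))),
               "self-intersecting")
  expect_error(computeCoverage(c(0, 0), 16,
                               list(list(class = "Tumornest",
                                         coords = cbind(0:1, 0:1)))), ">= 3")
})

test_that("annotations round-trip through GeoJSON", {
  ann <- list(list(class = "Tumornest", coords = randomBlob(20, 20, 8)),
              list(class = "Normal", coords = randomBlob(5, 5, 3)))
  f <- tempfile(fileext = ".geojson")
  writeAnnotations(ann, f)
  back <- readAnnotations(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$class, "Tumornest")
  expect_equal(back[[1]]$coords, ann[[1]]$coords, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("categorization follows the dense-tumor precedence", {
  expect_equal(categorizePatch(0.12), "T>=10%")
  expect_equal(categorizePatch(0.001, 0.2), "T>=0.05%")   # tumor beats stroma
  expect_equal(categorizePatch(0, 0, 0), "T<0.05%")
  expect_equal(categorizePatch(0.10), "T>=10%")            # tie -> higher
  expect_equal(categorizePatch(5e-4), "T>=0.05%")
  expect_equal(categorizePatch(0, 5e-4, 1), "S>=0.05%")
  expect_equal(categorizePatch(0, 0, 5e-4), "N>=0.05%")
  # categories partition any inventory
  set.seed(52)
  cats <- categorizePatch(runif(500, 0, 0.2), runif(500, 0, 0.2),
                          runif(500, 0, 0.2))
  expect_equal(sum(table(factor(cats, levels = patchCategories()))), 500)
})

test_that("resampling plans conserve the category targets exactly", {
  inv <- data.frame(category = rep(patchCategories(),
                                   c(175771 %/% 1000, 9537 %/% 1000 + 1,
                                     5528 %/% 1000 + 1, 9096 %/% 1000 + 1,
                                     9458 %/% 1000 + 1)))
  # identity plan
  p0 <- buildResamplingPlan(inv)
  expect_true(all(p0$repetitions == 1))
  expect_equal(sum(p0$repetitions), nrow(inv))
  # round-robin: 3 patches, target 10 -> 4, 3, 3
  inv3 <- data.frame(category = rep("T>=0.05%", 3))
  p3 <- buildResamplingPlan(inv3, c("T>=0.05%" = 10))
  expect_equal(p3$repetitions, c(4L, 3L, 3L))
  # errors
  expect_error(buildResamplingPlan(inv3, c("T>=0.05%" = 2)), "below")
  expect_error(buildResamplingPlan(inv3, c("T>=10%" = 5)), "empty")
  # conservation for random targets
  set.seed(53)
  for (i in 1:10) {
    n <- sample(3:30, 4)
    inv <- data.frame(category = rep(patchCategories()[-1], n))
    targets <- setNames(n + sample(0:50, 4), patchCategories()[-1])
    pl <- buildResamplingPlan(inv, targets)
    expect_equal(sum(pl$repetitions), sum(targets))
    for (cat in names(targets))
      expect_lte(diff(range(pl$repetitions[pl$category == cat])), 1)
  }
})

test_that("the reference category targets reproduce the printed plan total", {
  # per-category counts of the full reference patch corpus
  inv <- data.frame(category = rep(patchCategories(),
                                   c(175771, 9537, 5528, 9096, 9458)))
  plan <- buildResamplingPlan(inv, c("T>=0.05%" = 30000, "T>=10%" = 10000,
                                     "S>=0.05%" = 20000, "N>=0.05%" = 20000))
  expect_equal(nrow(inv), 209390)
  expect_equal(sum(plan$repetitions), 255771)
})

test_that("pixel unbalance follows coverage arithmetic and resampling direction", {
  one <- data.frame(coverage_T = 0.5)
  expect_equal(pixelUnbalance(one), 1)
  two <- data.frame(coverage_T = c(0.1, 0))
  expect_equal(pixelUnbalance(two), 19)
  expect_error(pixelUnbalance(data.frame(coverage_T = c(0, 0))), "undefined")
  # oversampling the tumor-rich categories strictly decreases the ratio
  inv <- data.frame(coverage_T = c(0.2, 0.01, 0, 0, 0),
                    category = c("T>=10%", "T>=0.05%", "T<0.05%", "T<0.05%",
                                 "S>=0.05%"))
  before <- pixelUnbalance(inv)
  plan <- buildResamplingPlan(inv, c("T>=10%" = 4, "T>=0.05%" = 3))
  expect_lt(pixelUnbalance(plan), before)
})

test_that("inventories round-trip through CSV", {
  inv <- data.frame(patch_id = c("a", "b"), origin_x = c(0L, 64L),
                    origin_y = 0L, coverage_T = c(0.5, 0), coverage_S = 0,
                    coverage_N = 0, category = c("T>=10%", "T<0.05%"),
                    repetitions = c(2L, 1L))
  f <- tempfile(fileext = ".csv")
  writeInventory(inv, f)
  expect_equal(readInventory(f), inv, ignore_attr = TRUE)
})

test_that("augmentation keeps pairs consistent and targets one-hot", {
  set.seed(54)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tgt <- randomOneHot(32, 32, p = 0.3)
  # identity configuration returns the inputs unchanged
  idcfg <- augmentConfig(flip = FALSE, rotate90 = FALSE, maxRotation = 0,
                         scaleRange = c(1, 1), elasticProb = 0,
                         blurSigmaMax = 0, colorJitter = 0)
  a0 <- augmentPatch(img, tgt, idcfg)
  expect_identical(a0$image, img)
  expect_identical(a0$target, tgt)
  # full augmentation: shapes unchanged, target exactly one-hot
  for (i in 1:10) {
    a <- augmentPatch(img, tgt, augmentConfig())
    expect_equal(dim(a$image), dim(img))
    expect_true(all(a$target %in% c(0, 1)))
    expect_true(all(a$target[, , 1] + a$target[, , 2] == 1))
  }
})

test_that("a pure 90-degree rotation moves the mask exactly with the image", {
  set.seed(55)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tgt <- randomOneHot(16, 16, p = 0.4)
  cfg <- augmentConfig(flip = FALSE, rotate90 = TRUE, maxRotation = 0,
                       scaleRange = c(1, 1), elasticProb = 0, blurSigmaMax = 0,
                       colorJitter = 0)
  found <- FALSE
  for (i in 1:40) {
    a <- augmentPatch(img, tgt, cfg)
    # identify the quarter turn by matching the image, then check the mask
    for (q in 0:3) {
      rimg <- img[, , 1]
      rtgt <- tgt[, , 1]
      if (q > 0) for (r in 1:q) {
        rimg <- t(apply(rimg, 2, rev))
        rtgt <- t(apply(rtgt, 2, rev))
      }
      if (max(abs(a$image[, , 1] - rimg)) < 1e-9) {
        found <- TRUE
        expect_equal(a$target[, , 1], rtgt, ignore_attr = TRUE)
      }
    }
  }
  expect_true(found)
})

test_that("small elastic deformations roughly preserve tumor pixel count", {
  set.seed(56)
  tgt <- array(0, c(48, 48, 2))
  m <- matrix(FALSE, 48, 48); m[8:40, 8:40] <- TRUE
  tgt[, , 1] <- m; tgt[, , 2] <- !m
  img <- array(0.5, c(48, 48, 3))
  cfg <- augmentConfig(flip = FALSE, rotate90 = FALSE, maxRotation = 0,
                       scaleRange = c(1, 1), elasticProb = 1, elasticAlpha = 1,
                       elasticSigma = 10, blurSigmaMax = 0, colorJitter = 0)
  for (i in 1:10) {
    a <- augmentPatch(img, tgt, cfg)
    expect_lt(abs(sum(a$target[, , 1]) - sum(m)), 0.1 * sum(m))
  }
})
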