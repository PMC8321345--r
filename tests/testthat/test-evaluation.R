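test_that("IoU counts intersections over unions", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, !a), 0)
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(iou(m1, m2), 1 / 3)
  expect_equal(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(iou(a, matrix(TRUE, 3, 3)), "mismatch")
})

test_that("confusion counts and derived metrics reproduce the reference test table", {
  # 1119 Tumor / 843 Normal sections; 41 missed tumors, 30 false alarms
  truth <- rep(c("Tumor", "Normal"), c(1119, 843))
  pred <- truth
  pred[seq_len(41)] <- "Normal"
  pred[1119 + seq_len(30)] <- "Tumor"
  cc <- confusionCounts(pred, truth)
  expect_equal(cc, c(TP = 1078L, FP = 30L, TN = 813L, FN = 41L))
  expect_equal(sum(cc), 1962L)
  m <- metricsFromCounts(cc)
  expect_equal(round(m[["accuracy"]], 3), 0.964)
  expect_equal(round(m[["sensitivity"]], 3), 0.963)
  expect_equal(m[["accuracy"]], 1891 / 1962, tolerance = 1e-12)
  # the reference specificity value rounds from 813/843; we report the computed value
  expect_equal(m[["specificity"]], 813 / 843, tolerance = 1e-12)
  fb <- fBeta(m[["precision"]], m[["sensitivity"]], beta = 1.5)
  expect_equal(round(fb, 3), 0.966)
})

test_that("confusion counts handle toy lists and reject bad labels", {
  cc <- confusionCounts(c("Tumor", "Normal", "Tumor"),
                        c("Tumor", "Tumor", "Normal"))
  expect_equal(cc, c(TP = 1L, FP = 1L, TN = 0L, FN = 1L))
  expect_error(confusionCounts("Tumor", c("Tumor", "Normal")), "length")
  expect_error(confusionCounts("tumour", "Tumor"), "labels")
  perfect <- metricsFromCounts(c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_true(all(perfect == 1))
  expect_error(metricsFromCounts(c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)), "no sections")
  w <- capture_warnings(metricsFromCounts(c(TP = 0L, FP = 0L, TN = 3L, FN = 0L)))
  expect_true(all(grepl("undefined", w)) && length(w) == 2)
})

test_that("F-beta follows the printed formula and its identities", {
  expect_equal(fBeta(1, 1), 1)
  expect_equal(fBeta(0.3, 0), 0)
  for (p in c(0.2, 0.7, 1)) expect_equal(fBeta(p, p, beta = 2.7), p)
  expect_error(fBeta(0, 0), "undefined")
  # strictly increasing in both arguments
  expect_gt(fBeta(0.8, 0.5), fBeta(0.7, 0.5))
  expect_gt(fBeta(0.8, 0.6), fBeta(0.8, 0.5))
  # beta = 1.5 weights recall more than precision
  expect_gt(fBeta(0.5, 0.9), fBeta(0.9, 0.5))
})

test_that("metrics agree with brute-force tallies on random label vectors", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    truth <- sample(c("Tumor", "Normal"), n, replace = TRUE)
    pred <- sample(c("Tumor", "Normal"), n, replace = TRUE)
    cc <- confusionCounts(pred, truth)
    expect_equal(sum(cc), n)
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (j in seq_len(n)) {
      if (pred[j] == "Tumor" && truth[j] == "Tumor") tp <- tp + 1L
      else if (pred[j] == "Tumor") fp <- fp + 1L
      else if (truth[j] == "Normal") tn <- tn + 1L
      else fn <- fn + 1L
    }
    expect_identical(unname(cc), c(tp, fp, tn, fn))
    m <- suppressWarnings(metricsFromCounts(cc))
    expect_equal(m[["accuracy"]], (tp + tn) / n)
    # accuracy = (sens*P + spec*N) / (P + N) whenever both are defined
    P <- tp + fn; N <- tn + fp
    if (P > 0 && N > 0)
      expect_equal(m[["accuracy"]],
                   (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N),
                   tolerance = 1e-12)
    if (P > 0 && tp + fp > 0 && (m[["precision"]] > 0 || m[["sensitivity"]] > 0)) {
      b2 <- 2.25
      expect_equal(fBeta(m[["precision"]], m[["sensitivity"]]),
                   (1 + b2) * m[["precision"]] * m[["sensitivity"]] /
                     (b2 * m[["precision"]] + m[["sensitivity"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold grid search maximizes F-beta with documented tie-breaks", {
  # single grid point is returned unchanged
  hm1 <- heatmap2d(matrix(0.9, 8, 8), 1)
  hm0 <- heatmap2d(matrix(0.1, 8, 8), 1)
  sel1 <- gridSearchThresholds(list(hm1, hm0), c("Tumor", "Normal"),
                               selectionConfig(predictionGrid = 0.5,
                                               areaGrid = 10))
  expect_equal(sel1$predictionThreshold, 0.5)
  expect_equal(sel1$areaThresholdUm2, 10)
  expect_equal(sel1$fBeta, 1)
  expect_equal(nrow(sel1$table), 1)
  # constructed heatmaps separable only at exactly (0.6, 100 um2):
  #  tumor sections: 15x15 block at 0.65 (area 225)
  #  normal sections: 6x6 block at 0.95 (area 36, needs the area filter)
  #  plus a 20x20 halo at 0.5 (area 400) that fools lower thresholds
  mk <- function(tumor) {
    p <- matrix(0, 30, 30)
    if (tumor) {
      p[3:17, 3:17] <- 0.65
    } else {
      p[3:22, 3:22] <- 0.5
      p[24:29, 24:29] <- 0.95
    }
    heatmap2d(p, 1)
  }
  hms <- c(lapply(1:4, function(i) mk(TRUE)), lapply(1:4, function(i) mk(FALSE)))
  truth <- rep(c("Tumor", "Normal"), each = 4)
  sel <- gridSearchThresholds(hms, truth,
                              selectionConfig(predictionGrid = c(0.4, 0.6, 0.8),
                                              areaGrid = c(0, 100, 400)))
  expect_equal(sel$fBeta, 1)
  expect_equal(sel$predictionThreshold, 0.6)
  expect_equal(sel$areaThresholdUm2, 100)
  # grid-order invariance
  sel2 <- gridSearchThresholds(hms, truth,
                               selectionConfig(predictionGrid = c(0.8, 0.4, 0.6),
                                               areaGrid = c(400, 0, 100)))
  expect_equal(sel2[c("predictionThreshold", "areaThresholdUm2", "fBeta")],
               sel[c("predictionThreshold", "areaThresholdUm2", "fBeta")])
  # equal F-beta and sensitivity: the smaller prediction threshold wins
  flat <- list(heatmap2d(matrix(0.9, 6, 6), 1), heatmap2d(matrix(0, 6, 6), 1))
  selt <- gridSearchThresholds(flat, c("Tumor", "Normal"),
                               selectionConfig(predictionGrid = c(0.3, 0.5),
                                               areaGrid = c(0, 10)))
  expect_equal(selt$predictionThreshold, 0.3)
  expect_equal(selt$areaThresholdUm2, 0)
  expect_error(gridSearchThresholds(list(), character(0)), "no heatmaps")
})

test_that("per-block evaluation reuses one forward pass per tile", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 4,
                                   seed = 72))
  set.seed(73)
  sections <- lapply(1:3, function(i)
    list(image = array(runif(96 * 96 * 3, 0.4, 1), c(96, 96, 3)), mpp = 2,
         sectionId = paste0("s", i)))
  truth <- c("Tumor", "Normal", "Normal")
  tab <- perBlockEvaluation(net, sections, truth, 0.5, 500)
  expect_equal(nrow(tab), 4)          # exactly k rows
  expect_equal(tab$block, 0:3)
  # the last row equals the full-model evaluation exactly
  full <- vapply(sections, function(sec)
    sectionLabel(runInference(net, sec$image, sec$mpp, 0.5, 500)$result), "")
  cc <- confusionCounts(full, truth)
  expect_equal(tab$accuracy[4], (cc[["TP"]] + cc[["TN"]]) / 3)
})
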