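# Segmentation and sectionwise metrics, the two-dimensional threshold grid
# search, and the per-decoder-block evaluation protocol. Tumor is the
# positive class throughout.

#' Intersection over Union of two binary masks
#'
#' `|A & B| / |A | B|`, defined as 1 when both masks are empty.
#'
#' @param predMask,trueMask logical (or 0/1) arrays of equal shape.
#' @return a number in `[0, 1]`.
#' @export
iou <- function(predMask, trueMask) {
  predMask <- as.logical(predMask); trueMask <- as.logical(trueMask)
  if (length(predMask) != length(trueMask)) stop("mask shape mismatch")
  u <- sum(predMask | trueMask)
  if (u == 0) return(1)
  sum(predMask & trueMask) / u
}

#' Sectionwise confusion counts
#'
#' @param predicted,truth character vectors of `"Tumor"`/`"Normal"` labels,
#'   aligned by section.
#' @return named integer vector `c(TP, FP, TN, FN)` with Tumor positive.
#' @examples
#' confusionCounts(c("Tumor", "Normal"), c("Tumor", "Tumor"))
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  ok <- c("Tumor", "Normal")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'Tumor' or 'Normal'")
  c(TP = sum(predicted == "Tumor" & truth == "Tumor"),
    FP = sum(predicted == "Tumor" & truth == "Normal"),
    TN = sum(predicted == "Normal" & truth == "Normal"),
    FN = sum(predicted == "Normal" & truth == "Tumor"))
}

#' Accuracy, sensitivity, specificity and precision from counts
#'
#' `accuracy = (TP+TN)/total`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `precision = TP/(TP+FP)`. A zero denominator
#' yields `NA` with a warning rather than `NaN`; zero total is an error.
#'
#' @param counts named vector as from [confusionCounts()].
#' @return named numeric vector.
#' @export
metricsFromCounts <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  total <- sum(counts)
  if (total == 0) stop("no sections evaluated")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NA_real_) }
    num / den
  }
  c(accuracy = (counts[["TP"]] + counts[["TN"]]) / total,
    sensitivity = safe(counts[["TP"]], counts[["TP"]] + counts[["FN"]], "sensitivity"),
    specificity = safe(counts[["TN"]], counts[["TN"]] + counts[["FP"]], "specificity"),
    precision = safe(counts[["TP"]], counts[["TP"]] + counts[["FP"]], "precision"))
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) * precision * recall / (beta^2 * precision +
#' recall)`. The default `beta = 1.5` weights recall (sensitivity) above
#' precision, reflecting that a missed tumor section costs more than a
#' false alarm. Undefined when precision and recall are both zero.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param beta positive weight; `beta^2` is computed exactly (2.25 for the
#'   default).
#' @return a value in `[0, 1]`.
#' @export
fBeta <- function(precision, recall, beta = 1.5) {
  stopifnot(beta > 0)
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) stop("F-beta undefined: precision = recall = 0")
  b2 <- beta^2
  (1 + b2) * precision * recall / (b2 * precision + recall)
}

#' Selection configuration for the threshold grid search
#'
#' The default grids cover the plausible operating range: prediction
#' threshold 0.30 to 0.80 in steps of 0.05, and area thresholds at
#' multiples of 1280 um2 from 0 to 10240.
#'
#' @param beta F-beta weight (default 1.5).
#' @param predictionGrid,areaGrid numeric grids (nonempty).
#' @return a list with class `"wsisegSelectionConfig"`.
#' @export
selectionConfig <- function(beta = 1.5,
                            predictionGrid = seq(0.30, 0.80, by = 0.05),
                            areaGrid = seq(0, 10240, by = 1280)) {
  stopifnot(beta > 0, length(predictionGrid) > 0, length(areaGrid) > 0)
  structure(list(beta = beta, predictionGrid = predictionGrid,
                 areaGrid = areaGrid), class = "wsisegSelectionConfig")
}

#' Grid search for the prediction and area thresholds
#'
#' Evaluates the sectionwise classification over the full two-dimensional
#' grid against the true labels and returns the pair maximizing the F-beta
#' score. Heatmaps are computed once by the caller; only cheap thresholding
#' is repeated. Ties are broken by higher sensitivity, then lower
#' prediction threshold, then lower area threshold. Sections where every
#' region is filtered out under a grid point count as Normal there.
#'
#' @param heatmaps list of [Heatmap-class] objects.
#' @param truth character vector of true labels aligned with `heatmaps`.
#' @param config a [selectionConfig()].
#' @return list with `predictionThreshold`, `areaThresholdUm2`, `fBeta`,
#'   and `table` (the full score table: one row per grid point with
#'   confusion counts and metrics).
#' @export
gridSearchThresholds <- function(heatmaps, truth, config = selectionConfig()) {
  stopifnot(length(heatmaps) == length(truth))
  if (length(heatmaps) == 0) stop("no heatmaps supplied")
  grid <- expand.grid(predictionThreshold = sort(config$predictionGrid),
                      areaThresholdUm2 = sort(config$areaGrid))
  # per section and prediction threshold: areas of all regions, largest first
  rows <- vector("list", nrow(grid))
  pts <- sort(unique(grid$predictionThreshold))
  areasByPt <- lapply(pts, function(pt)
    lapply(heatmaps, function(h) extractRegions(h, pt)$area_um2))
  names(areasByPt) <- as.character(pts)
  for (g in seq_len(nrow(grid))) {
    pt <- grid$predictionThreshold[g]
    at <- grid$areaThresholdUm2[g]
    areas <- areasByPt[[as.character(pt)]]
    pred <- ifelse(vapply(areas, function(a) any(a >= at), logical(1)),
                   "Tumor", "Normal")
    cc <- confusionCounts(pred, truth)
    m <- suppressWarnings(metricsFromCounts(cc))
    fb <- if (!is.na(m[["precision"]]) && (m[["precision"]] > 0 || m[["sensitivity"]] > 0))
      fBeta(m[["precision"]], m[["sensitivity"]], config$beta) else NA_real_
    rows[[g]] <- data.frame(predictionThreshold = pt, areaThresholdUm2 = at,
                            TP = cc[["TP"]], FP = cc[["FP"]],
                            TN = cc[["TN"]], FN = cc[["FN"]],
                            accuracy = m[["accuracy"]],
                            sensitivity = m[["sensitivity"]],
                            specificity = m[["specificity"]], fBeta = fb)
  }
  tab <- do.call(rbind, rows)
  cand <- tab[!is.na(tab$fBeta), , drop = FALSE]
  if (nrow(cand) == 0) stop("F-beta undefined on the whole grid")
  ord <- order(-cand$fBeta, -cand$sensitivity, cand$predictionThreshold,
               cand$areaThresholdUm2)
  best <- cand[ord[1], ]
  list(predictionThreshold = best$predictionThreshold,
       areaThresholdUm2 = best$areaThresholdUm2,
       fBeta = best$fBeta, table = tab)
}

#' Evaluate the sectionwise task with every decoder block
#'
#' Generates each section's heatmap from the output of each decoder block
#' `l = 0..k-1` (one shared forward pass per tile; the block maps are read
#' off the per-block score heads) and classifies all sections with the
#' *same* prediction and area thresholds. For deep-supervision-trained
#' networks the early blocks are expected to perform almost as well as the
#' full decoder; for other networks the intermediate outputs carry no
#' supervised meaning and a warning is issued by the caller's choice of
#' network, not detectable here.
#'
#' @param network a trained [SegNet-class] (deep supervision intended).
#' @param sections list of `list(image, mpp, sectionId)` entries (see
#'   [readSection()]).
#' @param truth character vector of true labels aligned with `sections`.
#' @param predictionThreshold,areaThresholdUm2 thresholds selected for the
#'   full model.
#' @param batchSize tiles per forward batch.
#' @return data.frame with one row per block: `block`, confusion counts,
#'   `accuracy`, `sensitivity`, `specificity`, `fBeta`.
#' @export
perBlockEvaluation <- function(network, sections, truth, predictionThreshold,
                               areaThresholdUm2, batchSize = 16L) {
  k <- network@config@nBlocks
  sz <- network@config@inputSize
  blocks <- 0:(k - 1L)
  preds <- matrix("", nrow = length(sections), ncol = k)
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    sectionSize <- c(dim(sec$image)[2], dim(sec$image)[1])
    origins <- planTiles(sectionSize, sz, sz %/% 2L)
    tiles <- lapply(seq_len(nrow(origins)), function(i)
      extractTile(sec$image, origins$x0[i], origins$y0[i], sz))
    maps <- tileBlockMaps(network, tiles, blocks, batchSize)
    for (b in blocks) {
      hm <- stitchHeatmap(maps[[as.character(b)]], origins, sectionSize,
                          sec$mpp, sec$sectionId)
      res <- classifySection(extractRegions(hm, predictionThreshold),
                             areaThresholdUm2, sec$sectionId)
      preds[si, b + 1L] <- sectionLabel(res)
    }
  }
  do.call(rbind, lapply(blocks, function(b) {
    cc <- confusionCounts(preds[, b + 1L], truth)
    m <- suppressWarnings(metricsFromCounts(cc))
    fb <- if (!is.na(m[["precision"]]))
      fBeta(m[["precision"]], m[["sensitivity"]]) else NA_real_
    data.frame(block = b, TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
               FN = cc[["FN"]], accuracy = m[["accuracy"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], fBeta = fb)
  }))
}
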