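# End-to-end synthetic study: generate fixtures, build the balanced patch
# stream, train a small deep-supervision U-Net, select thresholds by F-beta
# grid search on the validation partitions, and evaluate every decoder
# block on the held-out test split.

#' Load the sections of one dataset split
#'
#' @param dataDir dataset root written by [generateDataset()].
#' @param split split name (`"train"`, `"val1"`, `"val2"`, `"test"`).
#' @return list with `sections` (list of `list(image, mpp, sectionId)`),
#'   `labels` (named character vector by section id), and `annotations`
#'   (named list, detailed splits only).
#' @export
loadSplit <- function(dataDir, split) {
  secDir <- file.path(dataDir, split, "sections")
  files <- sort(list.files(secDir, pattern = "\\.png$", full.names = TRUE))
  sections <- lapply(files, readSection)
  lab <- read.csv(file.path(dataDir, split, "labels.csv"),
                  stringsAsFactors = FALSE)
  labels <- setNames(lab$label, lab$section_id)
  annDir <- file.path(dataDir, split, "annotations")
  annotations <- NULL
  if (dir.exists(annDir)) {
    af <- sort(list.files(annDir, pattern = "\\.geojson$", full.names = TRUE))
    annotations <- lapply(af, readAnnotations)
    names(annotations) <- sub("\\.geojson$", "", basename(af))
  }
  list(sections = sections, labels = labels, annotations = annotations)
}

# rasterized tumor mask (rows = y) for a section from its annotations
tumorMask <- function(annotations, width, height) {
  polys <- lapply(Filter(function(a) a$class == "Tumornest", annotations),
                  `[[`, "coords")
  if (length(polys) == 0) return(matrix(FALSE, height, width))
  cpp_rasterize_polygons(polys, as.integer(height), as.integer(width))
}

# cut (image, target) patches for every row of an inventory
cutPatches <- function(image, mask, inventory, patchSize) {
  lapply(seq_len(nrow(inventory)), function(i) {
    x0 <- inventory$origin_x[i]; y0 <- inventory$origin_y[i]
    img <- image[y0 + seq_len(patchSize), x0 + seq_len(patchSize), , drop = FALSE]
    m <- mask[y0 + seq_len(patchSize), x0 + seq_len(patchSize)]
    target <- array(0, c(patchSize, patchSize, 2L))
    target[, , 1] <- m
    target[, , 2] <- 1 - m
    list(image = img, target = target)
  })
}

# Per-category oversampling targets mirroring the reference resampling
# ratios (about 3.1x for tumor-containing, 1.8x extra for dense-tumor,
# 2.2x for stroma, 2.1x for distractor patches; background untouched).
referenceResamplingTargets <- function(inventory) {
  mult <- c("T>=0.05%" = 30000 / 9537, "T>=10%" = 10000 / 5528,
            "S>=0.05%" = 20000 / 9096, "N>=0.05%" = 20000 / 9458)
  counts <- table(inventory$category)
  targets <- integer(0)
  for (cat in names(mult)) {
    if (cat %in% names(counts) && counts[[cat]] > 0)
      targets[cat] <- as.integer(ceiling(counts[[cat]] * mult[[cat]]))
  }
  targets
}

#' Build the balanced training patch set of a detailed split
#'
#' Tiles every annotated section on a non-overlapping grid, computes
#' annotation coverage and categories, applies the reference oversampling
#' ratios via [buildResamplingPlan()], and cuts the (image, target) pairs.
#'
#' @param splitData result of [loadSplit()] for a detailed split.
#' @param patchSize patch side length in pixels.
#' @param resample apply the oversampling plan (`FALSE` for validation).
#' @return list with `patches`, `repetitions`, `inventory` (plan included
#'   when resampled).
#' @export
preparePatches <- function(splitData, patchSize, resample = TRUE) {
  allPatches <- list()
  invs <- list()
  for (i in seq_along(splitData$sections)) {
    sec <- splitData$sections[[i]]
    ann <- splitData$annotations[[sec$sectionId]]
    W <- dim(sec$image)[2]; H <- dim(sec$image)[1]
    inv <- buildPatchInventory(c(W, H), patchSize, ann, sectionId = sec$sectionId)
    mask <- tumorMask(ann, W, H)
    allPatches <- c(allPatches, cutPatches(sec$image, mask, inv, patchSize))
    invs[[i]] <- inv
  }
  inventory <- do.call(rbind, invs)
  if (resample) {
    plan <- buildResamplingPlan(inventory, referenceResamplingTargets(inventory))
    list(patches = allPatches, repetitions = plan$repetitions, inventory = plan)
  } else {
    list(patches = allPatches, repetitions = rep(1L, nrow(inventory)),
         inventory = inventory)
  }
}

# stitched final-block heatmaps for a list of sections
sectionHeatmaps <- function(network, sections, batchSize = 16L) {
  k <- network@config@nBlocks
  lapply(sections, function(sec) {
    sz <- network@config@inputSize
    sectionSize <- c(dim(sec$image)[2], dim(sec$image)[1])
    origins <- planTiles(sectionSize, sz, sz %/% 2L)
    tiles <- lapply(seq_len(nrow(origins)), function(i)
      extractTile(sec$image, origins$x0[i], origins$y0[i], sz))
    maps <- tileBlockMaps(network, tiles, k - 1L, batchSize)[[1]]
    stitchHeatmap(maps, origins, sectionSize, sec$mpp, sec$sectionId)
  })
}

#' Run the complete synthetic study
#'
#' Generates the synthetic dataset, trains a small vanilla-encoder U-Net
#' (64 px patches, k = 4 decoder blocks, base width 8) with Focal-Loss and
#' deep supervision on the balanced, augmented patch stream, selects the
#' prediction and area thresholds by F-beta grid search over the combined
#' validation partitions, evaluates the selected model on the test split,
#' and repeats the test evaluation with every truncated decoder prefix.
#'
#' @param seed master seed for the whole study (dataset, initialization,
#'   training order, augmentation).
#' @param dataDir where to generate the dataset (default: a temporary
#'   directory, removed afterwards).
#' @param params fixture parameters; defaults are the reference synthetic
#'   conditions of [fixtureParams()].
#' @param epochs training epochs.
#' @param patchSize,nBlocks,baseWidth network scale.
#' @param verbose print progress.
#' @return list with `history`, `thresholds` (grid-search result), `test`
#'   (named metrics of the full model on the test split), `perBlock`
#'   (data.frame from [perBlockEvaluation()]), `valIoU` (best validation
#'   IoU) and `network`.
#' @export
runFixtureStudy <- function(seed = 1L, dataDir = NULL, params = NULL,
                            epochs = 14L, patchSize = 64L, nBlocks = 4L,
                            baseWidth = 8L, verbose = FALSE) {
  cleanup <- FALSE
  if (is.null(dataDir)) {
    dataDir <- tempfile("wsiseg_study_")
    cleanup <- TRUE
    on.exit(unlink(dataDir, recursive = TRUE), add = TRUE)
  }
  if (is.null(params)) params <- fixtureParams(seed = seed)
  if (!file.exists(file.path(dataDir, "manifest.json")))
    generateDataset(params, dataDir)
  train <- loadSplit(dataDir, "train")
  val1 <- loadSplit(dataDir, "val1")
  val2 <- loadSplit(dataDir, "val2")
  test <- loadSplit(dataDir, "test")

  if (verbose) message("preparing patches ...")
  trainSet <- preparePatches(train, patchSize, resample = TRUE)
  valSet <- preparePatches(val1, patchSize, resample = FALSE)

  cfg <- segNetConfig(encoder = "vanilla", inputSize = patchSize,
                      nBlocks = nBlocks, baseWidth = baseWidth,
                      seed = seed + 11L)
  net <- buildNetwork(cfg)
  if (verbose) message("training ...")
  fit <- trainNetwork(net, trainSet$patches, valSet$patches,
                      config = trainConfig(maxEpochs = epochs, batchSize = 8L,
                                           seed = seed + 12L),
                      loss = lossConfig(gamma = 2, strategy = "deep_supervision"),
                      repetitions = trainSet$repetitions,
                      augment = augmentConfig(), verbose = verbose)
  net <- fit$network

  if (verbose) message("selecting thresholds ...")
  valSections <- c(val1$sections, val2$sections)
  valTruth <- c(unname(val1$labels[vapply(val1$sections, `[[`, "", "sectionId")]),
                unname(val2$labels[vapply(val2$sections, `[[`, "", "sectionId")]))
  hms <- sectionHeatmaps(net, valSections)
  sel <- gridSearchThresholds(hms, valTruth)

  if (verbose) message("evaluating test split per decoder block ...")
  testTruth <- unname(test$labels[vapply(test$sections, `[[`, "", "sectionId")])
  perBlock <- perBlockEvaluation(net, test$sections, testTruth,
                                 sel$predictionThreshold, sel$areaThresholdUm2)
  full <- perBlock[perBlock$block == nBlocks - 1L, ]
  testMetrics <- c(accuracy = full$accuracy, sensitivity = full$sensitivity,
                   specificity = full$specificity, fBeta = full$fBeta)
  list(history = fit$history,
       thresholds = sel[c("predictionThreshold", "areaThresholdUm2", "fBeta")],
       test = testMetrics, perBlock = perBlock,
       valIoU = max(fit$history$valIoU), network = net)
}
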