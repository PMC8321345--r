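# Section-level inference: tissue detection, overlapping tile planning,
# heatmap stitching, connected-region extraction with physical areas, and
# the sectionwise Tumor/Normal decision. Coordinates are 0-based and
# half-open everywhere; x indexes matrix columns, y indexes rows.

#' Detect tissue sections on a slide image
#'
#' Separates tissue from the bright scanner background by intensity and
#' saturation thresholding, groups tissue pixels into 8-connected
#' components, merges components into axis-aligned bounding boxes and
#' returns them sorted top-left to bottom-right (row-major by origin).
#' Boxes are half-open and clipped to the image bounds.
#'
#' @param image `(H, W, 3)` RGB array in `[0, 1]` with bright background.
#' @param intensityMax pixels darker than this count as tissue.
#' @param saturationMin pixels with channel spread above this count as tissue.
#' @param minPixels components smaller than this are ignored (dust).
#' @return data.frame with columns `x0`, `y0`, `width`, `height`; zero rows
#'   for a blank image.
#' @export
detectSections <- function(image, intensityMax = 0.85, saturationMin = 0.12,
                           minPixels = 64L) {
  intensity <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  saturation <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  tissue <- intensity < intensityMax | saturation > saturationMin
  labels <- cpp_label_components(tissue, 8L)
  n <- max(labels)
  out <- data.frame(x0 = integer(), y0 = integer(),
                    width = integer(), height = integer())
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    px <- which(labels == i, arr.ind = TRUE)
    if (nrow(px) < minPixels) next
    y0 <- min(px[, 1]) - 1L; y1 <- max(px[, 1])       # half-open
    x0 <- min(px[, 2]) - 1L; x1 <- max(px[, 2])
    out <- rbind(out, data.frame(x0 = x0, y0 = y0,
                                 width = x1 - x0, height = y1 - y0))
  }
  out[order(out$y0, out$x0), , drop = FALSE]
}

#' Plan overlapping tiles covering a section
#'
#' Per axis of length `L`: `n = ceil((L - patchSize) / (patchSize -
#' minOverlap)) + 1` origins, evenly spaced integers from `0` to
#' `L - patchSize`. Adjacent tiles then overlap by at least `minOverlap`
#' pixels and the union of tiles covers every pixel. Sections smaller than
#' the patch yield a single (padded) tile at origin 0.
#'
#' @param sectionSize length-2 integer `(width, height)` in pixels.
#' @param patchSize tile side length (default 512).
#' @param minOverlap minimum overlap of adjacent tiles (default 256, i.e.
#'   50 percent).
#' @return data.frame of tile origins `x0`, `y0` (0-based, half-open tiles)
#'   with the patch size in `attr(, "patchSize")`.
#' @examples
#' planTiles(c(1024, 1024))[, "x0"]  # origins 0, 256, 512 per axis
#' @export
planTiles <- function(sectionSize, patchSize = 512L, minOverlap = patchSize %/% 2L) {
  stopifnot(length(sectionSize) == 2, patchSize > minOverlap)
  if (any(sectionSize <= 0)) stop("non-positive section size")
  axisOrigins <- function(L) {
    if (L <= patchSize) return(0L)
    n <- ceiling((L - patchSize) / (patchSize - minOverlap)) + 1L
    as.integer(round(seq(0L, L - patchSize, length.out = n)))
  }
  grid <- expand.grid(x0 = axisOrigins(sectionSize[1]),
                      y0 = axisOrigins(sectionSize[2]))
  attr(grid, "patchSize") <- as.integer(patchSize)
  grid
}

#' Stitch per-tile probability maps into a section heatmap
#'
#' Overlapping predictions are combined by the per-pixel arithmetic mean of
#' all covering tiles (sum and count accumulated, then divided), which is
#' invariant to tile processing order and smooths tile-border artifacts.
#' Tile parts outside the section (padding) are discarded; pixels covered by
#' no tile (e.g. skipped background tiles) default to probability 0.
#'
#' @param tileMaps list of `patchSize x patchSize` matrices of tumor
#'   probabilities (rows = y).
#' @param origins data.frame of tile origins as from [planTiles()].
#' @param sectionSize `(width, height)` of the section in pixels.
#' @param mpp micrometres per pixel, copied into the heatmap.
#' @param sectionId identifier for the result.
#' @return a [Heatmap-class].
#' @export
stitchHeatmap <- function(tileMaps, origins, sectionSize, mpp,
                          sectionId = "section") {
  stopifnot(length(tileMaps) == nrow(origins))
  W <- sectionSize[1]; H <- sectionSize[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(tileMaps)) {
    tm <- tileMaps[[i]]
    x0 <- origins$x0[i]; y0 <- origins$y0[i]
    if (x0 < 0 || y0 < 0 || x0 >= W || y0 >= H) stop("tile origin outside section")
    ys <- seq_len(min(nrow(tm), H - y0))
    xs <- seq_len(min(ncol(tm), W - x0))
    acc[y0 + ys, x0 + xs] <- acc[y0 + ys, x0 + xs] + tm[ys, xs]
    cnt[y0 + ys, x0 + xs] <- cnt[y0 + ys, x0 + xs] + 1
  }
  prob <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  heatmap2d(prob, mpp, sectionId)
}

#' Extract thresholded connected tumor regions from a heatmap
#'
#' Binarizes the heatmap at `probability >= threshold`, labels connected
#' components (8-connectivity by default, so thin diagonal strands stay
#' whole), and reports each component's pixel count, physical area
#' (`pixels * mpp^2`, in square micrometres) and peak probability.
#'
#' @param heatmap a [Heatmap-class].
#' @param predictionThreshold threshold in `[0, 1]`.
#' @param connectivity 4 or 8.
#' @return data.frame (`region_id`, `n_pixels`, `area_um2`, `peak_prob`)
#'   with the label matrix in `attr(, "labels")`.
#' @export
extractRegions <- function(heatmap, predictionThreshold, connectivity = 8L) {
  stopifnot(predictionThreshold >= 0, predictionThreshold <= 1,
            connectivity %in% c(4L, 8L))
  mask <- probMatrix(heatmap) >= predictionThreshold
  labels <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(labels)
  if (n == 0) {
    out <- data.frame(region_id = integer(), n_pixels = integer(),
                      area_um2 = numeric(), peak_prob = numeric())
  } else {
    npix <- tabulate(labels[labels > 0], nbins = n)
    peak <- vapply(seq_len(n), function(i) max(probMatrix(heatmap)[labels == i]),
                   numeric(1))
    out <- data.frame(region_id = seq_len(n), n_pixels = npix,
                      area_um2 = npix * mpp(heatmap)^2, peak_prob = peak)
  }
  attr(out, "labels") <- labels
  out
}

#' Sectionwise Tumor/Normal call from extracted regions
#'
#' Keeps regions with `area_um2 >= areaThresholdUm2` (the filter that
#' absorbs small false detections such as hair follicles) and labels the
#' section `Tumor` iff any region survives.
#'
#' @param regions data.frame from [extractRegions()].
#' @param areaThresholdUm2 area threshold in square micrometres, `>= 0`.
#' @param sectionId identifier for the result.
#' @return a [SectionResult-class].
#' @export
classifySection <- function(regions, areaThresholdUm2, sectionId = "section") {
  if (areaThresholdUm2 < 0) stop("negative area threshold")
  kept <- regions[regions$area_um2 >= areaThresholdUm2, , drop = FALSE]
  attr(kept, "labels") <- NULL
  new("SectionResult", sectionId = as.character(sectionId),
      label = if (nrow(kept) > 0) "Tumor" else "Normal", regions = kept)
}

# Extract a (possibly padded) tile image; padding is white (1.0).
extractTile <- function(image, x0, y0, patchSize) {
  H <- dim(image)[1]; W <- dim(image)[2]
  tile <- array(1, c(patchSize, patchSize, dim(image)[3]))
  ys <- seq_len(min(patchSize, H - y0))
  xs <- seq_len(min(patchSize, W - x0))
  tile[ys, xs, ] <- image[y0 + ys, x0 + xs, , drop = FALSE]
  tile
}

# Forward a set of tiles and return per-block tumor-probability matrices
# (upsampled to patch size). blocks: integer vector of 0-based block
# indices to collect (k-1 alone = standard final output path).
tileBlockMaps <- function(network, tiles, blocks, batchSize = 16L) {
  k <- network@config@nBlocks
  sz <- network@config@inputSize
  nt <- length(tiles)
  maps <- lapply(blocks, function(b) vector("list", nt))
  names(maps) <- as.character(blocks)
  i <- 1L
  maxBlock <- max(blocks)
  while (i <= nt) {
    take <- i:min(i + batchSize - 1L, nt)
    x <- stackPatches(tiles[take])
    fw <- segnetForward(network, x, training = FALSE,
                        uptoBlock = maxBlock + 1L, withMerge = FALSE)
    useMerge <- network@config@useLinearMerge && maxBlock == k - 1L &&
      !is.null(network@params[["merge.w"]])
    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      if (useMerge && b == k - 1L) {
        sm <- lapply(fw$scoreIds, function(id) fw$tp$vals[[id]])
        prob <- mergeLinear(sm, network@params[["merge.w"]], outputSize = sz)
      } else {
        prob <- softmaxChannels(fw$tp$vals[[fw$scoreIds[b + 1L]]])
        if (dim(prob)[1] != sz) prob <- cpp_resize_bilinear_fw(prob, sz, sz)
      }
      for (j in seq_along(take))
        maps[[bi]][[take[j]]] <- matrix(prob[, , 1, j], sz, sz)
    }
    i <- i + batchSize
  }
  maps
}

#' Run inference on one section image
#'
#' Composes the pipeline: tile planning with at least 50 percent overlap,
#' network forward passes, mean-stitching of the tumor-probability maps,
#' thresholded region extraction and the sectionwise call. With `blockIndex
#' < k-1` the decoder is truncated after that block (fast inference; only
#' meaningful for deep-supervision-trained networks).
#'
#' @param network a trained [SegNet-class].
#' @param image `(H, W, 3)` section image in `[0, 1]`.
#' @param mpp micrometres per pixel; required (physical areas depend on it).
#' @param predictionThreshold,areaThresholdUm2 the selected thresholds.
#' @param blockIndex 0-based decoder block used for the heatmap (default
#'   `k-1`, the full decoder).
#' @param minOverlap minimum tile overlap in pixels (default half the patch).
#' @param sectionId identifier.
#' @param batchSize tiles per forward batch.
#' @return list with `result` (a [SectionResult-class]) and `heatmap`
#'   (a [Heatmap-class]).
#' @export
runInference <- function(network, image, mpp, predictionThreshold,
                         areaThresholdUm2, blockIndex = NULL,
                         minOverlap = NULL, sectionId = "section",
                         batchSize = 16L) {
  if (missing(mpp) || is.null(mpp) || !is.finite(mpp) || mpp <= 0)
    stop("mpp metadata is required to compute region areas in um2")
  sz <- network@config@inputSize
  k <- network@config@nBlocks
  if (is.null(blockIndex)) blockIndex <- k - 1L
  if (is.null(minOverlap)) minOverlap <- sz %/% 2L
  sectionSize <- c(dim(image)[2], dim(image)[1])
  origins <- planTiles(sectionSize, sz, minOverlap)
  tiles <- lapply(seq_len(nrow(origins)), function(i)
    extractTile(image, origins$x0[i], origins$y0[i], sz))
  maps <- tileBlockMaps(network, tiles, blockIndex, batchSize)[[1]]
  hm <- stitchHeatmap(maps, origins, sectionSize, mpp, sectionId)
  regions <- extractRegions(hm, predictionThreshold)
  list(result = classifySection(regions, areaThresholdUm2, sectionId),
       heatmap = hm)
}

#' Run inference on a multi-section slide image
#'
#' Detects tissue sections with [detectSections()] and runs [runInference()]
#' on each bounding box.
#'
#' @inheritParams runInference
#' @param mpp micrometres per pixel of the slide image at the working
#'   magnification (0.92 by default).
#' @return list of per-section `list(result, heatmap, box)`.
#' @export
runSlide <- function(network, image, mpp = 0.92, predictionThreshold,
                     areaThresholdUm2, blockIndex = NULL, batchSize = 16L) {
  boxes <- detectSections(image)
  out <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    crop <- image[b$y0 + seq_len(b$height), b$x0 + seq_len(b$width), , drop = FALSE]
    r <- runInference(network, crop, mpp, predictionThreshold, areaThresholdUm2,
                      blockIndex = blockIndex, sectionId = sprintf("section_%d", i),
                      batchSize = batchSize)
    out[[i]] <- c(r, list(box = b))
  }
  out
}

#' Section image and heatmap input/output
#'
#' Sections are stored as plain PNG with a JSON sidecar (`<path>.json`)
#' holding `mpp` and `section_id`; heatmaps as single-channel 8-bit PNG
#' (probability times 255) with the same sidecar convention plus any
#' thresholds supplied.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mpp micrometres per pixel.
#' @param path PNG file path.
#' @param sectionId identifier stored in the sidecar.
#' @return readers return `list(image | prob, mpp, sectionId, ...)`;
#'   writers return `path` invisibly.
#' @export
writeSection <- function(image, mpp, path, sectionId = "section") {
  png::writePNG(image, path)
  jsonlite::write_json(list(mpp = mpp, section_id = sectionId),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSection
#' @export
readSection <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$mpp)) stop("missing mpp metadata for ", path)
  list(image = img, mpp = meta$mpp, sectionId = meta$section_id)
}

#' @rdname writeSection
#' @param heatmap a [Heatmap-class].
#' @param thresholds optional named list recorded in the sidecar.
#' @export
writeHeatmap <- function(heatmap, path, thresholds = NULL) {
  png::writePNG(probMatrix(heatmap), path)
  meta <- list(mpp = mpp(heatmap), section_id = sectionId(heatmap))
  if (!is.null(thresholds)) meta <- c(meta, thresholds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSection
#' @export
readHeatmap <- function(path) {
  prob <- png::readPNG(path)
  if (length(dim(prob)) == 3) prob <- prob[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  heatmap2d(prob, meta$mpp, meta$section_id)
}

#' Write sectionwise results as CSV
#'
#' Columns: `section_id`, `label`, `n_regions`, `largest_area_um2`.
#'
#' @param results list of [SectionResult-class] objects.
#' @param path CSV path.
#' @export
writeSectionResults <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    section_id = sectionId(r), label = sectionLabel(r),
    n_regions = nrow(tumorRegions(r)),
    largest_area_um2 = if (nrow(tumorRegions(r))) max(tumorRegions(r)$area_um2) else 0
  )))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
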