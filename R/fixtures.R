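# Synthetic histology-like fixtures: sections with tumor nests, stroma
# halos and follicle-like distractors, pixel-accurate polygon annotations,
# and sectionwise labels. The textures make no attempt at visual realism;
# the classes are separable by color/texture so CPU-scale networks can
# learn them quickly, while distractors share part of the nest appearance
# so the area-threshold filtering stage is genuinely exercised.

#' Fixture generation parameters
#'
#' Defaults define the reference synthetic study conditions at CPU scale:
#' 256-384 px sections at 2 um/px, half the sections tumorous with 1-3
#' nests of mean area 30,000 um2 (minimum 15,000), stroma halos of 30 um,
#' and 0-3 small (500-3,000 um2) distractors per section. Distractor areas
#' sit well below nest areas, so a correctly chosen area threshold
#' separates follicle-like false detections from true nests.
#'
#' @param nSections named integer vector: sections per split. Detailed
#'   polygon annotations are written for `train` and `val1` only; `val2`
#'   and `test` carry sectionwise labels only.
#' @param sectionSizeRange min/max section side length, pixels.
#' @param mpp micrometres per pixel.
#' @param prevalence fraction of sections labelled Tumor (exact up to
#'   rounding, balanced assignment).
#' @param nestCountRange min/max nests per tumor section.
#' @param nestAreaMeanUm2,nestAreaSdUm2,nestAreaMinUm2 truncated-normal
#'   nest area distribution, um2.
#' @param stromaHaloUm stroma halo width around each nest, um.
#' @param distractorCountRange min/max distractors per section.
#' @param distractorAreaRangeUm2 distractor area range, um2.
#' @param textureScale correlation length of the background texture, px.
#' @param stainVariation per-section stain color jitter (sd).
#' @param seed master seed; per-split seeds are derived from it.
#' @return a list with class `"wsisegFixtureParams"`.
#' @export
fixtureParams <- function(nSections = c(train = 16L, val1 = 8L, val2 = 24L, test = 64L),
                          sectionSizeRange = c(256L, 384L), mpp = 2.0,
                          prevalence = 0.5, nestCountRange = c(1L, 3L),
                          nestAreaMeanUm2 = 30000, nestAreaSdUm2 = 10000,
                          nestAreaMinUm2 = 15000, stromaHaloUm = 30,
                          distractorCountRange = c(0L, 3L),
                          distractorAreaRangeUm2 = c(500, 3000),
                          textureScale = 8, stainVariation = 0.04,
                          seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1, all(sectionSizeRange > 0),
            mpp > 0, nestAreaMinUm2 > 0)
  structure(list(nSections = nSections, sectionSizeRange = sectionSizeRange,
                 mpp = mpp, prevalence = prevalence,
                 nestCountRange = nestCountRange,
                 nestAreaMeanUm2 = nestAreaMeanUm2,
                 nestAreaSdUm2 = nestAreaSdUm2,
                 nestAreaMinUm2 = nestAreaMinUm2,
                 stromaHaloUm = stromaHaloUm,
                 distractorCountRange = distractorCountRange,
                 distractorAreaRangeUm2 = distractorAreaRangeUm2,
                 textureScale = textureScale,
                 stainVariation = stainVariation,
                 seed = as.integer(seed)),
            class = "wsisegFixtureParams")
}

# signed shoelace area of an n x 2 polygon
polygonArea <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# irregular star-convex blob with exact target area (pixel^2)
blobPolygon <- function(cx, cy, targetAreaPx, irregularity = 0.25,
                        nVertices = 40L) {
  ang <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  wob <- rep(0, nVertices)
  for (m in 1:3)
    wob <- wob + rnorm(1, 0, 1 / m) * cos(m * ang) + rnorm(1, 0, 1 / m) * sin(m * ang)
  r0 <- sqrt(targetAreaPx / pi)
  r <- pmax(r0 * (1 + irregularity * wob / 2), 0.25 * r0)
  coords <- cbind(cx + r * cos(ang), cy + r * sin(ang))
  s <- sqrt(targetAreaPx / polygonArea(coords))
  cbind(cx + s * (coords[, 1] - cx), cy + s * (coords[, 2] - cy))
}

# scale a polygon outward from its centroid by a fixed margin (pixels)
dilatePolygon <- function(coords, marginPx) {
  cx <- mean(coords[, 1]); cy <- mean(coords[, 2])
  dx <- coords[, 1] - cx; dy <- coords[, 2] - cy
  r <- sqrt(dx^2 + dy^2)
  f <- (r + marginPx) / pmax(r, 1e-9)
  cbind(cx + dx * f, cy + dy * f)
}

rasterPoly <- function(coords, W, H) {
  cpp_rasterize_polygons(list(coords), as.integer(H), as.integer(W))
}

#' Generate one synthetic section
#'
#' Renders a tissue blob on a bright background; tumor nests as
#' distinct-texture blobs with stroma halos; follicle-like distractors
#' (dark rim, bright core) in tumor-free areas, annotated `Normal`. Uses
#' the current RNG stream. The sectionwise label is `Tumor` iff at least
#' one nest was placed.
#'
#' @param params a [fixtureParams()].
#' @param tumor logical; force the label (default: drawn with probability
#'   `params$prevalence`).
#' @param sectionId identifier.
#' @return list with `image` (H, W, 3), `annotations` (list of
#'   `list(class, coords)`), `label`, `mpp`, `sectionId`.
#' @export
generateSection <- function(params = fixtureParams(), tumor = NULL,
                            sectionId = "section") {
  sampleRange <- function(r) if (r[1] >= r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
  W <- sampleRange(params$sectionSizeRange)
  H <- sampleRange(params$sectionSizeRange)
  if (is.null(tumor)) tumor <- runif(1) < params$prevalence
  mpp2 <- params$mpp^2
  cx <- W / 2; cy <- H / 2
  tissueArea <- 0.55 * W * H
  tissuePoly <- blobPolygon(cx, cy, tissueArea, irregularity = 0.2)
  tissueR <- sqrt(tissueArea / pi)

  nests <- list()
  if (tumor) {
    nNests <- sampleRange(params$nestCountRange)
    for (i in seq_len(nNests)) {
      aUm <- max(params$nestAreaMinUm2,
                 rnorm(1, params$nestAreaMeanUm2, params$nestAreaSdUm2))
      aPx <- aUm / mpp2
      if (aPx > 0.5 * W * H)
        stop(sprintf("nest area %.0f um2 too large for a %dx%d px section",
                     aUm, W, H))
      for (try in 1:20) {
        d <- runif(1, 0, 0.5 * tissueR)
        th <- runif(1, 0, 2 * pi)
        ncx <- cx + d * cos(th); ncy <- cy + d * sin(th)
        ok <- TRUE
        for (nn in nests) {
          mind <- sqrt(aPx / pi) + sqrt(nn$areaPx / pi) + 4
          if (sqrt((ncx - nn$cx)^2 + (ncy - nn$cy)^2) < mind) { ok <- FALSE; break }
        }
        if (ok) break
      }
      poly <- blobPolygon(ncx, ncy, aPx, irregularity = 0.3)
      nests[[length(nests) + 1L]] <-
        list(cx = ncx, cy = ncy, areaPx = aPx, poly = poly)
    }
  }

  distractors <- list()
  nDist <- sampleRange(params$distractorCountRange)
  for (i in seq_len(nDist)) {
    aUm <- runif(1, params$distractorAreaRangeUm2[1], params$distractorAreaRangeUm2[2])
    aPx <- aUm / mpp2
    for (try in 1:30) {
      d <- runif(1, 0, 0.6 * tissueR)
      th <- runif(1, 0, 2 * pi)
      dcx <- cx + d * cos(th); dcy <- cy + d * sin(th)
      ok <- TRUE
      for (nn in nests) {
        mind <- sqrt(aPx / pi) + sqrt(nn$areaPx / pi) +
          params$stromaHaloUm / params$mpp + 6
        if (sqrt((dcx - nn$cx)^2 + (dcy - nn$cy)^2) < mind) { ok <- FALSE; break }
      }
      if (ok) break
    }
    distractors[[length(distractors) + 1L]] <-
      list(cx = dcx, cy = dcy, areaPx = aPx,
           poly = blobPolygon(dcx, dcy, aPx, irregularity = 0.2, nVertices = 24L))
  }

  # ---- rendering ---------------------------------------------------------
  tissueM <- rasterPoly(tissuePoly, W, H)
  nestM <- matrix(FALSE, H, W)
  stromaM <- matrix(FALSE, H, W)
  haloPx <- params$stromaHaloUm / params$mpp
  for (nn in nests) {
    nestM <- nestM | rasterPoly(nn$poly, W, H)
    stromaM <- stromaM | rasterPoly(dilatePolygon(nn$poly, haloPx), W, H)
  }
  stromaM <- stromaM & !nestM & tissueM
  distM <- matrix(FALSE, H, W)
  distCoreM <- matrix(FALSE, H, W)
  for (dd in distractors) {
    m <- rasterPoly(dd$poly, W, H)
    distM <- distM | m
    core <- blobPolygon(dd$cx, dd$cy, max(dd$areaPx * 0.25, 4), irregularity = 0.1,
                        nVertices = 16L)
    distCoreM <- distCoreM | rasterPoly(core, W, H)
  }
  distM <- distM & tissueM & !nestM
  distCoreM <- distCoreM & distM

  shift <- rnorm(3, 0, params$stainVariation)
  tex <- smoothNoise(H, W, params$textureScale) * 0.05
  grain <- matrix(runif(H * W), H, W)
  speckle <- grain < 0.05            # nuclei-like dark dots in tissue
  nestGrain <- grain < 0.25          # denser chromatin texture in nests
  img <- array(0, c(H, W, 3))
  tissueCol <- c(0.87, 0.70, 0.79) + shift
  nestCol <- c(0.45, 0.30, 0.55) + shift
  stromaCol <- tissueCol + c(0.04, 0.05, 0.03)
  coreCol <- c(0.93, 0.88, 0.90)
  for (ch in 1:3) {
    plane <- matrix(0.96, H, W) + smoothNoise(H, W, 32) * 0.01
    plane[tissueM] <- tissueCol[ch] + tex[tissueM]
    plane[speckle & tissueM] <- plane[speckle & tissueM] - 0.25
    plane[stromaM] <- stromaCol[ch] + tex[stromaM] * 0.5
    plane[nestM] <- nestCol[ch] + tex[nestM]
    plane[nestGrain & nestM] <- plane[nestGrain & nestM] - 0.10
    plane[distM] <- nestCol[ch] + 0.06 + tex[distM]
    plane[nestGrain & distM] <- plane[nestGrain & distM] - 0.08
    plane[distCoreM] <- coreCol[ch]
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }

  annotations <- c(
    lapply(nests, function(nn) list(class = "Tumornest", coords = nn$poly)),
    lapply(nests, function(nn)
      list(class = "Stroma", coords = dilatePolygon(nn$poly, haloPx))),
    lapply(distractors, function(dd) list(class = "Normal", coords = dd$poly))
  )
  list(image = img, annotations = annotations,
       label = if (length(nests) > 0) "Tumor" else "Normal",
       mpp = params$mpp, sectionId = sectionId)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes a train/val1/val2/test directory tree: PNG sections with mpp JSON
#' sidecars, GeoJSON annotations (train and val1 only), per-split
#' `labels.csv`, and a `manifest.json`. Labels are assigned balanced: each
#' split gets exactly `round(prevalence * n)` Tumor sections, in shuffled
#' order. Per-split seeds are `seed + 1..4`, so any split can be
#' regenerated independently; the same master seed reproduces the dataset
#' byte for byte.
#'
#' @param params a [fixtureParams()].
#' @param outDir output directory.
#' @param force overwrite an existing dataset.
#' @return the manifest (invisibly).
#' @export
generateDataset <- function(params = fixtureParams(), outDir, force = FALSE) {
  if (file.exists(file.path(outDir, "manifest.json")) && !force)
    stop("output directory already contains a dataset; use force = TRUE")
  splits <- names(params$nSections)
  manifest <- list(seed = params$seed, mpp = params$mpp, splits = list())
  for (si in seq_along(splits)) {
    split <- splits[si]
    n <- params$nSections[[split]]
    detailed <- split %in% c("train", "val1")
    dir.create(file.path(outDir, split, "sections"), recursive = TRUE,
               showWarnings = FALSE)
    if (detailed)
      dir.create(file.path(outDir, split, "annotations"), showWarnings = FALSE)
    entries <- withLocalSeed(params$seed + si, {
      nTumor <- round(params$prevalence * n)
      labels <- sample(rep(c("Tumor", "Normal"), c(nTumor, n - nTumor)))
      lapply(seq_len(n), function(i) {
        id <- sprintf("%s_%03d", split, i)
        sec <- generateSection(params, tumor = labels[i] == "Tumor",
                               sectionId = id)
        writeSection(sec$image, sec$mpp,
                     file.path(outDir, split, "sections", paste0(id, ".png")),
                     sectionId = id)
        if (detailed)
          writeAnnotations(sec$annotations,
                           file.path(outDir, split, "annotations",
                                     paste0(id, ".geojson")))
        list(id = id, width = dim(sec$image)[2], height = dim(sec$image)[1],
             label = sec$label,
             n_nests = sum(vapply(sec$annotations, function(a)
               a$class == "Tumornest", logical(1))))
      })
    })
    labdf <- data.frame(section_id = vapply(entries, `[[`, "", "id"),
                        label = vapply(entries, `[[`, "", "label"))
    write.csv(labdf, file.path(outDir, split, "labels.csv"), row.names = FALSE)
    manifest$splits[[split]] <- list(n = n, detailed = detailed,
                                     sections = entries)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
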