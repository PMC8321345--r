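# Annotation-coverage bookkeeping and the patch-balancing scheme: per-tile
# coverage fractions for the three annotation classes (Tumornest, Stroma,
# Normal), the five disjoint patch categories, the oversampling plan, and
# the pixel-unbalance statistic.

#' The five patch categories, in reporting order
#'
#' Background first, then tumor-containing, dense-tumor, stroma and
#' distractor patches. Categories are disjoint: each patch falls in exactly
#' one, assigned with precedence `T>=10%` > `T>=0.05%` > `S>=0.05%` >
#' `N>=0.05%` > `T<0.05%`; ties at a threshold fall into the higher
#' category (comparison is `>=` on the exact fractions 0.10 and 0.0005).
#'
#' @return character vector of category labels.
#' @export
patchCategories <- function() {
  c("T<0.05%", "T>=0.05%", "T>=10%", "S>=0.05%", "N>=0.05%")
}

ANNOTATION_CLASSES <- c(T = "Tumornest", S = "Stroma", N = "Normal")

checkPolygon <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 2 || nrow(coords) < 3)
    stop("polygon must be a matrix with >= 3 rows of (x, y) coordinates")
  if (!all(is.finite(coords))) stop("polygon has non-finite coordinates")
  n <- nrow(coords)
  segInt <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segInt(coords[i, ], coords[i %% n + 1, ],
                 coords[j, ], coords[j %% n + 1, ]))
        stop(sprintf("self-intersecting polygon (edges %d and %d)", i, j))
    }
  }
  invisible(TRUE)
}

#' Read / write polygon annotations as GeoJSON
#'
#' One FeatureCollection per section; each feature is a polygon (outer ring
#' only) with a `class` property in `Tumornest`, `Stroma`, `Normal`.
#' Coordinates are continuous pixel coordinates in the section frame,
#' 0-based: pixel `(ix, iy)` covers `[ix, ix+1) x [iy, iy+1)`.
#'
#' @param path GeoJSON file path.
#' @return `readAnnotations` returns a list of `list(class, coords)` with
#'   `coords` an n x 2 matrix of (x, y) vertices.
#' @export
readAnnotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  lapply(gj$features, function(f) {
    cls <- f$properties$class
    if (!cls %in% ANNOTATION_CLASSES)
      stop("unknown annotation class: ", cls)
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closing copy
    if (nrow(coords) > 1 && all(coords[1, ] == coords[nrow(coords), ]))
      coords <- coords[-nrow(coords), , drop = FALSE]
    list(class = cls, coords = coords)
  })
}

#' @rdname readAnnotations
#' @param annotations list as returned by `readAnnotations`.
#' @export
writeAnnotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    ring <- rbind(a$coords, a$coords[1, ])
    list(type = "Feature",
         properties = list(class = a$class),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(unname(ring[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# rasterize all polygons of one class into a tile-local mask
rasterizeClass <- function(annotations, class, origin, size) {
  polys <- lapply(Filter(function(a) a$class == class, annotations),
                  function(a) sweep(a$coords, 2, as.numeric(origin)))
  if (length(polys) == 0) return(matrix(FALSE, size, size))
  cpp_rasterize_polygons(polys, as.integer(size), as.integer(size))
}

#' Annotation coverage of a tile
#'
#' Fraction of tile pixels covered by polygons of each annotation class,
#' computed by scanline rasterization at pixel centers. The tile is the
#' half-open square `[x0, x0+size) x [y0, y0+size)` in section pixel
#' coordinates.
#'
#' @param origin length-2 integer `(x0, y0)`, 0-based tile origin.
#' @param size tile side length in pixels.
#' @param annotations list of `list(class, coords)` (see
#'   [readAnnotations()]); polygons must be in the same pixel frame as the
#'   tile. Invalid (self-intersecting) polygons are rejected with a
#'   diagnostic unless `validate = FALSE`.
#' @param validate check polygons before rasterizing.
#' @return named numeric `c(T = , S = , N = )` of fractions in `[0, 1]`.
#' @export
computeCoverage <- function(origin, size, annotations, validate = TRUE) {
  if (validate) for (a in annotations) checkPolygon(a$coords)
  vapply(ANNOTATION_CLASSES, function(cls)
    mean(rasterizeClass(annotations, cls, origin, size)), numeric(1))
}

#' Categorize patches by annotation coverage
#'
#' Assigns each patch to exactly one of the five disjoint categories of
#' [patchCategories()], with dense-tumor precedence: `T>=10%`, then
#' `T>=0.05%`, then `S>=0.05%`, then `N>=0.05%`, else the background
#' category `T<0.05%`.
#'
#' @param coverageT,coverageS,coverageN coverage fractions (vectors of equal
#'   length) in `[0, 1]`.
#' @return character vector of category labels.
#' @examples
#' categorizePatch(c(0.12, 0.001, 0), c(0, 0.2, 0), c(0, 0, 0))
#' @export
categorizePatch <- function(coverageT, coverageS = 0, coverageN = 0) {
  n <- max(length(coverageT), length(coverageS), length(coverageN))
  coverageT <- rep_len(coverageT, n)
  coverageS <- rep_len(coverageS, n)
  coverageN <- rep_len(coverageN, n)
  out <- rep(patchCategories()[1], n)
  out[coverageN >= 5e-4] <- "N>=0.05%"
  out[coverageS >= 5e-4] <- "S>=0.05%"
  out[coverageT >= 5e-4] <- "T>=0.05%"
  out[coverageT >= 0.10] <- "T>=10%"
  out
}

#' Build a patch inventory for a section
#'
#' Tiles the section on a regular grid (origins `0, stride, 2*stride, ...`,
#' plus a final flush tile when the section size is not a multiple of the
#' stride) and computes annotation coverage and category for every tile.
#'
#' @param sectionSize length-2 integer `(width, height)` in pixels.
#' @param patchSize tile side length.
#' @param annotations see [computeCoverage()].
#' @param stride grid step (default `patchSize`, i.e. non-overlapping).
#' @param sectionId id stored in the `section_id` column.
#' @return data.frame: `patch_id`, `section_id`, `origin_x`, `origin_y`,
#'   `coverage_T`, `coverage_S`, `coverage_N`, `category`.
#' @export
buildPatchInventory <- function(sectionSize, patchSize, annotations,
                                stride = patchSize, sectionId = "section") {
  for (a in annotations) checkPolygon(a$coords)
  gridAxis <- function(L) {
    if (L <= patchSize) return(0L)
    o <- seq(0L, L - patchSize, by = stride)
    if (o[length(o)] != L - patchSize) o <- c(o, L - patchSize)
    o
  }
  ox <- gridAxis(sectionSize[1])
  oy <- gridAxis(sectionSize[2])
  grid <- expand.grid(origin_x = ox, origin_y = oy)
  cov <- t(vapply(seq_len(nrow(grid)), function(i)
    computeCoverage(c(grid$origin_x[i], grid$origin_y[i]), patchSize,
                    annotations, validate = FALSE), numeric(3)))
  data.frame(
    patch_id = sprintf("%s_%d_%d", sectionId, grid$origin_x, grid$origin_y),
    section_id = sectionId,
    origin_x = grid$origin_x, origin_y = grid$origin_y,
    coverage_T = cov[, 1], coverage_S = cov[, 2], coverage_N = cov[, 3],
    category = categorizePatch(cov[, 1], cov[, 2], cov[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Build an oversampling plan from per-category targets
#'
#' Assigns a repetition count to every patch so that, within each category,
#' counts sum exactly to the category target and differ by at most one
#' across patches (round-robin: the remainder goes to the first patches in
#' inventory order). No patch is dropped: targets must be at least the
#' current category counts, and categories missing from `targets` keep
#' their current count (repetition 1).
#'
#' @param inventory data.frame with a `category` column (see
#'   [buildPatchInventory()]).
#' @param targets named numeric vector of per-category total counts, e.g.
#'   `c("T>=0.05%" = 30000, "T>=10%" = 10000)`.
#' @return the inventory with an added `repetitions` column; the realized
#'   per-category targets are stored in `attr(, "targets")`.
#' @examples
#' inv <- data.frame(category = rep(c("T<0.05%", "T>=0.05%"), c(5, 3)))
#' plan <- buildResamplingPlan(inv, c("T>=0.05%" = 10))
#' sum(plan$repetitions)  # 15
#' @export
buildResamplingPlan <- function(inventory, targets = numeric()) {
  stopifnot("category" %in% names(inventory))
  counts <- table(inventory$category)
  for (cat in names(targets)) {
    n <- if (cat %in% names(counts)) as.integer(counts[[cat]]) else 0L
    if (n == 0L && targets[[cat]] > 0)
      stop(sprintf("category '%s' is empty but has target %d", cat,
                   as.integer(targets[[cat]])))
    if (targets[[cat]] < n)
      stop(sprintf("target %d below current count %d for category '%s'",
                   as.integer(targets[[cat]]), n, cat))
  }
  reps <- rep(1L, nrow(inventory))
  realized <- counts
  for (cat in names(targets)) {
    idx <- which(inventory$category == cat)
    n <- length(idx)
    if (n == 0L) next
    t <- as.integer(targets[[cat]])
    base <- t %/% n
    rem <- t %% n
    reps[idx] <- base + as.integer(seq_len(n) <= rem)
    realized[[cat]] <- t
  }
  plan <- inventory
  plan$repetitions <- reps
  attr(plan, "targets") <- as.integer(realized)
  names(attr(plan, "targets")) <- names(realized)
  plan
}

#' Pixelwise tumor unbalance of an inventory or plan
#'
#' The ratio between the amounts of tumor-free and tumor pixels over all
#' patches, with repetition counts applied when present: with equally sized
#' tiles this is `sum((1 - coverage_T) * reps) / sum(coverage_T * reps)`.
#' An inventory with zero tumor pixels has no defined unbalance and is
#' rejected rather than returning infinity.
#'
#' @param inventory data.frame with `coverage_T` (and optionally
#'   `repetitions`).
#' @return the unbalance ratio (oversampling tumor-rich categories lowers it).
#' @export
pixelUnbalance <- function(inventory) {
  reps <- if ("repetitions" %in% names(inventory)) inventory$repetitions
          else rep(1, nrow(inventory))
  tumor <- sum(inventory$coverage_T * reps)
  if (tumor <= 0) stop("no tumor pixels: unbalance is undefined")
  sum((1 - inventory$coverage_T) * reps) / tumor
}

#' Read / write a patch inventory or plan as CSV
#' @param x inventory/plan data.frame.
#' @param path CSV file path.
#' @return `readInventory` returns the data.frame.
#' @export
writeInventory <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInventory
#' @export
readInventory <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
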