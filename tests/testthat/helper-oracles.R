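# Independent oracles used to cross-check the implementation.

# Connected-component labelling by iterative label relaxation (each pixel
# takes the minimum label among itself and its neighbours until a fixed
# point) -- independent of the union-find/stack labelling in the package.
floodFillOracle <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dy, dx) {
    out <- matrix(Inf, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  labNum <- matrix(Inf, H, W)
  labNum[mask] <- lab[mask]
  repeat {
    new <- labNum
    for (o in offs) new <- pmin(new, shift(labNum, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, labNum)) break
    labNum <- new
  }
  # renumber components in first-appearance (column-major) order
  out <- matrix(0L, H, W)
  ids <- unique(labNum[mask])
  for (i in seq_along(ids)) out[labNum == ids[i] & mask] <- i
  out
}

# Even-odd point-in-polygon test (ray casting) at pixel centers.
pointInPolygonOracle <- function(polys, H, W) {
  out <- matrix(FALSE, H, W)
  for (P in polys) {
    n <- nrow(P)
    for (y in seq_len(H)) {
      yc <- y - 0.5
      for (x in seq_len(W)) {
        xc <- x - 0.5
        inside <- FALSE
        j <- n
        for (i in seq_len(n)) {
          if ((P[i, 2] > yc) != (P[j, 2] > yc)) {
            xint <- P[i, 1] + (yc - P[i, 2]) * (P[j, 1] - P[i, 1]) /
              (P[j, 2] - P[i, 2])
            if (xc < xint) inside <- !inside
          }
          j <- i
        }
        if (inside) out[y, x] <- TRUE
      }
    }
  }
  out
}

# irregular test polygon around a center (not axis-aligned, never tie-prone)
randomBlob <- function(cx, cy, r, nv = 12) {
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- r * runif(nv, 0.5, 1)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

tinyConfig <- function(...) {
  segNetConfig(encoder = "vanilla", inputSize = 16L, nBlocks = 2L,
               baseWidth = 4L, seed = 99L, ...)
}

randomOneHot <- function(h, w, n = 1, p = 0.5) {
  y <- array(0, c(h, w, 2, n))
  m <- array(runif(h * w * n) < p, c(h, w, n))
  y[, , 1, ][m] <- 1
  y[, , 2, ][!m] <- 1
  if (n == 1) dim(y) <- c(h, w, 2)
  y
}
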