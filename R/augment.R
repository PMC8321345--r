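# Paired augmentation of (image, target) patches. Geometric transforms
# (rotation, scaling, elastic deformation, flips) are applied through one
# shared backward warp so image and mask stay aligned; photometric
# transforms (smoothing, color jitter) touch the image only. The target
# is resampled with nearest-neighbour so it stays exactly one-hot.

#' Band-limited smooth noise field
#'
#' Gaussian white noise drawn on a coarse grid and bilinearly upsampled,
#' giving a smooth random field with correlation length about `scale`
#' pixels. Used for elastic-deformation displacement fields and for the
#' synthetic fixture textures.
#'
#' @param h,w output size.
#' @param scale correlation length in pixels.
#' @param sd standard deviation of the coarse noise.
#' @return an `h x w` matrix.
#' @export
smoothNoise <- function(h, w, scale, sd = 1) {
  ch <- max(2L, ceiling(h / scale))
  cw <- max(2L, ceiling(w / scale))
  coarse <- array(rnorm(ch * cw, 0, sd), c(ch, cw, 1L, 1L))
  matrix(cpp_resize_bilinear_fw(coarse, as.integer(h), as.integer(w)), h, w)
}

#' Augmentation configuration
#'
#' Magnitudes are deliberately conservative defaults and fully exposed.
#' Setting every magnitude to zero (and the flags to `FALSE`) makes
#' [augmentPatch()] the identity.
#'
#' @param flip random horizontal/vertical flips.
#' @param rotate90 random rotation by a multiple of 90 degrees.
#' @param maxRotation extra continuous rotation, degrees (0 disables).
#' @param scaleRange multiplicative zoom range, e.g. `c(0.9, 1.1)`.
#' @param elasticProb probability of applying an elastic deformation.
#' @param elasticAlpha displacement amplitude in pixels.
#' @param elasticSigma correlation length of the displacement field, pixels.
#' @param blurSigmaMax smoothing: Gaussian sigma drawn from `[0, max]`.
#' @param colorJitter per-channel multiplicative/additive jitter amplitude.
#' @return a list with class `"wsisegAugmentConfig"`.
#' @export
augmentConfig <- function(flip = TRUE, rotate90 = TRUE, maxRotation = 10,
                          scaleRange = c(0.9, 1.1), elasticProb = 0.5,
                          elasticAlpha = 2, elasticSigma = 8,
                          blurSigmaMax = 0.8, colorJitter = 0.05) {
  structure(list(flip = flip, rotate90 = rotate90, maxRotation = maxRotation,
                 scaleRange = scaleRange, elasticProb = elasticProb,
                 elasticAlpha = elasticAlpha, elasticSigma = elasticSigma,
                 blurSigmaMax = blurSigmaMax, colorJitter = colorJitter),
            class = "wsisegAugmentConfig")
}

gaussianKernel <- function(sigma, radius = max(1L, ceiling(2 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

blurChannels <- function(img, sigma) {
  k <- gaussianKernel(sigma)
  r <- (length(k) - 1L) / 2L
  K <- array(outer(k, k), c(length(k), length(k), 1L, 1L))
  d <- dim(img)
  # renormalize by the blurred all-ones mask so zero padding does not darken borders
  wts <- array(cpp_conv_fw(array(1, c(d[1], d[2], 1L, 1L)), K, 0, 1L,
                           as.integer(r)), c(d[1], d[2]))
  for (cc in seq_len(d[3])) {
    ch <- array(img[, , cc], c(d[1], d[2], 1L, 1L))
    img[, , cc] <- array(cpp_conv_fw(ch, K, 0, 1L, as.integer(r)),
                         c(d[1], d[2])) / wts
  }
  img
}

#' Augment an (image, target) patch pair
#'
#' Draws one random geometric transform (flips, 90-degree and continuous
#' rotation, zoom, elastic deformation) applied identically to image and
#' target, followed by photometric smoothing and color jitter on the image
#' only. Uses the current RNG stream, so augmentation is reproducible under
#' a fixed seed. The returned target is exactly one-hot and shapes are
#' unchanged.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param target `(H, W, 2)` one-hot array (channel 1 = Tumor).
#' @param config an [augmentConfig()].
#' @return `list(image, target)`.
#' @export
augmentPatch <- function(image, target, config = augmentConfig()) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  # -- geometric draw ------------------------------------------------------
  flipH <- config$flip && runif(1) < 0.5
  flipV <- config$flip && runif(1) < 0.5
  quarter <- if (config$rotate90) sample(0:3, 1) else 0L
  angle <- quarter * 90 +
    if (config$maxRotation > 0) runif(1, -config$maxRotation, config$maxRotation) else 0
  zoom <- if (!is.null(config$scaleRange) && diff(range(config$scaleRange)) > 0)
    runif(1, config$scaleRange[1], config$scaleRange[2])
  else config$scaleRange[1]
  elastic <- config$elasticProb > 0 && runif(1) < config$elasticProb
  needWarp <- flipH || flipV || angle != 0 || zoom != 1 || elastic
  if (needWarp) {
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    gy <- matrix(seq_len(H) - 1, H, W) - cy
    gx <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
    th <- -angle * pi / 180           # inverse rotation for backward warp
    sy <- (cos(th) * gy - sin(th) * gx) / zoom
    sx <- (sin(th) * gy + cos(th) * gx) / zoom
    if (flipH) sx <- -sx
    if (flipV) sy <- -sy
    mapy <- sy + cy
    mapx <- sx + cx
    if (elastic) {
      mapy <- mapy + smoothNoise(H, W, config$elasticSigma) * config$elasticAlpha
      mapx <- mapx + smoothNoise(H, W, config$elasticSigma) * config$elasticAlpha
    }
    image <- cpp_warp(image, mapy, mapx, bilinear = TRUE, fill = 1)
    tumor <- cpp_warp(array(target[, , 1], c(H, W, 1L)), mapy, mapx,
                      bilinear = FALSE, fill = 0)
    target <- array(0, c(H, W, 2L))
    target[, , 1] <- tumor
    target[, , 2] <- 1 - tumor
  }
  # -- photometric ---------------------------------------------------------
  if (config$blurSigmaMax > 0) {
    sigma <- runif(1, 0, config$blurSigmaMax)
    if (sigma > 0.05) image <- blurChannels(image, sigma)
  }
  if (config$colorJitter > 0) {
    j <- config$colorJitter
    for (cc in 1:3)
      image[, , cc] <- image[, , cc] * (1 + runif(1, -j, j)) + runif(1, -j, j)
    image[image < 0] <- 0
    image[image > 1] <- 1
  }
  list(image = image, target = target)
}
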