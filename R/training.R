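# Loss functions, target downsampling, the optimizer schedule and the
# training loop.

PROB_CLAMP <- 1e-7

checkOneHot <- function(target) {
  t1 <- asBatch(target)
  if (dim(t1)[3] != 2L) stop("target map must have 2 channels (shape mismatch)")
  if (!all(t1 == 0 | t1 == 1)) stop("target map must be binary one-hot")
  s <- t1[, , 1, , drop = FALSE] + t1[, , 2, , drop = FALSE]
  if (!all(s == 1)) stop("target channels must sum to 1 at every pixel")
  invisible(TRUE)
}

# probability of the true class per pixel, (H, W, 1, N)
trueClassProb <- function(prob, target) {
  prob <- asBatch(prob); target <- asBatch(target)
  if (!identical(dim(prob), dim(target))) stop("prob/target shape mismatch")
  prob[, , 1, , drop = FALSE] * target[, , 1, , drop = FALSE] +
    prob[, , 2, , drop = FALSE] * target[, , 2, , drop = FALSE]
}

#' Focal loss on a probability map
#'
#' Per-pixel `-(1 - p_t)^gamma * log(p_t)` with `p_t` the predicted
#' probability of the true class, averaged over all pixels (and batch
#' entries). `gamma = 0` reduces to mean cross-entropy; larger `gamma`
#' down-weights easy (high `p_t`) pixels. Probabilities are clamped to
#' `[1e-7, 1]` inside the logarithm.
#'
#' @param prob probability map `(H, W, 2[, N])` (per-pixel softmax output).
#' @param target one-hot target of the same shape.
#' @param gamma focal exponent, `>= 0` (default 2 as used for training).
#' @return nonnegative scalar.
#' @examples
#' p <- array(c(0.9, 0.1), c(1, 1, 2)); y <- array(c(1, 0), c(1, 1, 2))
#' focalLoss(p, y, gamma = 2)  # 0.01 * (-log 0.9)
#' @export
focalLoss <- function(prob, target, gamma = 2) {
  stopifnot(gamma >= 0)
  checkOneHot(target)
  pt <- pmax(trueClassProb(prob, target), PROB_CLAMP)
  mean((1 - pt)^gamma * (-log(pt)))
}

# gradient of focalLoss(softmax(z), target) with respect to the scores z
focalGradScores <- function(scores, target, gamma) {
  prob <- softmaxChannels(scores)
  target <- asBatch(target)
  pt <- trueClassProb(prob, target)
  ptc <- pmin(pmax(pt, PROB_CLAMP), 1 - PROB_CLAMP)
  npix <- length(ptc)
  dpt <- if (gamma > 0) {
    (gamma * (1 - ptc)^(gamma - 1) * log(ptc) - (1 - ptc)^gamma / ptc) / npix
  } else {
    -1 / ptc / npix
  }
  g <- prob
  for (cc in 1:2) {
    g[, , cc, ] <- dpt * ptc *
      (target[, , cc, , drop = FALSE] - prob[, , cc, , drop = FALSE])
  }
  g
}

#' Downsample a one-hot target map to a decoder block's resolution
#'
#' The reduction operator mapping the full-resolution target to the grid of
#' decoder block `level` (0-based): the spatial size shrinks from
#' `inputSize` to `inputSize / 2^(k - 1 - level)`. The dialect is
#' class-preserving max-decimation: a coarse cell is Tumor if *any* of its
#' pixels is Tumor, so thin tumor structures survive at coarse scales; the
#' output is re-one-hot by construction.
#'
#' @param target one-hot array `(H, W, 2[, N])`, channel 1 = Tumor.
#' @param level 0-based decoder block index in `0..k-1`.
#' @param k number of decoder blocks.
#' @return one-hot array at the reduced resolution.
#' @export
downsampleTarget <- function(target, level, k) {
  if (level < 0 || level > k - 1) stop(sprintf("level must be in 0..%d", k - 1))
  checkOneHot(target)
  single <- length(dim(target)) == 3L
  target <- asBatch(target)
  f <- 2L^(k - 1L - level)
  if (f == 1L) return(if (single) array(target, dim(target)[1:3]) else target)
  d <- dim(target)
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop("target size not divisible by the downsampling factor")
  ho <- d[1] %/% f; wo <- d[2] %/% f
  out <- array(0, c(ho, wo, 2L, d[4]))
  for (n in seq_len(d[4])) {
    tum <- array(target[, , 1, n], c(f, ho, f, wo))
    m <- apply(tum, c(2, 4), max)
    out[, , 1, n] <- m
    out[, , 2, n] <- 1 - m
  }
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Deep supervision loss over all decoder blocks
#'
#' Sum over blocks `l = 0..k-1` of the focal loss between the block's
#' probability map and the correspondingly downsampled target, with equal
#' weight per scale. With `k = 1` this is exactly the focal loss on the
#' final map.
#'
#' @param outputs a [DecoderOutputs-class] (or a plain list of k probability
#'   maps, coarse to fine).
#' @param target full-resolution one-hot target.
#' @param config see [lossConfig()]; only `gamma` is used.
#' @return nonnegative scalar.
#' @export
deepSupervisionLoss <- function(outputs, target, config = lossConfig()) {
  maps <- if (is(outputs, "DecoderOutputs")) probMaps(outputs) else outputs
  k <- length(maps)
  if (k < 1) stop("no probability maps supplied")
  total <- 0
  for (l in seq_len(k)) {
    tl <- downsampleTarget(target, l - 1L, k)
    total <- total + focalLoss(maps[[l]], tl, config$gamma)
  }
  total
}

#' Loss configuration
#'
#' @param gamma focal exponent (default 2.0, the value used for training).
#' @param strategy `"deep_supervision"` (loss on every decoder block against
#'   downsampled targets), `"plain"` (focal loss on the final map only), or
#'   `"linear_merge"` (focal loss on the merged map; trains `w` jointly).
#' @return a list with class `"wsisegLossConfig"`.
#' @export
lossConfig <- function(gamma = 2,
                       strategy = c("deep_supervision", "plain", "linear_merge")) {
  stopifnot(gamma >= 0)
  structure(list(gamma = gamma, strategy = match.arg(strategy)),
            class = "wsisegLossConfig")
}

#' Training configuration
#'
#' Defaults follow the reference schedule: Adam, at most 40 epochs, batch
#' size 64, learning rate 5e-4 multiplied by 0.8 every 5 epochs.
#'
#' @param maxEpochs,batchSize,learningRate,lrDecayFactor,lrDecayEvery,seed
#'   see Description; all positive, decay factor in `(0, 1]`.
#' @param keepCheckpoints how many best epochs (by validation IoU) to retain.
#' @return a list with class `"wsisegTrainConfig"`.
#' @export
trainConfig <- function(maxEpochs = 40L, batchSize = 64L, learningRate = 5e-4,
                        lrDecayFactor = 0.8, lrDecayEvery = 5L,
                        keepCheckpoints = 5L, seed = NA_integer_) {
  stopifnot(maxEpochs >= 1, batchSize >= 1, learningRate > 0,
            lrDecayFactor > 0, lrDecayFactor <= 1, lrDecayEvery >= 1)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, lrDecayFactor = lrDecayFactor,
                 lrDecayEvery = as.integer(lrDecayEvery),
                 keepCheckpoints = as.integer(keepCheckpoints),
                 seed = as.integer(seed)),
            class = "wsisegTrainConfig")
}

#' Stepped learning-rate schedule
#'
#' `lr = learningRate * lrDecayFactor^floor(epoch / lrDecayEvery)` with
#' 0-based epochs: 5e-4 at epoch 0, 4e-4 at epoch 5, 3.2e-4 at epoch 10,
#' under the defaults.
#'
#' @param epoch 0-based epoch index.
#' @param config a [trainConfig()].
#' @return the learning rate.
#' @export
learningRateAt <- function(epoch, config = trainConfig()) {
  stopifnot(all(epoch >= 0))
  config$learningRate * config$lrDecayFactor^(epoch %/% config$lrDecayEvery)
}

adamInit <- function() list(m = list(), v = list(), t = 0L)

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- if (is.null(opt$m[[nm]])) g * 0 else opt$m[[nm]]
    v <- if (is.null(opt$v[[nm]])) g * 0 else opt$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# stack a list of (H,W,C) arrays into (H,W,C,B)
stackPatches <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Train a segmentation network
#'
#' Adam optimization with the stepped learning-rate schedule of
#' [learningRateAt()] and the loss selected by `lossConfig$strategy`.
#' Training patches may carry repetition counts (from a resampling plan) and
#' are optionally augmented on the fly; validation patches are used as-is
#' (no resampling, no augmentation). After every epoch the mean validation
#' IoU of the thresholded final map (tumor probability >= 0.5) is recorded,
#' and the parameter sets of the best `keepCheckpoints` epochs by validation
#' IoU are retained.
#'
#' @param network a freshly built (or partially trained) [SegNet-class].
#' @param trainPatches list of `list(image = (H,W,3), target = (H,W,2))`.
#' @param valPatches like `trainPatches`; un-augmented validation stream.
#' @param config a [trainConfig()]. The seed makes patch order, augmentation
#'   draws, and hence the whole history reproducible.
#' @param loss a [lossConfig()].
#' @param repetitions integer vector of per-patch repetition counts (default
#'   all 1), e.g. the `repetitions` column of a resampling plan.
#' @param augment an [augmentConfig()] or `NULL` for no augmentation.
#' @param verbose print per-epoch progress.
#' @return list with elements `network` (best epoch by validation IoU),
#'   `checkpoints` (list of `list(network, epoch, valIoU)`, best first) and
#'   `history` (data.frame: epoch, loss, valIoU, lr).
#' @export
trainNetwork <- function(network, trainPatches, valPatches,
                         config = trainConfig(), loss = lossConfig(),
                         repetitions = NULL, augment = NULL, verbose = FALSE) {
  if (length(trainPatches) == 0) stop("empty training set")
  if (length(valPatches) == 0) stop("empty validation set")
  if (is.null(repetitions)) repetitions <- rep(1L, length(trainPatches))
  stopifnot(length(repetitions) == length(trainPatches), all(repetitions >= 1))
  if (loss$strategy == "linear_merge" && is.null(network@params[["merge.w"]]))
    stop("linear_merge training requires a network built with useLinearMerge")
  k <- network@config@nBlocks
  params <- network@params
  state <- network@state
  opt <- adamInit()
  history <- data.frame(epoch = integer(), loss = numeric(),
                        valIoU = numeric(), lr = numeric())
  checkpoints <- list()
  withLocalSeed(config$seed, {
    pool <- rep(seq_along(trainPatches), times = repetitions)
    for (epoch in 0:(config$maxEpochs - 1L)) {
      lr <- learningRateAt(epoch, config)
      order <- sample(pool)
      nb <- ceiling(length(order) / config$batchSize)
      epochLoss <- 0
      for (b in seq_len(nb)) {
        take <- order[((b - 1L) * config$batchSize + 1L):
                      min(b * config$batchSize, length(order))]
        imgs <- vector("list", length(take))
        tgts <- vector("list", length(take))
        for (i in seq_along(take)) {
          p <- trainPatches[[take[i]]]
          if (!is.null(augment)) {
            a <- augmentPatch(p$image, p$target, augment)
            imgs[[i]] <- a$image; tgts[[i]] <- a$target
          } else {
            imgs[[i]] <- p$image; tgts[[i]] <- p$target
          }
        }
        x <- stackPatches(imgs)
        y <- stackPatches(tgts)
        net <- new("SegNet", config = network@config, params = params, state = state)
        fw <- segnetForward(net, x, training = TRUE,
                            withMerge = loss$strategy == "linear_merge")
        state <- fw$tp$state
        seeds <- list()
        lossVal <- 0
        if (loss$strategy == "plain") {
          z <- fw$tp$vals[[fw$scoreIds[k]]]
          lossVal <- focalLoss(softmaxChannels(z), y, loss$gamma)
          seeds[[as.character(fw$scoreIds[k])]] <- focalGradScores(z, y, loss$gamma)
        } else if (loss$strategy == "deep_supervision") {
          for (l in seq_len(k)) {
            tl <- downsampleTarget(y, l - 1L, k)
            z <- fw$tp$vals[[fw$scoreIds[l]]]
            lossVal <- lossVal + focalLoss(softmaxChannels(z), tl, loss$gamma)
            seeds[[as.character(fw$scoreIds[l])]] <- focalGradScores(z, tl, loss$gamma)
          }
        } else {
          z <- fw$tp$vals[[fw$mergeId]]
          lossVal <- focalLoss(softmaxChannels(z), y, loss$gamma)
          seeds[[as.character(fw$mergeId)]] <- focalGradScores(z, y, loss$gamma)
        }
        if (!is.finite(lossVal))
          stop(sprintf("non-finite training loss at epoch %d batch %d; aborting",
                       epoch, b))
        grads <- tapeBackward(fw$tp, seeds)
        st <- adamStep(params, grads, opt, lr)
        params <- st$params
        opt <- st$opt
        epochLoss <- epochLoss + lossVal * length(take)
      }
      epochLoss <- epochLoss / length(order)
      net <- new("SegNet", config = network@config, params = params, state = state)
      valIoU <- meanValidationIoU(net, valPatches)
      history <- rbind(history, data.frame(epoch = epoch, loss = epochLoss,
                                           valIoU = valIoU, lr = lr))
      checkpoints[[length(checkpoints) + 1L]] <-
        list(network = net, epoch = epoch, valIoU = valIoU)
      if (length(checkpoints) > config$keepCheckpoints) {
        drop <- which.min(vapply(checkpoints, function(c) c$valIoU, numeric(1)))
        checkpoints[[drop]] <- NULL
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.5f, val IoU %.4f, lr %.2e",
                        epoch, epochLoss, valIoU, lr))
    }
  })
  ord <- order(vapply(checkpoints, function(c) c$valIoU, numeric(1)),
               decreasing = TRUE)
  checkpoints <- checkpoints[ord]
  list(network = checkpoints[[1]]$network, checkpoints = checkpoints,
       history = history)
}

# mean IoU of thresholded final tumor maps over validation patches
meanValidationIoU <- function(network, valPatches, batchSize = 16L) {
  n <- length(valPatches)
  ious <- numeric(n)
  i <- 1L
  while (i <= n) {
    take <- i:min(i + batchSize - 1L, n)
    x <- stackPatches(lapply(valPatches[take], `[[`, "image"))
    out <- forwardSegment(network, x)
    fin <- finalMap(out)
    for (j in seq_along(take)) {
      pred <- fin[, , 1, j] >= 0.5
      truth <- valPatches[[take[j]]]$target[, , 1] > 0.5
      ious[take[j]] <- iou(pred, truth)
    }
    i <- i + batchSize
  }
  mean(ious)
}
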