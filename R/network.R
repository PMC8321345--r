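# Network construction and forward passes.
#
# Both encoders expose one feature map per scale (1/2, 1/4, ..., 1/2^k of
# the input). The decoder has k blocks, each: bilinear 2x upsampling,
# concatenation with the symmetric encoder feature (the last block has no
# skip), two 3x3 conv+BN+ReLU, and a 1x1 score head producing a 2-channel
# pre-activation map. Every convolution except the 1x1 heads is followed by
# batch normalization and ReLU; padding keeps spatial sizes unchanged.

# channel count of each encoder scale, shallow (1/2) to deep (1/2^k)
encoderChannels <- function(config) {
  W <- config@baseWidth
  if (config@encoder == "vanilla") {
    W * 2L^(seq_len(config@nBlocks) - 1L)
  } else {
    as.integer(W * c(1, 1, 2, 4, 8))
  }
}

# decoder output channels per block: start from the bottleneck count, halve
# per block, floored at 16
decoderChannels <- function(config) {
  cb <- encoderChannels(config)[config@nBlocks]
  pmax(cb %/% 2L^seq_len(config@nBlocks), 16L)
}

RESNET34_UNITS <- c(3L, 4L, 6L, 3L)

#' Build a segmentation network
#'
#' Initializes all parameters of the configured U-Net variant (He-normal
#' convolution weights, unit batch-norm scale) and, when the linear merge is
#' enabled, the merge weight vector `w` (initialized uniformly to `1/k`).
#'
#' @param config a [SegNetConfig-class] (see [segNetConfig()]); its `seed`
#'   slot, when not `NA`, makes the initialization reproducible without
#'   touching the caller's RNG stream.
#' @return a [SegNet-class].
#' @examples
#' net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 4, seed = 1))
#' net
#' @export
buildNetwork <- function(config) {
  stopifnot(is(config, "SegNetConfig"))
  validObject(config)
  withLocalSeed(config@seed, {
    params <- list()
    state <- list()
    addConv <- function(name, kh, kw, cin, cout) {
      sd <- sqrt(2 / (kh * kw * cin))
      params[[paste0(name, ".w")]] <<-
        array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
      params[[paste0(name, ".b")]] <<- numeric(cout)
    }
    addBN <- function(name, cc) {
      params[[paste0(name, ".gamma")]] <<- rep(1, cc)
      params[[paste0(name, ".beta")]] <<- rep(0, cc)
      state[[paste0(name, ".mean")]] <<- rep(0, cc)
      state[[paste0(name, ".var")]] <<- rep(1, cc)
    }
    k <- config@nBlocks
    W <- config@baseWidth
    encCh <- encoderChannels(config)
    addConv("enc.stem.conv", 7, 7, config@inChannels, W)
    addBN("enc.stem.bn", W)
    if (config@encoder == "vanilla") {
      if (k >= 2) for (i in 2:k) {
        addConv(sprintf("enc.b%d.conv1", i), 3, 3, encCh[i - 1], encCh[i])
        addBN(sprintf("enc.b%d.bn1", i), encCh[i])
        addConv(sprintf("enc.b%d.conv2", i), 3, 3, encCh[i], encCh[i])
        addBN(sprintf("enc.b%d.bn2", i), encCh[i])
      }
    } else {
      chans <- W * c(1L, 2L, 4L, 8L)
      prev <- W
      for (s in 1:4) {
        for (u in seq_len(RESNET34_UNITS[s])) {
          pf <- sprintf("enc.s%d.u%d", s, u)
          stride <- if (u == 1L && s > 1L) 2L else 1L
          addConv(paste0(pf, ".conv1"), 3, 3, prev, chans[s])
          addBN(paste0(pf, ".bn1"), chans[s])
          addConv(paste0(pf, ".conv2"), 3, 3, chans[s], chans[s])
          addBN(paste0(pf, ".bn2"), chans[s])
          if (stride != 1L || prev != chans[s]) {
            addConv(paste0(pf, ".down.conv"), 1, 1, prev, chans[s])
            addBN(paste0(pf, ".down.bn"), chans[s])
          }
          prev <- chans[s]
        }
      }
    }
    decCh <- decoderChannels(config)
    for (l in seq_len(k)) {
      cinUp <- if (l == 1L) encCh[k] else decCh[l - 1]
      cin <- cinUp + if (l <= k - 1L) encCh[k - l] else 0L
      addConv(sprintf("dec.b%d.conv1", l), 3, 3, cin, decCh[l])
      addBN(sprintf("dec.b%d.bn1", l), decCh[l])
      addConv(sprintf("dec.b%d.conv2", l), 3, 3, decCh[l], decCh[l])
      addBN(sprintf("dec.b%d.bn2", l), decCh[l])
      addConv(sprintf("dec.b%d.head", l), 1, 1, decCh[l], config@nClasses)
    }
    if (config@useLinearMerge) params[["merge.w"]] <- rep(1 / k, k)
    new("SegNet", config = config, params = params, state = state)
  })
}

convBNReLU <- function(tp, id, pf, stride, pad, convName = "conv", bnName = "bn") {
  id <- opConv(tp, id, paste0(pf, ".", convName), stride, pad)
  id <- opBN(tp, id, paste0(pf, ".", bnName))
  opReLU(tp, id)
}

resnetUnit <- function(tp, id, pf, stride, hasDown) {
  idn <- opConv(tp, id, paste0(pf, ".conv1"), stride, 1)
  idn <- opBN(tp, idn, paste0(pf, ".bn1"))
  idn <- opReLU(tp, idn)
  idn <- opConv(tp, idn, paste0(pf, ".conv2"), 1, 1)
  idn <- opBN(tp, idn, paste0(pf, ".bn2"))
  sid <- if (hasDown) {
    opBN(tp, opConv(tp, id, paste0(pf, ".down.conv"), stride, 0),
         paste0(pf, ".down.bn"))
  } else id
  opReLU(tp, opAdd(tp, idn, sid))
}

# Internal forward pass. Runs the encoder and decoder blocks 1..uptoBlock
# (1-based; default all k). Returns the tape, the encoder feature ids and
# the score-head ids; when the linear merge is active and the full decoder
# was run, also the id of the merged pre-activation map.
segnetForward <- function(net, x, training = FALSE, uptoBlock = NULL,
                          withMerge = net@config@useLinearMerge) {
  cfg <- net@config
  x <- asBatch(x)
  d <- dim(x)
  if (d[1] != cfg@inputSize || d[2] != cfg@inputSize || d[3] != cfg@inChannels)
    stop(sprintf("input shape %dx%dx%d does not match configured %dx%dx%d",
                 d[1], d[2], d[3], cfg@inputSize, cfg@inputSize, cfg@inChannels))
  k <- cfg@nBlocks
  if (is.null(uptoBlock)) uptoBlock <- k
  stopifnot(uptoBlock >= 1L, uptoBlock <= k)
  tp <- tapeNew(net@params, net@state, training)
  id <- tapePut(tp, x)
  feats <- integer(k)
  id <- convBNReLU(tp, id, "enc.stem", 2, 3)
  feats[1] <- id
  if (cfg@encoder == "vanilla") {
    if (k >= 2) for (i in 2:k) {
      pf <- sprintf("enc.b%d", i)
      id <- convBNReLU(tp, id, pf, 2, 1, "conv1", "bn1")
      id <- convBNReLU(tp, id, pf, 1, 1, "conv2", "bn2")
      feats[i] <- id
    }
  } else {
    chans <- cfg@baseWidth * c(1L, 2L, 4L, 8L)
    prev <- cfg@baseWidth
    id <- opMaxPool(tp, id, 3, 2, 1)
    for (s in 1:4) {
      for (u in seq_len(RESNET34_UNITS[s])) {
        stride <- if (u == 1L && s > 1L) 2L else 1L
        id <- resnetUnit(tp, id, sprintf("enc.s%d.u%d", s, u), stride,
                         hasDown = (stride != 1L || prev != chans[s]))
        prev <- chans[s]
      }
      feats[s + 1] <- id
    }
  }
  scoreIds <- rep(NA_integer_, k)
  for (l in seq_len(uptoBlock)) {
    sz <- dim(tp$vals[[id]])[1] * 2L
    id <- opUpsample(tp, id, sz, sz)
    if (l <= k - 1L) id <- opConcat(tp, id, feats[k - l])
    pf <- sprintf("dec.b%d", l)
    id <- convBNReLU(tp, id, pf, 1, 1, "conv1", "bn1")
    id <- convBNReLU(tp, id, pf, 1, 1, "conv2", "bn2")
    scoreIds[l] <- opConv(tp, id, paste0(pf, ".head"), 1, 0)
  }
  mergeId <- NULL
  if (withMerge && uptoBlock == k && !is.null(net@params[["merge.w"]])) {
    upIds <- integer(k)
    for (l in seq_len(k))
      upIds[l] <- opUpsample(tp, scoreIds[l], cfg@inputSize, cfg@inputSize)
    mergeId <- opMerge(tp, upIds, "merge.w")
  }
  list(tp = tp, feats = feats, scoreIds = scoreIds, mergeId = mergeId)
}

#' Run a full forward segmentation pass
#'
#' Computes all per-block score maps, their per-pixel softmax probability
#' maps, and the final full-resolution probability map. With the linear
#' merge disabled the final map is the last block's probability map; with it
#' enabled, the softmax of the `w`-weighted sum of all bilinearly upsampled
#' score maps (softmax applied only once, after the combination).
#'
#' @param network a [SegNet-class].
#' @param image `(H, W, C)` array in `[0, 1]`, or an `(H, W, C, N)` batch,
#'   matching the configured input size and channels.
#' @param train logical; training mode uses batch statistics in the
#'   batch-normalization layers, evaluation mode (the default) uses the
#'   frozen running statistics, making the pass deterministic.
#' @return a [DecoderOutputs-class].
#' @examples
#' net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 4, seed = 1))
#' out <- forwardSegment(net, array(0.5, c(64, 64, 3)))
#' vapply(probMaps(out), function(m) dim(m)[1], numeric(1))
#' @export
forwardSegment <- function(network, image, train = FALSE) {
  single <- length(dim(image)) == 3L
  fw <- segnetForward(network, image, training = train)
  scores <- lapply(fw$scoreIds, function(i) fw$tp$vals[[i]])
  probs <- lapply(scores, softmaxChannels)
  final <- if (!is.null(fw$mergeId)) softmaxChannels(fw$tp$vals[[fw$mergeId]])
           else probs[[length(probs)]]
  if (single) {
    scores <- lapply(scores, function(a) array(a, dim(a)[1:3]))
    probs <- lapply(probs, function(a) array(a, dim(a)[1:3]))
    final <- array(final, dim(final)[1:3])
  }
  new("DecoderOutputs", scoreMaps = scores, probMaps = probs, final = final)
}

#' Linearly merge per-block score maps into a final probability map
#'
#' Each pre-activation score map is bilinearly upsampled to the output
#' resolution, the maps are combined as `sum_l w[l] * up(score_l)`, and the
#' softmax is applied once at the end. With `w = (0, ..., 0, 1)` this
#' reproduces the standard final output (softmax of the last score map).
#'
#' @param scoreMaps list of k `(h_l, w_l, 2[, N])` pre-activation arrays
#'   (e.g. `scoreMaps(forwardSegment(...))`).
#' @param weights numeric vector of length k.
#' @param outputSize target spatial size; defaults to the size of the last
#'   (finest) score map.
#' @return probability array `(outputSize, outputSize, 2[, N])`.
#' @export
mergeLinear <- function(scoreMaps, weights, outputSize = NULL) {
  k <- length(scoreMaps)
  if (length(weights) != k)
    stop(sprintf("%d score maps but %d weights", k, length(weights)))
  single <- length(dim(scoreMaps[[k]])) == 3L
  if (is.null(outputSize)) outputSize <- dim(scoreMaps[[k]])[1]
  acc <- NULL
  for (l in seq_len(k)) {
    up <- cpp_resize_bilinear_fw(asBatch(scoreMaps[[l]]),
                                 as.integer(outputSize), as.integer(outputSize))
    acc <- if (is.null(acc)) weights[l] * up else acc + weights[l] * up
  }
  out <- softmaxChannels(acc)
  if (single) out <- array(out, dim(out)[1:3])
  out
}

#' Truncated inference through a prefix of the decoder
#'
#' Runs the encoder plus decoder blocks `0..blockIndex`, applies that
#' block's 1x1 score head and softmax, and bilinearly upsamples the result
#' to the input resolution. `blockIndex = k - 1` reproduces the full forward
#' pass exactly; small indices trade boundary detail for speed. Meaningful
#' intermediate outputs require a network trained with deep supervision.
#'
#' @inheritParams forwardSegment
#' @param blockIndex 0-based decoder block index `l` in `0..k-1`.
#' @return full-resolution probability array `(inputSize, inputSize, 2[, N])`.
#' @export
truncatedForward <- function(network, image, blockIndex) {
  k <- network@config@nBlocks
  if (blockIndex < 0 || blockIndex > k - 1)
    stop(sprintf("blockIndex must be in 0..%d", k - 1))
  single <- length(dim(image)) == 3L
  fw <- segnetForward(network, image, training = FALSE,
                      uptoBlock = blockIndex + 1L, withMerge = FALSE)
  prob <- softmaxChannels(fw$tp$vals[[fw$scoreIds[blockIndex + 1L]]])
  sz <- network@config@inputSize
  if (dim(prob)[1] != sz) prob <- cpp_resize_bilinear_fw(prob, sz, sz)
  if (single) prob <- array(prob, dim(prob)[1:3])
  prob
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the configuration, so [loadCheckpoint()] restores a
#' runnable network without the original training configuration.
#'
#' @param network a [SegNet-class].
#' @param path file path (`.rds`).
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the restored [SegNet-class].
#' @export
saveCheckpoint <- function(network, path) {
  cfg <- network@config
  saveRDS(list(
    format = "wsiseg-checkpoint-1",
    config = list(encoder = cfg@encoder, inputSize = cfg@inputSize,
                  inChannels = cfg@inChannels, nClasses = cfg@nClasses,
                  nBlocks = cfg@nBlocks, baseWidth = cfg@baseWidth,
                  useLinearMerge = cfg@useLinearMerge, seed = cfg@seed),
    params = network@params, state = network@state
  ), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "wsiseg-checkpoint-1")) stop("not a wsiseg checkpoint")
  cfg <- do.call(segNetConfig, ck$config)
  new("SegNet", config = cfg, params = ck$params, state = ck$state)
}
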