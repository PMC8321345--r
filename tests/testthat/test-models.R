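test_that("configuration invariants are enforced", {
  expect_error(segNetConfig(inputSize = 500), "divisible")
  expect_error(segNetConfig(encoder = "resnet34", nBlocks = 4, inputSize = 128),
               "nBlocks = 5")
  expect_error(segNetConfig(nClasses = 3), "nClasses")
  expect_s4_class(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 8),
                  "SegNetConfig")
})

test_that("network configs round-trip through YAML and JSON blocks", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("network:", "  encoder_kind: resnet34", "  input_size: 128",
               "  n_decoder_blocks: 5", "  base_width: 4",
               "  use_linear_merge: true", "  seed: 7"), yml)
  cfg <- readNetworkConfig(yml)
  expect_identical(cfg@encoder, "resnet34")
  expect_identical(cfg@inputSize, 128L)
  expect_true(cfg@useLinearMerge)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(encoder = "vanilla", inputSize = 64, nBlocks = 4,
                            baseWidth = 8), js, auto_unbox = TRUE)
  expect_identical(readNetworkConfig(js)@inputSize, 64L)
})

test_that("decoder emits score maps at 32*2^l scaling and a full-size final map", {
  # reference 512-px geometry, k = 5 (width scaled down for CPU)
  net <- buildNetwork(segNetConfig(inputSize = 512, nBlocks = 5, baseWidth = 4,
                                   seed = 1))
  out <- forwardSegment(net, array(runif(512 * 512 * 3), c(512, 512, 3)))
  expect_equal(vapply(probMaps(out), function(m) dim(m)[1], numeric(1)),
               32 * 2^(0:4))
  expect_equal(dim(finalMap(out)), c(512, 512, 2))
  # smaller geometry shares the exact topology: halving/doubling symmetry
  net128 <- buildNetwork(segNetConfig(inputSize = 128, nBlocks = 5,
                                      baseWidth = 4, seed = 1))
  out128 <- forwardSegment(net128, array(0.5, c(128, 128, 3)))
  expect_equal(vapply(probMaps(out128), function(m) dim(m)[1], numeric(1)),
               c(8, 16, 32, 64, 128))
})

test_that("first encoder stage halves resolution with baseWidth channels", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 8,
                                   seed = 2))
  fw <- wsiseg:::segnetForward(net, array(0.5, c(64, 64, 3)))
  stem <- fw$tp$vals[[fw$feats[1]]]
  expect_equal(dim(stem)[1:3], c(32, 32, 8))
  expect_equal(dim(net@params[["enc.stem.conv.w"]]), c(7, 7, 3, 8))
})

test_that("probability maps are per-pixel distributions and final equals last map", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 8,
                                   seed = 3))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- forwardSegment(net, x)
  for (m in probMaps(out)) {
    expect_true(all(m >= 0))
    expect_lt(max(abs(m[, , 1] + m[, , 2] - 1)), 1e-5)
  }
  expect_identical(finalMap(out), probMaps(out)[[4]])
  # deterministic in evaluation mode
  out2 <- forwardSegment(net, x)
  expect_identical(finalMap(out2), finalMap(out))
  expect_error(forwardSegment(net, array(0.5, c(32, 32, 3))), "match")
})

test_that("resnet34 backbone has more encoder parameters than the vanilla encoder", {
  encParams <- function(net) {
    nm <- names(net@params)
    sum(vapply(net@params[startsWith(nm, "enc.")], length, numeric(1)))
  }
  v <- buildNetwork(segNetConfig("vanilla", inputSize = 128, nBlocks = 5,
                                 baseWidth = 8, seed = 1))
  r <- buildNetwork(segNetConfig("resnet34", inputSize = 128, nBlocks = 5,
                                 baseWidth = 8, seed = 1))
  expect_gt(encParams(r), encParams(v))
})

test_that("linear merge reduces to the standard output for w = (0,...,0,1)", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 8,
                                   seed = 4))
  out <- forwardSegment(net, array(runif(64 * 64 * 3), c(64, 64, 3)))
  merged <- mergeLinear(scoreMaps(out), c(0, 0, 0, 1))
  expect_equal(merged, finalMap(out), tolerance = 1e-12)
  # all-zero weights: softmax of zeros is uniform
  flat <- mergeLinear(scoreMaps(out), c(0, 0, 0, 0))
  expect_equal(max(abs(flat - 0.5)), 0, tolerance = 1e-12)
  expect_error(mergeLinear(scoreMaps(out), c(1, 2)), "weights")
})

test_that("linear merge matches scalar softmax arithmetic on toy maps", {
  # two constant 1x1-upsampled score maps, hand-set weights
  s1 <- array(c(2, -1), c(1, 1, 2))       # coarse block
  s2 <- array(c(0.5, 1), c(2, 2, 2))      # fine block, constant per channel
  s2[, , 1] <- 0.5; s2[, , 2] <- 1
  w <- c(0.3, -0.7)
  got <- mergeLinear(list(s1, s2), w, outputSize = 2)
  z1 <- 0.3 * 2 + (-0.7) * 0.5
  z2 <- 0.3 * (-1) + (-0.7) * 1
  expect_equal(got[1, 1, 1], exp(z1) / (exp(z1) + exp(z2)), tolerance = 1e-12)
  expect_equal(got[2, 2, 2], exp(z2) / (exp(z1) + exp(z2)), tolerance = 1e-12)
})

test_that("truncated inference is a prefix of the full pass", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 8,
                                   seed = 5))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  full <- forwardSegment(net, x)
  expect_identical(truncatedForward(net, x, 3), finalMap(full))
  # psi0 lives on an 8x8 grid here; truncated output is upsampled to full size
  t0 <- truncatedForward(net, x, 0)
  expect_equal(dim(t0), c(64, 64, 2))
  expect_lt(max(abs(t0[, , 1] + t0[, , 2] - 1)), 1e-5)
  expect_error(truncatedForward(net, x, 4), "blockIndex")
  expect_error(truncatedForward(net, x, -1), "blockIndex")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- tinyConfig()
  net <- buildNetwork(cfg)
  set.seed(11)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- randomOneHot(16, 16, 2)
  gamma <- 2
  k <- cfg@nBlocks
  lossOf <- function(params) {
    n2 <- new("SegNet", config = cfg, params = params, state = net@state)
    fw <- wsiseg:::segnetForward(n2, x, training = TRUE, withMerge = FALSE)
    L <- 0
    for (l in seq_len(k)) {
      tl <- downsampleTarget(y, l - 1L, k)
      z <- fw$tp$vals[[fw$scoreIds[l]]]
      L <- L + focalLoss(wsiseg:::softmaxChannels(z), tl, gamma)
    }
    L
  }
  fw <- wsiseg:::segnetForward(net, x, training = TRUE, withMerge = FALSE)
  seeds <- list()
  for (l in seq_len(k)) {
    tl <- downsampleTarget(y, l - 1L, k)
    seeds[[as.character(fw$scoreIds[l])]] <-
      wsiseg:::focalGradScores(fw$tp$vals[[fw$scoreIds[l]]], tl, gamma)
  }
  grads <- wsiseg:::tapeBackward(fw$tp, seeds)
  eps <- 1e-5
  set.seed(12)
  for (nm in sample(names(grads), 8)) {
    i <- sample(length(net@params[[nm]]), 1)
    p1 <- net@params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- net@params; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
    ana <- grads[[nm]][i]
    expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
  }
})

test_that("checkpoints embed the configuration and restore exactly", {
  net <- buildNetwork(segNetConfig(inputSize = 64, nBlocks = 4, baseWidth = 4,
                                   seed = 6))
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  expect_identical(net2@params, net@params)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(finalMap(forwardSegment(net2, x)),
                   finalMap(forwardSegment(net, x)))
})
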