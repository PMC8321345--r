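#' Network configuration for the U-Net variants
#'
#' Describes the topology of a segmentation network: which encoder backbone
#' to use, the input patch geometry, the number of decoder blocks `k`, the
#' base channel width, and whether the final map is produced by the learned
#' linear merge of the per-block score maps.
#'
#' The decoder always has `nBlocks` (= `k`) blocks, each doubling the spatial
#' resolution; block `l` (0-based) therefore emits a score map of spatial
#' size `inputSize / 2^(k - 1 - l)`, i.e. `32 * 2^l` for the reference
#' 512-pixel geometry with `k = 5`. `inputSize` must be divisible by
#' `2^(k+1)` so every encoder scale has integer size.
#'
#' @slot encoder `"vanilla"` (strided-convolution U-Net encoder) or
#'   `"resnet34"` (34-layer residual backbone; requires `nBlocks = 5`).
#' @slot inputSize patch side length in pixels.
#' @slot inChannels number of input channels (3 for RGB).
#' @slot nClasses number of output classes (fixed to 2: Tumor, Normal).
#' @slot nBlocks number of decoder blocks `k`.
#' @slot baseWidth channel count of the first encoder stage (64 for the
#'   reference geometry; scale down for CPU-sized networks).
#' @slot useLinearMerge logical; final map = softmax of the `w`-weighted sum
#'   of bilinearly upsampled per-block score maps.
#' @slot seed integer seed used for parameter initialization (`NA` = leave
#'   the RNG stream alone).
#' @seealso [segNetConfig()], [buildNetwork()]
#' @export
setClass("SegNetConfig",
  representation(
    encoder = "character",
    inputSize = "integer",
    inChannels = "integer",
    nClasses = "integer",
    nBlocks = "integer",
    baseWidth = "integer",
    useLinearMerge = "logical",
    seed = "integer"
  )
)

setValidity("SegNetConfig", function(object) {
  msg <- character()
  if (!object@encoder %in% c("vanilla", "resnet34"))
    msg <- c(msg, "encoder must be 'vanilla' or 'resnet34'")
  k <- object@nBlocks
  if (k < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@nClasses != 2L) msg <- c(msg, "nClasses must be 2 (Tumor, Normal)")
  if (object@inputSize < 2L || object@inputSize %% (2L^(k + 1L)) != 0L)
    msg <- c(msg, sprintf("inputSize must be divisible by 2^(k+1) = %d", 2L^(k + 1L)))
  if (object@encoder == "resnet34" && k != 5L)
    msg <- c(msg, "the resnet34 encoder has a fixed 5-scale topology (nBlocks = 5)")
  if (object@baseWidth < 1L) msg <- c(msg, "baseWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmentation network (encoder-decoder with per-block score heads)
#'
#' Holds the configuration, all trainable parameters (a flat named list of
#' arrays), and the non-trainable state (batch-normalization running
#' statistics). Built by [buildNetwork()]; run with [forwardSegment()] or
#' [truncatedForward()].
#'
#' @slot config a [SegNetConfig-class].
#' @slot params flat named list of parameter arrays.
#' @slot state flat named list of batch-norm running means/variances.
#' @export
setClass("SegNet",
  representation(config = "SegNetConfig", params = "list", state = "list")
)

#' Decoder outputs of a forward pass
#'
#' The per-block score maps (pre-activation), the same maps after per-pixel
#' softmax, and the final full-resolution probability map. With the linear
#' merge disabled the final map is identical to the last probability map.
#'
#' @slot scoreMaps list of k pre-activation arrays, block `l` (1-based list
#'   position `l`) of spatial size `inputSize / 2^(k - l)`.
#' @slot probMaps the same maps after per-pixel softmax.
#' @slot final the final probability map, `inputSize x inputSize x 2 [x N]`.
#' @export
setClass("DecoderOutputs",
  representation(scoreMaps = "list", probMaps = "list", final = "array")
)

setValidity("DecoderOutputs", function(object) {
  if (length(object@scoreMaps) != length(object@probMaps))
    return("scoreMaps and probMaps must have equal length")
  TRUE
})

#' Stitched tumor-probability heatmap for one section
#'
#' @slot prob matrix of per-pixel tumor probabilities (rows = y, cols = x),
#'   values in `[0, 1]`.
#' @slot mpp micrometres per pixel of the section grid.
#' @slot sectionId identifier of the section.
#' @export
setClass("Heatmap",
  representation(prob = "matrix", mpp = "numeric", sectionId = "character")
)

setValidity("Heatmap", function(object) {
  if (length(object@mpp) != 1 || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a single positive number")
  pr <- range(object@prob)
  if (pr[1] < -1e-9 || pr[2] > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' Sectionwise classification result
#'
#' Regions that survived the area filter and the resulting Tumor/Normal call.
#' The label is `"Tumor"` iff at least one region was kept.
#'
#' @slot sectionId identifier of the section.
#' @slot label `"Tumor"` or `"Normal"`.
#' @slot regions data.frame with one row per kept region: `region_id`,
#'   `n_pixels`, `area_um2`, `peak_prob`.
#' @export
setClass("SectionResult",
  representation(sectionId = "character", label = "character", regions = "data.frame")
)

setValidity("SectionResult", function(object) {
  if (!object@label %in% c("Tumor", "Normal")) return("label must be Tumor or Normal")
  wantTumor <- nrow(object@regions) > 0
  if (wantTumor != (object@label == "Tumor"))
    return("label must be Tumor iff kept regions are nonempty")
  TRUE
})

#' @describeIn SegNetConfig-class constructor.
#' @param encoder,inputSize,inChannels,nClasses,nBlocks,baseWidth,useLinearMerge,seed
#'   see the corresponding slots.
#' @return a validated `SegNetConfig`.
#' @examples
#' segNetConfig(encoder = "vanilla", inputSize = 64, nBlocks = 4, baseWidth = 8)
#' @export
segNetConfig <- function(encoder = c("vanilla", "resnet34"), inputSize = 512L,
                         inChannels = 3L, nClasses = 2L, nBlocks = 5L,
                         baseWidth = 64L, useLinearMerge = FALSE,
                         seed = NA_integer_) {
  encoder <- match.arg(encoder)
  obj <- new("SegNetConfig",
    encoder = encoder, inputSize = as.integer(inputSize),
    inChannels = as.integer(inChannels), nClasses = as.integer(nClasses),
    nBlocks = as.integer(nBlocks), baseWidth = as.integer(baseWidth),
    useLinearMerge = as.logical(useLinearMerge), seed = as.integer(seed)
  )
  validObject(obj)
  obj
}

#' Read a network configuration from a YAML or JSON block
#'
#' The block may sit at the top level or under a `network:` key and uses the
#' field names of [segNetConfig()] (snake_case accepted: `encoder_kind`,
#' `input_size`, `in_channels`, `n_classes`, `n_decoder_blocks`,
#' `base_width`, `use_linear_merge`, `seed`).
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a [SegNetConfig-class].
#' @export
readNetworkConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$network)) cfg <- cfg$network
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(cfg[[nm]])) return(cfg[[nm]])
    NULL
  }
  args <- list(
    encoder = pick("encoder", "encoder_kind"),
    inputSize = pick("inputSize", "input_size"),
    inChannels = pick("inChannels", "in_channels"),
    nClasses = pick("nClasses", "n_classes"),
    nBlocks = pick("nBlocks", "n_decoder_blocks", "k"),
    baseWidth = pick("baseWidth", "base_width"),
    useLinearMerge = pick("useLinearMerge", "use_linear_merge"),
    seed = pick("seed")
  )
  do.call(segNetConfig, args[!vapply(args, is.null, logical(1))])
}

#' Heatmap constructor
#' @param prob matrix of tumor probabilities (rows = y).
#' @param mpp micrometres per pixel.
#' @param sectionId section identifier.
#' @return a [Heatmap-class].
#' @export
heatmap2d <- function(prob, mpp, sectionId = "section") {
  obj <- new("Heatmap", prob = prob, mpp = as.numeric(mpp),
             sectionId = as.character(sectionId))
  validObject(obj)
  obj
}

setMethod("show", "SegNetConfig", function(object) {
  cat(sprintf("SegNetConfig: %s encoder, input %dx%dx%d, k=%d, baseWidth=%d%s\n",
    object@encoder, object@inputSize, object@inputSize, object@inChannels,
    object@nBlocks, object@baseWidth,
    if (object@useLinearMerge) ", linear merge" else ""))
})

setMethod("show", "SegNet", function(object) {
  cfg <- object@config
  cat(sprintf("SegNet (%s encoder, k=%d, baseWidth=%d): %s parameters\n",
    cfg@encoder, cfg@nBlocks, cfg@baseWidth,
    format(nParameters(object), big.mark = ",")))
  cat(sprintf("  input %dx%dx%d -> %d prob maps (psi0 at %dx%d) -> final %dx%dx%d%s\n",
    cfg@inputSize, cfg@inputSize, cfg@inChannels, cfg@nBlocks,
    cfg@inputSize %/% 2L^(cfg@nBlocks - 1L), cfg@inputSize %/% 2L^(cfg@nBlocks - 1L),
    cfg@inputSize, cfg@inputSize, cfg@nClasses,
    if (cfg@useLinearMerge) " (linear merge)" else ""))
})

setMethod("show", "DecoderOutputs", function(object) {
  sz <- vapply(object@probMaps, function(m) dim(m)[1], numeric(1))
  cat(sprintf("DecoderOutputs: %d blocks (sizes %s), final %s\n",
    length(object@probMaps), paste(sz, collapse = ", "),
    paste(dim(object@final), collapse = "x")))
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap '%s': %dx%d px at %.3g um/px, prob range [%.3f, %.3f]\n",
    object@sectionId, nrow(object@prob), ncol(object@prob), object@mpp,
    min(object@prob), max(object@prob)))
})

setMethod("show", "SectionResult", function(object) {
  cat(sprintf("SectionResult '%s': %s (%d region%s kept%s)\n",
    object@sectionId, object@label, nrow(object@regions),
    if (nrow(object@regions) == 1) "" else "s",
    if (nrow(object@regions)) sprintf(", largest %.0f um2", max(object@regions$area_um2))
    else ""))
})
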