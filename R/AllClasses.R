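#' Network architecture configuration
#'
#' Describes a Bayesian U-Net architecture: the number of pooling levels
#' (`depth`), the channel width at the top level (`baseFilters`, doubled at
#' every level down), the number of pixel classes, the input channel count,
#' where stochasticity is injected (`variant`) and at what rate, and whether
#' batch normalization follows each pair of convolutions.
#'
#' The four variants mirror the benchmarked placements of dropout:
#' \describe{
#'   \item{plain}{no dropout anywhere (batch normalization only).}
#'   \item{standard_dropout}{dropout after every two-convolution block
#'     (encoder, bottleneck and decoder).}
#'   \item{maxpool_dropout}{dropout immediately after each max-pool layer,
#'     i.e. exactly `depth` sites.}
#'   \item{both}{the union of the two placements.}
#' }
#'
#' @slot depth number of max-pool levels (positive integer).
#' @slot baseFilters channels of the first encoder block.
#' @slot nClasses number of pixel classes, at least 2.
#' @slot inChannels image channels (1 for greyscale).
#' @slot variant dropout placement, one of `"plain"`, `"standard_dropout"`,
#'   `"maxpool_dropout"`, `"both"`.
#' @slot dropoutRate per-unit drop probability in (0, 1).
#' @slot useBatchnorm logical; batch normalization after each pair of
#'   consecutive convolutions.
#' @export
setClass("ModelConfig",
  representation(depth = "integer", baseFilters = "integer",
                 nClasses = "integer", inChannels = "integer",
                 variant = "character", dropoutRate = "numeric",
                 useBatchnorm = "logical"),
  prototype(depth = 3L, baseFilters = 16L, nClasses = 2L, inChannels = 1L,
            variant = "maxpool_dropout", dropoutRate = 0.5,
            useBatchnorm = TRUE))

.variants <- c("plain", "standard_dropout", "maxpool_dropout", "both")

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@depth) != 1L || object@depth < 1L)
    msg <- c(msg, "depth must be a positive integer")
  if (length(object@baseFilters) != 1L || object@baseFilters < 1L)
    msg <- c(msg, "baseFilters must be a positive integer")
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    msg <- c(msg, "nClasses must be at least 2")
  if (length(object@inChannels) != 1L || object@inChannels < 1L)
    msg <- c(msg, "inChannels must be a positive integer")
  if (!object@variant %in% .variants)
    msg <- c(msg, paste("variant must be one of:",
                        paste(.variants, collapse = ", ")))
  if (object@dropoutRate <= 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create a network configuration
#'
#' @param depth number of max-pool levels.
#' @param baseFilters channels of the first encoder block (doubled per
#'   level).
#' @param nClasses number of pixel classes c (labels run 0..c-1).
#' @param inChannels input image channels.
#' @param variant dropout placement; see [ModelConfig-class].
#' @param dropoutRate drop probability p of the Bernoulli dropout masks.
#' @param useBatchnorm add batch normalization after each convolution pair.
#' @return a [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig(depth = 2L, baseFilters = 8L, nClasses = 5L)
#' @export
modelConfig <- function(depth = 3L, baseFilters = 16L, nClasses = 2L,
                        inChannels = 1L, variant = "maxpool_dropout",
                        dropoutRate = 0.5, useBatchnorm = TRUE) {
  new("ModelConfig", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters), nClasses = as.integer(nClasses),
      inChannels = as.integer(inChannels), variant = variant,
      dropoutRate = as.numeric(dropoutRate),
      useBatchnorm = as.logical(useBatchnorm))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: depth %d, base filters %d, %d classes, %d input channel(s)\n",
    object@depth, object@baseFilters, object@nClasses, object@inChannels))
  cat(sprintf("  variant: %s (dropout rate %.2f), batchnorm: %s\n",
              object@variant, object@dropoutRate, object@useBatchnorm))
})

#' A built Bayesian U-Net
#'
#' Holds the full parameter set of a built network (convolution kernels and
#' biases, batch-norm scale/offset) together with the non-trained state
#' (batch-norm running statistics). The object is the weights handle passed
#' to prediction, training and the active-learning loop; [saveCheckpoint()]
#' and [loadCheckpoint()] round-trip it through a single checkpoint file.
#'
#' @slot config the [ModelConfig-class] the network was built from.
#' @slot params nested list of numeric arrays (trained parameters).
#' @slot state nested list of batch-norm running means/variances.
#' @export
setClass("UNetModel",
  representation(config = "ModelConfig", params = "list", state = "list"))

setMethod("show", "UNetModel", function(object) {
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("UNetModel: %s variant, depth %d, %s parameters, %d dropout site(s)\n",
              object@config@variant, object@config@depth,
              format(np, big.mark = ","), countStochasticSites(object)))
})

#' Per-pixel class-probability map
#'
#' An H x W x c array of class probabilities; every pixel's c-vector is
#' non-negative and sums to one. This is the unit all acquisition functions
#' consume.
#'
#' @slot values numeric array of dimension (H, W, c).
#' @export
setClass("ProbMap", representation(values = "array"))

setValidity("ProbMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be an (H, W, c) array")
  if (any(v < -1e-9)) return("probabilities must be non-negative")
  s <- rowSums(matrix(v, dim(v)[1] * dim(v)[2], dim(v)[3]))
  if (max(abs(s - 1)) > 1e-6)
    return("per-pixel probabilities must sum to 1 (within 1e-6)")
  TRUE
})

#' @param values an (H, W, c) probability array.
#' @rdname ProbMap-class
#' @export
probMap <- function(values) new("ProbMap", values = values)

setMethod("show", "ProbMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbMap: %d x %d pixels, %d classes\n", d[1], d[2], d[3]))
})

#' Stack of Monte-Carlo forward passes
#'
#' T probability maps from T stochastic forward passes of the same image,
#' stored as an (H, W, c, T) array. The mean over passes is the Monte-Carlo
#' predictive distribution; the spread across passes carries the epistemic
#' uncertainty used by BALD and the predictive-variance map.
#'
#' @slot passes numeric array of dimension (H, W, c, T).
#' @export
setClass("MCStack", representation(passes = "array"))

setValidity("MCStack", function(object) {
  v <- object@passes
  if (length(dim(v)) != 4L) return("passes must be an (H, W, c, T) array")
  if (dim(v)[4] < 1L) return("need at least one pass")
  d <- dim(v)
  s <- vapply(seq_len(d[4]), function(t)
    max(abs(rowSums(matrix(v[, , , t], d[1] * d[2], d[3])) - 1)), numeric(1))
  if (max(s) > 1e-6)
    return("each pass must be per-pixel normalized (within 1e-6)")
  TRUE
})

#' @param passes an (H, W, c, T) array of stacked probability maps.
#' @rdname MCStack-class
#' @export
mcStack <- function(passes) new("MCStack", passes = passes)

setMethod("show", "MCStack", function(object) {
  d <- dim(object@passes)
  cat(sprintf("MCStack: %d passes of %d x %d x %d\n", d[4], d[1], d[2], d[3]))
})

#' Integer segmentation mask
#'
#' An H x W integer label field with values in 0..c-1; label 0 is
#' background by convention.
#'
#' @slot labels integer matrix.
#' @slot nClasses number of classes c.
#' @export
setClass("MaskImage",
  representation(labels = "matrix", nClasses = "integer"))

setValidity("MaskImage", function(object) {
  l <- object@labels
  if (!is.integer(l)) return("labels must be an integer matrix")
  if (any(l < 0L) || any(l >= object@nClasses))
    return(sprintf("labels must lie in 0..%d", object@nClasses - 1L))
  TRUE
})

#' @param labels integer matrix of pixel labels.
#' @param nClasses number of classes c (labels must lie in 0..c-1).
#' @rdname MaskImage-class
#' @export
maskImage <- function(labels, nClasses) {
  storage.mode(labels) <- "integer"
  new("MaskImage", labels = labels, nClasses = as.integer(nClasses))
}

setMethod("show", "MaskImage", function(object) {
  cat(sprintf("MaskImage: %d x %d, %d classes, %.1f%% foreground\n",
              nrow(object@labels), ncol(object@labels), object@nClasses,
              100 * mean(object@labels > 0L)))
})

#' Paired images and masks
#'
#' An ordered collection of images (each an (H, W, C) numeric array with
#' intensities in [0, 1]) and, optionally, their integer segmentation
#' masks, addressed by character ids. Pools handed to the active-learning
#' loop may omit the masks (the oracle holds them).
#'
#' @slot images named list of (H, W, C) arrays.
#' @slot masks named list of integer matrices (may be empty).
#' @slot nClasses number of classes of the masks.
#' @export
setClass("SegDataset",
  representation(images = "list", masks = "list", nClasses = "integer"))

setValidity("SegDataset", function(object) {
  if (is.null(names(object@images)) && length(object@images))
    return("images must be named by id")
  if (length(object@masks)) {
    if (!all(names(object@masks) %in% names(object@images)))
      return("every mask must correspond to an image id")
    bad <- vapply(names(object@masks), function(id) {
      !identical(dim(object@masks[[id]]), dim(object@images[[id]])[1:2])
    }, logical(1))
    if (any(bad))
      return(paste("mask/image shape mismatch for:",
                   paste(names(object@masks)[bad], collapse = ", ")))
    mx <- max(vapply(object@masks, max, 0L), 0L)
    if (mx >= object@nClasses)
      return(sprintf("mask label %d exceeds nClasses - 1 = %d",
                     mx, object@nClasses - 1L))
  }
  TRUE
})

#' @param images named list of (H, W, C) arrays (a bare H x W matrix is
#'   promoted to one channel).
#' @param masks named list of integer matrices, or `NULL`.
#' @param nClasses number of classes.
#' @rdname SegDataset-class
#' @export
segDataset <- function(images, masks = NULL, nClasses) {
  images <- lapply(images, function(im) {
    if (is.matrix(im)) im <- array(im, c(dim(im), 1L))
    im
  })
  if (is.null(names(images)))
    names(images) <- sprintf("img%04d", seq_along(images))
  if (!is.null(masks)) {
    masks <- lapply(masks, function(m) { storage.mode(m) <- "integer"; m })
    if (is.null(names(masks))) names(masks) <- names(images)[seq_along(masks)]
  } else masks <- list()
  new("SegDataset", images = images, masks = masks,
      nClasses = as.integer(nClasses))
}

setMethod("show", "SegDataset", function(object) {
  n <- length(object@images)
  d <- if (n) dim(object@images[[1]]) else c(0, 0, 0)
  cat(sprintf("SegDataset: %d image(s) of %d x %d x %d, %d mask(s), %d classes\n",
              n, d[1], d[2], d[3], length(object@masks), object@nClasses))
})

#' Simulated labelling oracle
#'
#' Holds the ground-truth masks withheld from the learner and releases them
#' on request, counting every label released. `query(ids)` returns the masks
#' for `ids` and increments `queryCount` by `length(ids)`.
#'
#' @field masks named list of integer mask matrices.
#' @field queryCount total number of labels released so far.
#' @export Oracle
#' @exportClass Oracle
Oracle <- setRefClass("Oracle",
  fields = list(masks = "list", queryCount = "integer"),
  methods = list(
    initialize = function(masks = list(), ...) {
      initFields(masks = masks, queryCount = 0L)
      callSuper(...)
    },
    query = function(ids) {
      "Release the ground-truth masks for `ids`, counting each label."
      missing <- setdiff(ids, names(masks))
      if (length(missing))
        stop("oracle has no label for: ", paste(missing, collapse = ", "))
      queryCount <<- queryCount + length(ids)
      masks[ids]
    },
    show = function() {
      cat(sprintf("Oracle: %d held-out masks, %d labels released\n",
                  length(masks), queryCount))
    }))

#' Build an oracle from a fully labelled dataset
#'
#' @param dataset a [SegDataset-class] whose masks become the held-out
#'   ground truth.
#' @return an [Oracle] reference object.
#' @export
makeOracle <- function(dataset) {
  stopifnot(is(dataset, "SegDataset"), length(dataset@masks) > 0)
  Oracle$new(masks = dataset@masks)
}

#' State of an active-learning run
#'
#' Snapshot returned by [runActiveLearning()]: the final iteration index,
#' the disjoint labelled/pool id sets, the trained model, the per-iteration
#' history table and the oracle with its query count.
#'
#' @slot iteration final iteration index t.
#' @slot labeledIds ids whose labels have been acquired.
#' @slot poolIds ids still unlabelled.
#' @slot model the trained [UNetModel-class].
#' @slot history data.frame, one row per active-learning iteration.
#' @slot oracle the [Oracle] used during the run.
#' @export
setClass("ALState",
  representation(iteration = "integer", labeledIds = "character",
                 poolIds = "character", model = "UNetModel",
                 history = "data.frame", oracle = "Oracle"))

setValidity("ALState", function(object) {
  if (length(intersect(object@labeledIds, object@poolIds)))
    return("labeled and pool id sets must be disjoint")
  TRUE
})

setMethod("show", "ALState", function(object) {
  cat(sprintf("ALState: iteration %d, %d labelled, %d in pool, %d labels queried\n",
              object@iteration, length(object@labeledIds),
              length(object@poolIds), object@oracle$queryCount))
  if (nrow(object@history))
    cat(sprintf("  final MC validation dice: %.4f\n",
                object@history$val_dice_mean[nrow(object@history)]))
})

#' Synthetic dataset specification
#'
#' Parameters of the procedural multi-class shape-segmentation generator:
#' image count and size, class count, how many geometric objects (discs,
#' rectangles, rings) to scatter per image, the additive Gaussian intensity
#' noise, whether per-shape intensity jitter ("texture") is applied, and the
#' seed that makes generation fully deterministic.
#'
#' @slot nImages number of image/mask pairs.
#' @slot height,width image size in pixels.
#' @slot nClasses number of classes c including background 0.
#' @slot shapesPerImage inclusive integer range (min, max) of objects.
#' @slot noiseSd standard deviation of additive intensity noise.
#' @slot texture logical; per-shape intensity jitter instead of flat bands.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nImages = "integer", height = "integer", width = "integer",
                 nClasses = "integer", shapesPerImage = "integer",
                 noiseSd = "numeric", texture = "logical", seed = "integer"),
  prototype(nImages = 40L, height = 64L, width = 64L, nClasses = 5L,
            shapesPerImage = c(3L, 6L), noiseSd = 0.05, texture = FALSE,
            seed = 1L))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nImages < 1L) msg <- c(msg, "nImages must be positive")
  if (object@height < 8L || object@width < 8L)
    msg <- c(msg, "images must be at least 8 x 8")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be at least 2")
  if (length(object@shapesPerImage) != 2L ||
      any(object@shapesPerImage < 1L) ||
      object@shapesPerImage[1] > object@shapesPerImage[2])
    msg <- c(msg, "shapesPerImage must be an increasing (min, max) pair")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param nImages,height,width,nClasses,shapesPerImage,noiseSd,texture,seed
#'   see [SyntheticSpec-class]. Defaults give the "hela-like" preset: 5
#'   classes at 64 x 64 with moderate noise.
#' @rdname SyntheticSpec-class
#' @export
syntheticSpec <- function(nImages = 40L, height = 64L, width = 64L,
                          nClasses = 5L, shapesPerImage = c(3L, 6L),
                          noiseSd = 0.05, texture = FALSE, seed = 1L) {
  new("SyntheticSpec", nImages = as.integer(nImages),
      height = as.integer(height), width = as.integer(width),
      nClasses = as.integer(nClasses),
      shapesPerImage = as.integer(shapesPerImage),
      noiseSd = as.numeric(noiseSd), texture = as.logical(texture),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d images, %d x %d, %d classes, %d-%d shapes, noise sd %.3f%s\n",
    object@nImages, object@height, object@width, object@nClasses,
    object@shapesPerImage[1], object@shapesPerImage[2], object@noiseSd,
    if (object@texture) ", textured" else ""))
})

#' Affine augmentation parameters
#'
#' Ranges from which one random affine transform (rotation, shift, isotropic
#' scale, shear) is drawn and applied identically to an image and its mask.
#' Degenerate ranges (0 rotation/shift/shear, scale 1) reproduce the input
#' exactly.
#'
#' @slot rotationDeg rotation range in degrees (min, max).
#' @slot shiftFrac translation range as a fraction of image size.
#' @slot scale isotropic scale factor range.
#' @slot shearDeg shear angle range in degrees.
#' @export
setClass("AugmentParams",
  representation(rotationDeg = "numeric", shiftFrac = "numeric",
                 scale = "numeric", shearDeg = "numeric"),
  prototype(rotationDeg = c(-15, 15), shiftFrac = c(-0.1, 0.1),
            scale = c(0.9, 1.1), shearDeg = c(-8, 8)))

setValidity("AugmentParams", function(object) {
  rng <- function(x) length(x) == 2L && x[1] <= x[2]
  if (!rng(object@rotationDeg) || !rng(object@shiftFrac) ||
      !rng(object@scale) || !rng(object@shearDeg))
    return("all parameters must be (min, max) ranges")
  if (any(object@scale <= 0)) return("scale must be positive")
  TRUE
})

#' @param rotationDeg,shiftFrac,scale,shearDeg see [AugmentParams-class].
#' @rdname AugmentParams-class
#' @export
augmentParams <- function(rotationDeg = c(-15, 15), shiftFrac = c(-0.1, 0.1),
                          scale = c(0.9, 1.1), shearDeg = c(-8, 8)) {
  new("AugmentParams", rotationDeg = as.numeric(rotationDeg),
      shiftFrac = as.numeric(shiftFrac), scale = as.numeric(scale),
      shearDeg = as.numeric(shearDeg))
}
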