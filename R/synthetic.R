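# Procedural multi-class shape-segmentation data and affine augmentation.
#
# Each image scatters randomly placed geometric objects (discs, rectangles,
# rings) over a dark background; the object's class determines its
# intensity band, the mask records the exact rendered geometry, and
# additive Gaussian noise controls difficulty. Later shapes overwrite
# earlier ones (z-order). Everything is a deterministic function of the
# spec's seed.

.shapeRadii <- function(H) max(3L, round(H / 16)):max(4L, round(H / 7))

classIntensity <- function(k, nClasses) {
  ifelse(k == 0L, 0.02, 0.1 + 0.8 * k / (nClasses - 1))
}

# paint one random shape; returns updated mask and the shape's pixel set
paintShape <- function(mask, nClasses, radii) {
  H <- nrow(mask); W <- ncol(mask)
  k <- sample(seq_len(nClasses - 1L), 1L)
  type <- sample(c("disc", "rect", "ring"), 1L)
  r <- sample(radii, 1L)
  ci <- sample((r + 1L):(H - r), 1L)
  cj <- sample((r + 1L):(W - r), 1L)
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (ii - ci)^2 + (jj - cj)^2
  inside <- switch(type,
    disc = d2 <= r^2,
    rect = abs(ii - ci) <= r & abs(jj - cj) <= max(2L, round(0.6 * r)),
    ring = d2 <= r^2 & d2 >= (0.55 * r)^2)
  mask[inside] <- k
  mask
}

#' Generate a synthetic segmentation dataset
#'
#' Renders `nImages` image/mask pairs according to a [SyntheticSpec-class].
#' With `texture = FALSE` and `noiseSd = 0` the pixel intensity is an exact
#' deterministic function of the mask label; `texture = TRUE` adds a
#' per-image, per-class intensity jitter, and Gaussian noise (clipped to [0, 1]) is
#' added at `noiseSd`. Generation is fully determined by `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a labelled [SegDataset-class].
#' @examples
#' ds <- generateDataset(syntheticSpec(nImages = 2L, height = 32L,
#'                                     width = 32L, seed = 7L))
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  c0 <- spec@nClasses
  if (!spec@texture) {
    bands <- round(255 * classIntensity(0:(c0 - 1L), c0))
    if (anyDuplicated(bands))
      stop(sprintf(
        "%d classes exceed the distinguishable flat intensity bands; use texture = TRUE or fewer classes",
        c0))
  }
  withSeed(spec@seed, {
    radii <- .shapeRadii(min(spec@height, spec@width))
    images <- vector("list", spec@nImages)
    masks <- vector("list", spec@nImages)
    for (n in seq_len(spec@nImages)) {
      mask <- matrix(0L, spec@height, spec@width)
      nShapes <- sample(spec@shapesPerImage[1]:spec@shapesPerImage[2], 1L)
      for (s in seq_len(nShapes)) mask <- paintShape(mask, c0, radii)
      img <- matrix(classIntensity(mask, c0), spec@height, spec@width)
      if (spec@texture) {
        jit <- c(1, runif(c0 - 1L, 0.85, 1.15))
        img <- img * matrix(jit[mask + 1L], spec@height, spec@width)
      }
      if (spec@noiseSd > 0)
        img <- img + matrix(rnorm(length(img), sd = spec@noiseSd),
                            spec@height, spec@width)
      img <- pmin(pmax(img, 0), 1)
      images[[n]] <- array(img, c(spec@height, spec@width, 1L))
      masks[[n]] <- mask
    }
    ids <- sprintf("img%04d", seq_len(spec@nImages))
    names(images) <- ids
    names(masks) <- ids
    segDataset(images, masks, nClasses = c0)
  })
}

#' Analytic expected foreground fraction
#'
#' Expected fraction of non-background pixels of images drawn from a
#' [SyntheticSpec-class], computed from the exact rasterized pixel counts
#' of every (shape type, radius) combination under the independent-coverage
#' approximation `E[fg] = E_m[1 - (1 - mu)^m]` with `mu` the mean
#' single-shape area fraction. Overlap between shapes is handled by the
#' approximation; its error is small at the default densities.
#'
#' @param spec a [SyntheticSpec-class].
#' @return expected foreground fraction in (0, 1).
#' @export
expectedForegroundFraction <- function(spec) {
  H <- spec@height; W <- spec@width
  radii <- .shapeRadii(min(H, W))
  areas <- unlist(lapply(radii, function(r) {
    g <- expand.grid(i = -r:r, j = -r:r)
    d2 <- g$i^2 + g$j^2
    c(disc = sum(d2 <= r^2),
      rect = sum(abs(g$i) <= r & abs(g$j) <= max(2L, round(0.6 * r))),
      ring = sum(d2 <= r^2 & d2 >= (0.55 * r)^2))
  }))
  mu <- mean(areas) / (H * W)
  ms <- spec@shapesPerImage[1]:spec@shapesPerImage[2]
  mean(1 - (1 - mu)^ms)
}

#' Apply one random affine transform to an image/mask pair
#'
#' Draws a rotation, shift, isotropic scale and shear from the ranges in
#' `params` and applies the same transform to the image (bilinear
#' interpolation) and the mask (nearest-neighbour, so labels stay
#' integral). Out-of-frame regions are filled with background: intensity 0
#' and label 0. Degenerate ranges reproduce the pair exactly.
#'
#' @param image an (H, W, C) array or H x W matrix.
#' @param mask an integer matrix or [MaskImage-class] of matching size.
#' @param params an [AugmentParams-class].
#' @param seed optional integer seed for the transform draw.
#' @return list with transformed `image` and `mask` (same types as input
#'   shapes: image as (H, W, C) array, mask as integer matrix).
#' @export
augmentPair <- function(image, mask, params = augmentParams(),
                        seed = NULL) {
  stopifnot(is(params, "AugmentParams"))
  wasMatrix <- is.matrix(image)
  if (wasMatrix) image <- array(image, c(dim(image), 1L))
  m <- asMaskMatrix(mask)
  if (!identical(dim(image)[1:2], dim(m)))
    stop("image and mask must have matching spatial dimensions")
  withSeed(seed, {
    theta <- runif(1, params@rotationDeg[1], params@rotationDeg[2]) * pi / 180
    shr <- runif(1, params@shearDeg[1], params@shearDeg[2]) * pi / 180
    sc <- runif(1, params@scale[1], params@scale[2])
    H <- dim(m)[1]; W <- dim(m)[2]
    shift <- c(runif(1, params@shiftFrac[1], params@shiftFrac[2]) * H,
               runif(1, params@shiftFrac[1], params@shiftFrac[2]) * W)
    L <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2) %*%
      matrix(c(1, tan(shr), 0, 1), 2, 2) * sc
    cen <- matrix(c(H / 2, W / 2), 1, 2)
    A <- rbind(L, cen - cen %*% L + shift)
    outImg <- array(0, dim(image))
    for (ch in seq_len(dim(image)[3]))
      outImg[, , ch] <- EBImage::affine(image[, , ch], A,
                                        filter = "bilinear", bg.col = 0)
    outMask <- EBImage::affine(matrix(as.numeric(m), H, W), A,
                               filter = "none", bg.col = 0)
    outMask <- matrix(as.integer(round(outMask)), H, W)
    if (wasMatrix) outImg <- outImg[, , 1]
    list(image = outImg, mask = outMask)
  })
}

#' Augment a whole dataset
#'
#' Adds `times` augmented copies of every image/mask pair to a dataset.
#'
#' @param dataset a labelled [SegDataset-class].
#' @param params an [AugmentParams-class].
#' @param times augmented copies per original pair.
#' @param seed optional integer seed.
#' @return an enlarged [SegDataset-class].
#' @export
augmentDataset <- function(dataset, params = augmentParams(), times = 1L,
                           seed = NULL) {
  stopifnot(is(dataset, "SegDataset"), length(dataset@masks) > 0)
  withSeed(seed, {
    images <- dataset@images
    masks <- dataset@masks
    for (r in seq_len(times)) {
      for (id in names(dataset@masks)) {
        aug <- augmentPair(dataset@images[[id]], dataset@masks[[id]], params)
        nid <- sprintf("%s_aug%d", id, r)
        images[[nid]] <- if (is.matrix(aug$image))
          array(aug$image, c(dim(aug$image), 1L)) else aug$image
        masks[[nid]] <- aug$mask
      }
    }
    segDataset(images, masks, nClasses = dataset@nClasses)
  })
}
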