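# Deterministic and Monte-Carlo predictive inference.

#' Deterministic forward pass
#'
#' Single forward pass with every dropout site disabled and batch
#' normalization in running-statistics mode; repeated calls are
#' bit-identical. This is the "standard prediction" the committee
#' divergences compare against the Monte-Carlo prediction.
#'
#' @param model a [UNetModel-class].
#' @param image an (H, W, C) array (or H x W matrix for one channel) with
#'   H and W divisible by `2^depth`.
#' @return a [ProbMap-class].
#' @export
standardPredict <- function(model, image) {
  stopifnot(is(model, "UNetModel"))
  x <- asBatch1(image)
  r <- unetForward(model@params, model@state, model@config, x, mode = "det")
  probMap(array(r$probs, dim(r$probs)[1:3]))
}

#' Monte-Carlo dropout prediction
#'
#' Runs `T` stochastic forward passes with dropout kept active (a fresh
#' Bernoulli mask per pass) and batch normalization frozen at its running
#' statistics, and averages them into the Monte-Carlo predictive
#' distribution. The individual passes are retained for BALD and the
#' predictive-variance map.
#'
#' @param model a [UNetModel-class].
#' @param image an (H, W, C) array or H x W matrix.
#' @param T number of forward passes (>= 1).
#' @param seed optional integer seed for the dropout masks.
#' @param mcBatchnorm logical; additionally re-estimate batch-norm
#'   statistics from the input on every pass (off by default, dropout is
#'   the stochasticity source).
#' @return list with elements `mean` (a [ProbMap-class]) and `stack`
#'   (an [MCStack-class] of all T passes).
#' @export
mcPredict <- function(model, image, T = 20L, seed = NULL,
                      mcBatchnorm = FALSE) {
  stopifnot(is(model, "UNetModel"))
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be a positive integer")
  x <- asBatch1(image)
  withSeed(seed, {
    if (mcBatchnorm) {
      # statistics are re-estimated per pass, so passes cannot share a batch
      passes <- NULL
      for (t in seq_len(T)) {
        r <- unetForward(model@params, model@state, model@config, x,
                         mode = "mc", mcBatchnorm = TRUE)
        pr <- array(r$probs, dim(r$probs)[1:3])
        if (is.null(passes)) passes <- array(0, c(dim(pr), T))
        passes[, , , t] <- pr
      }
    } else {
      # batch-norm is frozen at running statistics and dropout masks are
      # drawn independently per batch sample, so the T passes run as one
      # batched forward
      d <- dim(x)
      xrep <- array(x, c(d[1], d[2], d[3], T))
      r <- unetForward(model@params, model@state, model@config, xrep,
                       mode = "mc")
      passes <- r$probs
    }
    d3 <- dim(passes)[1:3]
    mean3 <- array(rowMeans(matrix(passes, prod(d3), T)), d3)
    list(mean = probMap(mean3), stack = mcStack(passes))
  })
}

#' Predictive-variance map
#'
#' Per-pixel population variance, across Monte-Carlo passes, of the
#' probability assigned to the pixel's predicted class (the argmax of the
#' mean prediction). This is the scalar uncertainty summary used to shade
#' prediction maps.
#'
#' @param stack an [MCStack-class] with at least two passes.
#' @return an H x W non-negative matrix.
#' @export
predictiveVariance <- function(stack) {
  s <- asStackArray(stack)
  d <- dim(s)
  if (d[4] < 2L) stop("predictive variance needs at least T = 2 passes")
  npix <- d[1] * d[2]
  meanP <- matrix(0, npix, d[3])
  for (t in seq_len(d[4])) meanP <- meanP + matrix(s[, , , t], npix, d[3])
  cls <- max.col(meanP, ties.method = "first")
  sel <- vapply(seq_len(d[4]), function(t)
    matrix(s[, , , t], npix, d[3])[cbind(seq_len(npix), cls)],
    numeric(npix))
  matrix(pmax(rowMeans(sel * sel) - rowMeans(sel)^2, 0), d[1], d[2])
}

#' Most probable class per pixel
#'
#' @param p a [ProbMap-class] or (H, W, c) array.
#' @return a [MaskImage-class] of argmax labels (0-based).
#' @export
probToMask <- function(p) {
  v <- asProbArray(p)
  d <- dim(v)
  cls <- max.col(matrix(v, d[1] * d[2], d[3]), ties.method = "first")
  maskImage(matrix(cls - 1L, d[1], d[2]), d[3])
}
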