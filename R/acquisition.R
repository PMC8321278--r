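# Image-level acquisition functions: per-pixel information measures summed
# over the image give the informativeness score used to rank the unlabelled
# pool. All entropies and divergences are in nats (natural log); rankings
# are invariant to the base. Probabilities are clamped to [1e-12, 1] and
# renormalized before any logarithm so zero components cannot produce
# infinite or undefined scores.

.probEps <- 1e-12

clampNormalize <- function(m) {
  m <- pmax(m, .probEps)
  m / rowSums(m)
}

# (H, W, c) array -> (H*W, c) matrix of pixel distributions
pixmat <- function(p) {
  d <- dim(p)
  matrix(p, nrow = d[1] * d[2], ncol = d[3])
}

entropyRows <- function(m) {
  z <- m * log(m)
  z[m == 0] <- 0
  -rowSums(z)
}

#' Per-pixel Shannon entropy map
#'
#' Entropy `-sum_i p_i log p_i` (nats) of each pixel's class distribution;
#' values lie in [0, log c].
#'
#' @param p a [ProbMap-class] or (H, W, c) array.
#' @return an H x W matrix.
#' @export
pixelEntropyMap <- function(p) {
  v <- asProbArray(p)
  matrix(entropyRows(pixmat(v)), dim(v)[1], dim(v)[2])
}

#' Maximum-entropy acquisition score
#'
#' Image informativeness as the sum of per-pixel predictive entropies.
#' For Bayesian acquisition pass the Monte-Carlo mean prediction.
#'
#' @param p a [ProbMap-class] or (H, W, c) array.
#' @return a non-negative number (nats).
#' @export
scoreEntropy <- function(p) {
  sum(entropyRows(pixmat(asProbArray(p))))
}

#' BALD acquisition score
#'
#' Mutual information between the pixel prediction and the model posterior,
#' computed from the Monte-Carlo stack alone: per pixel, the entropy of the
#' mean distribution minus the mean of the per-pass entropies, summed over
#' pixels. Non-negative by Jensen's inequality; the final sum is floored at
#' zero to absorb floating-point cancellation on near-deterministic stacks.
#'
#' @param stack an [MCStack-class] or (H, W, c, T) array.
#' @return a non-negative number (nats).
#' @export
scoreBald <- function(stack) {
  s <- asStackArray(stack)
  d <- dim(s)
  npix <- d[1] * d[2]
  meanH <- numeric(npix)
  meanP <- matrix(0, npix, d[3])
  for (t in seq_len(d[4])) {
    m <- matrix(s[, , , t], npix, d[3])
    meanH <- meanH + entropyRows(m) / d[4]
    meanP <- meanP + m / d[4]
  }
  max(sum(entropyRows(meanP) - meanH), 0)
}

klRows <- function(p, q) rowSums(p * (log(p) - log(q)))

#' Committee Kullback--Leibler acquisition score
#'
#' Disagreement between the deterministic ("standard") prediction and the
#' Monte-Carlo mean prediction: the sum over pixels of
#' `KL(standard || mcMean)` in nats -- the information lost when the
#' standard prediction is approximated by the Monte-Carlo committee.
#'
#' @param standard,mcMean [ProbMap-class] objects or (H, W, c) arrays of
#'   identical shape.
#' @return a non-negative number (nats).
#' @export
scoreCommitteeKL <- function(standard, mcMean) {
  p <- asProbArray(standard); q <- asProbArray(mcMean)
  if (!identical(dim(p), dim(q)))
    stop("standard and mcMean must have the same shape")
  sum(klRows(clampNormalize(pixmat(p)), clampNormalize(pixmat(q))))
}

#' Committee Jensen--Shannon acquisition score
#'
#' Symmetric, bounded disagreement between the standard and Monte-Carlo
#' predictions: the sum over pixels of
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`; each
#' pixel term lies in [0, log 2].
#'
#' @param standard,mcMean [ProbMap-class] objects or (H, W, c) arrays of
#'   identical shape.
#' @return a non-negative number (nats).
#' @export
scoreCommitteeJSD <- function(standard, mcMean) {
  p <- asProbArray(standard); q <- asProbArray(mcMean)
  if (!identical(dim(p), dim(q)))
    stop("standard and mcMean must have the same shape")
  pm <- clampNormalize(pixmat(p)); qm <- clampNormalize(pixmat(q))
  mm <- (pm + qm) / 2
  sum(klRows(pm, mm) / 2 + klRows(qm, mm) / 2)
}

.acquisitionNames <- c("entropy", "bald", "committee_kl", "committee_jsd")

#' Score one image under a named acquisition function
#'
#' Convenience dispatcher used by the active-learning loop and the `score`
#' command: runs the predictions an acquisition function needs and returns
#' the image score. `entropy` and `bald` use the Monte-Carlo stack;
#' `committee_kl` / `committee_jsd` additionally use the deterministic pass.
#'
#' @param model a [UNetModel-class].
#' @param image an (H, W, C) array.
#' @param acquisition one of `"entropy"`, `"bald"`, `"committee_kl"`,
#'   `"committee_jsd"`.
#' @param T Monte-Carlo passes.
#' @param mcBatchnorm passed to [mcPredict()].
#' @return a single non-negative score (nats).
#' @export
acquireScore <- function(model, image, acquisition, T = 20L,
                         mcBatchnorm = FALSE) {
  acquisition <- match.arg(acquisition, .acquisitionNames)
  mc <- mcPredict(model, image, T = T, mcBatchnorm = mcBatchnorm)
  switch(acquisition,
         entropy = scoreEntropy(mc$mean),
         bald = scoreBald(mc$stack),
         committee_kl = scoreCommitteeKL(standardPredict(model, image),
                                         mc$mean),
         committee_jsd = scoreCommitteeJSD(standardPredict(model, image),
                                           mc$mean))
}

#' Select the top-k images by acquisition score
#'
#' Returns the ids of the `k` highest-scoring images; ties are broken by
#' the smallest image id, and `k` larger than the pool returns the whole
#' pool.
#'
#' @param scores a data.frame with columns `image_id`, `score` and
#'   optionally `function_name` (which must then be constant).
#' @param k number of images to select (>= 1).
#' @return character vector of selected ids, highest score first.
#' @export
selectTopK <- function(scores, k) {
  if (!is.data.frame(scores) || nrow(scores) == 0)
    stop("scores must be a non-empty data.frame")
  stopifnot(all(c("image_id", "score") %in% names(scores)))
  if (k < 1) stop("k must be at least 1")
  if ("function_name" %in% names(scores) &&
      length(unique(scores$function_name)) > 1)
    stop("all scores must come from the same acquisition function")
  ids <- as.character(scores$image_id)
  ord <- order(-scores$score, ids)
  ids[ord][seq_len(min(k, nrow(scores)))]
}
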