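# Segmentation quality metrics.

#' Binary dice coefficient
#'
#' The Sorensen--Dice overlap `2 |a.b| / (|a| + |b|)` between two binary
#' masks, equal to the F1 score of pixel classification. When both masks
#' are empty the coefficient is defined as 1 (perfect agreement on "nothing
#' to segment"); the raw formula is 0/0 there.
#'
#' @param a,b binary (0/1) vectors, matrices or logical arrays of the same
#'   shape.
#' @return a number in [0, 1].
#' @examples
#' diceBinary(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
diceBinary <- function(a, b) {
  if (is.logical(a)) a <- a + 0L
  if (is.logical(b)) b <- b + 0L
  if (length(a) != length(b) ||
      (!is.null(dim(a)) && !is.null(dim(b)) && !identical(dim(a), dim(b))))
    stop("masks must have the same shape")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary (values in {0, 1})")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Multi-class dice coefficient
#'
#' Macro average of the one-vs-rest binary dice over every class present in
#' the ground truth (background label 0 included when present). Classes
#' absent from the truth do not contribute, so trivially predicting an
#' absent class is neither rewarded nor punished.
#'
#' @param pred,truth [MaskImage-class] objects or integer matrices of the
#'   same shape and class count.
#' @param nClasses class count when plain matrices are given.
#' @return a number in [0, 1].
#' @export
diceMulticlass <- function(pred, truth, nClasses = NULL) {
  if (is(pred, "MaskImage") && is(truth, "MaskImage") &&
      pred@nClasses != truth@nClasses)
    stop("pred and truth disagree on the number of classes")
  p <- asMaskMatrix(pred)
  t0 <- asMaskMatrix(truth)
  if (!identical(dim(p), dim(t0)))
    stop("pred and truth must have the same shape")
  classes <- sort(unique(as.vector(t0)))
  mean(vapply(classes, function(k) diceBinary(p == k, t0 == k), numeric(1)))
}
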