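# internal helpers

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# (H, W, C, N) array -> (H*W*N, C) matrix with channels as columns.
chmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

# inverse of chmat for the original dims d = c(H, W, C, N)
unchmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# promote an image to (H, W, C) and then to a single-sample batch
asBatch1 <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot(length(dim(image)) == 3L)
  array(image, c(dim(image), 1L))
}

checkSpatialDims <- function(H, W, depth) {
  div <- 2L^depth
  if (H %% div != 0L)
    stop(sprintf("image height %d is not divisible by 2^depth = %d", H, div))
  if (W %% div != 0L)
    stop(sprintf("image width %d is not divisible by 2^depth = %d", W, div))
}

asMaskMatrix <- function(mask) {
  if (is(mask, "MaskImage")) mask <- maskLabels(mask)
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  mask
}

asProbArray <- function(p) {
  if (is(p, "ProbMap")) p <- probValues(p)
  stopifnot(length(dim(p)) == 3L)
  p
}

asStackArray <- function(s) {
  if (is(s, "MCStack")) s <- stackPasses(s)
  stopifnot(length(dim(s)) == 4L)
  s
}
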