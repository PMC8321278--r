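# Shared fixtures: tiny networks, random probability objects and small
# synthetic datasets, all built in code at test time.

tinyConfig <- function(variant = "maxpool_dropout", depth = 2L,
                       baseFilters = 4L, nClasses = 3L, ...) {
  modelConfig(depth = depth, baseFilters = baseFilters, nClasses = nClasses,
              inChannels = 1L, variant = variant, ...)
}

tinyModel <- function(variant = "maxpool_dropout", seed = 1L, ...) {
  buildUnet(tinyConfig(variant = variant, ...), seed = seed)
}

randomImage <- function(H = 16L, W = 16L, seed = NULL) {
  bunet:::withSeed(seed, matrix(runif(H * W), H, W))
}

# random pixel distributions as an (H, W, c) array
randomProbArray <- function(H = 4L, W = 4L, c = 3L) {
  m <- matrix(rexp(H * W * c), H * W, c)
  m <- m / rowSums(m)
  array(m, c(H, W, c))
}

randomStack <- function(H = 4L, W = 4L, c = 3L, T = 5L) {
  s <- array(0, c(H, W, c, T))
  for (t in seq_len(T)) s[, , , t] <- randomProbArray(H, W, c)
  s
}

# scalar-loop reference implementations of every acquisition score; these
# stay deliberately naive (per-pixel loops, no vectorization) so they are
# an independent oracle for the fast implementations
refEntropy <- function(p) {
  tot <- 0
  for (i in seq_len(dim(p)[1]))
    for (j in seq_len(dim(p)[2])) {
      v <- p[i, j, ]
      for (q in v) if (q > 0) tot <- tot - q * log(q)
    }
  tot
}

refBald <- function(s) {
  d <- dim(s)
  tot <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      pbar <- rep(0, d[3]); hbar <- 0
      for (t in seq_len(d[4])) {
        v <- s[i, j, , t]
        pbar <- pbar + v / d[4]
        for (q in v) if (q > 0) hbar <- hbar - q * log(q) / d[4]
      }
      hm <- 0
      for (q in pbar) if (q > 0) hm <- hm - q * log(q)
      tot <- tot + hm - hbar
    }
  tot
}

refClamp <- function(v, eps = 1e-12) { v <- pmax(v, eps); v / sum(v) }

refKL <- function(p, q) {
  tot <- 0
  for (i in seq_len(dim(p)[1]))
    for (j in seq_len(dim(p)[2])) {
      a <- refClamp(p[i, j, ]); b <- refClamp(q[i, j, ])
      tot <- tot + sum(a * (log(a) - log(b)))
    }
  tot
}

refJSD <- function(p, q) {
  tot <- 0
  for (i in seq_len(dim(p)[1]))
    for (j in seq_len(dim(p)[2])) {
      a <- refClamp(p[i, j, ]); b <- refClamp(q[i, j, ])
      m <- (a + b) / 2
      tot <- tot + sum(a * (log(a) - log(m))) / 2 +
        sum(b * (log(b) - log(m))) / 2
    }
  tot
}

# one-pixel probability array helper
pix <- function(...) array(c(...), c(1, 1, length(c(...))))
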