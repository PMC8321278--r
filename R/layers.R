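# R-side layers: batch normalization, ReLU, inverted dropout, softmax.
# All operate on (H, W, C, N) arrays. Convolution / pooling / transposed
# convolution live in src/conv_ops.cpp.

.bnEps <- 1e-5
.bnMomentum <- 0.1

# Batch normalization over (H, W, N) per channel.
# mode "train": batch statistics, running averages updated.
# mode "det" / "mc": running statistics (frozen); with useBatch = TRUE the
# statistics are re-estimated from the input (Monte-Carlo batch norm).
# Per-channel reductions and broadcasts work on the (H*W, C*N) matrix view
# of an (H, W, C, N) array: a length-H*W*C vector recycles exactly once per
# sample, so per-channel constants expand with rep(..., each = H*W) and no
# transpose is ever taken.
perChannelSum <- function(x, d) {
  s <- .colSums(x, d[1] * d[2], d[3] * d[4])
  if (d[4] > 1L) s <- rowSums(matrix(s, d[3], d[4]))
  s
}

bnForward <- function(gamma, beta, st, x, mode, useBatch = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  M <- hw * d[4]
  if (mode == "train" || useBatch) {
    mu <- perChannelSum(x, d) / M
    va <- perChannelSum(x * x, d) / M - mu * mu
  } else {
    mu <- st$mean
    va <- st$var
  }
  invstd <- 1 / sqrt(va + .bnEps)
  xhat <- (x - rep(mu, each = hw)) * rep(invstd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  if (mode == "train") {
    st$mean <- (1 - .bnMomentum) * st$mean + .bnMomentum * mu
    st$var <- (1 - .bnMomentum) * st$var + .bnMomentum * va
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       state = st)
}

bnBackward <- function(gamma, cache, dy) {
  d <- cache$d
  hw <- d[1] * d[2]
  M <- hw * d[4]
  xhat <- cache$xhat
  dxhat <- dy * rep(gamma, each = hw)
  s1 <- perChannelSum(dxhat, d)
  s2 <- perChannelSum(dxhat * xhat, d)
  dx <- (dxhat - rep(s1 / M, each = hw) - xhat * rep(s2 / M, each = hw)) *
    rep(cache$invstd, each = hw)
  list(dx = dx, dgamma = perChannelSum(dy * xhat, d),
       dbeta = perChannelSum(dy, d))
}

reluForward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

# Inverted dropout: units dropped with probability p, survivors scaled by
# 1/(1-p) so the deterministic (dropout-off) pass needs no rescaling.
dropoutForward <- function(x, p, active) {
  if (!active) return(list(y = x, mask = NULL))
  keep <- array(runif(length(x)) >= p, dim(x))
  list(y = x * keep / (1 - p), mask = keep)
}

dropoutBackward <- function(dy, mask, p) {
  if (is.null(mask)) return(dy)
  dy * mask / (1 - p)
}

# softmax over the channel dimension of (H, W, c, N)
softmaxForward <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  m <- exp(m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))])
  m <- m / rowSums(m)
  unchmat(m, d)
}
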