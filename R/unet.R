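# U-Net construction, forward and backward passes.
#
# Architecture, per encoder level: two 3x3 same-padding convolutions, batch
# normalization after the pair, then a rectifier; 2x2 max pool between
# levels. Channel width doubles per level. The decoder mirrors the encoder
# with 2x2 stride-2 transposed convolutions, concatenating the encoder
# feature map of matching resolution (skip connection) before each block.
# A 1x1 convolution and a per-pixel softmax produce the class probabilities.
#
# Dropout sites depend on the variant: "maxpool_dropout" puts one Bernoulli
# dropout immediately after each max pool (depth sites), "standard_dropout"
# one after each two-convolution block (2*depth + 1 sites), "both" the
# union, "plain" none.

encChannels <- function(cfg) cfg@baseFilters * 2L^(seq_len(cfg@depth) - 1L)

# Names of the dropout sites the variant wires into the network; the
# forward pass and countStochasticSites() both derive from this.
dropoutSiteNames <- function(cfg) {
  d <- cfg@depth
  std <- c(sprintf("enc%d.block", seq_len(d)), "bottleneck.block",
           sprintf("dec%d.block", seq_len(d)))
  mp <- sprintf("pool%d", seq_len(d))
  switch(cfg@variant,
         plain = character(),
         standard_dropout = std,
         maxpool_dropout = mp,
         both = c(std, mp))
}

heInit <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

initBlock <- function(cin, cout, useBn) {
  b <- list(W1 = heInit(3L, cin, cout), b1 = numeric(cout),
            W2 = heInit(3L, cout, cout), b2 = numeric(cout))
  if (useBn) {
    b$gamma <- rep(1, cout)
    b$beta <- numeric(cout)
  }
  b
}

initBnState <- function(cout) list(mean = numeric(cout), var = rep(1, cout))

#' Build a Bayesian U-Net
#'
#' Instantiates the network described by a [ModelConfig-class]: parameters
#' are He-initialized convolution kernels (seeded when `seed` is given),
#' batch-norm scales/offsets at 1/0 and running statistics at 0/1.
#'
#' @param config a [ModelConfig-class].
#' @param seed optional integer; makes initialization reproducible without
#'   touching the caller's RNG state.
#' @return a [UNetModel-class] weights handle.
#' @examples
#' model <- buildUnet(modelConfig(depth = 2L, baseFilters = 4L,
#'                                nClasses = 3L), seed = 1)
#' countStochasticSites(model)
#' @export
buildUnet <- function(config, seed = NULL) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  withSeed(seed, {
    d <- config@depth
    fs <- encChannels(config)
    fb <- config@baseFilters * 2L^d
    bn <- config@useBatchnorm
    params <- list(enc = vector("list", d), dec = vector("list", d))
    state <- list(enc = vector("list", d), dec = vector("list", d))
    cin <- config@inChannels
    for (i in seq_len(d)) {
      params$enc[[i]] <- initBlock(cin, fs[i], bn)
      state$enc[[i]] <- initBnState(fs[i])
      cin <- fs[i]
    }
    params$bottleneck <- initBlock(fs[d], fb, bn)
    state$bottleneck <- initBnState(fb)
    below <- fb
    for (i in rev(seq_len(d))) {
      params$dec[[i]] <- c(
        list(upW = array(rnorm(4 * below * fs[i], sd = sqrt(2 / below)),
                         c(2L, 2L, below, fs[i])),
             upb = numeric(fs[i])),
        initBlock(2L * fs[i], fs[i], bn))
      state$dec[[i]] <- initBnState(fs[i])
      below <- fs[i]
    }
    params$head <- list(W = heInit(1L, fs[1], config@nClasses),
                        b = numeric(config@nClasses))
    new("UNetModel", config = config, params = params, state = state)
  })
}

#' Count the dropout sites of a built network
#'
#' @param model a [UNetModel-class].
#' @return integer number of dropout layers wired into the network (0 for
#'   the plain variant, `depth` for maxpool dropout).
#' @export
countStochasticSites <- function(model) {
  stopifnot(is(model, "UNetModel"))
  length(dropoutSiteNames(model@config))
}

blockForward <- function(bp, bst, x, mode, useBn, mcBatchnorm) {
  c1 <- cpp_conv_fw(x, bp$W1, bp$b1)
  c2 <- cpp_conv_fw(c1, bp$W2, bp$b2)
  if (useBn) {
    bnr <- bnForward(bp$gamma, bp$beta, bst, c2, mode,
                     useBatch = mcBatchnorm && mode == "mc")
    z <- bnr$y; bst <- bnr$state; bnc <- bnr$cache
  } else {
    z <- c2; bnc <- NULL
  }
  rr <- reluForward(z)
  list(y = rr$y, state = bst,
       cache = list(x = x, c1 = c1, bn = bnc, mask = rr$mask))
}

blockBackward <- function(bp, cache, dy, useBn) {
  dz <- dy
  dz[!cache$mask] <- 0
  g <- list()
  if (useBn) {
    bb <- bnBackward(bp$gamma, cache$bn, dz)
    dc2 <- bb$dx; g$gamma <- bb$dgamma; g$beta <- bb$dbeta
  } else dc2 <- dz
  r2 <- cpp_conv_bw(cache$c1, bp$W2, dc2)
  r1 <- cpp_conv_bw(cache$x, bp$W1, r2$dx)
  g$W1 <- r1$dw; g$b1 <- r1$db; g$W2 <- r2$dw; g$b2 <- r2$db
  list(dx = r1$dx, grads = g)
}

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  z <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  z[, , seq_len(da[3]), ] <- a
  z[, , da[3] + seq_len(db[3]), ] <- b
  z
}

# Full forward pass.
# mode: "train" (batch-norm batch statistics + dropout), "det" (running
# statistics, no dropout), "mc" (running statistics, dropout active).
# Returns probs (H, W, c, N), the layer caches needed by unetBackward, and
# the (possibly updated) batch-norm state.
unetForward <- function(params, state, cfg, x, mode, mcBatchnorm = FALSE) {
  d <- cfg@depth
  p <- cfg@dropoutRate
  useBn <- cfg@useBatchnorm
  sites <- dropoutSiteNames(cfg)
  active <- mode %in% c("train", "mc")
  dims <- dim(x)
  checkSpatialDims(dims[1], dims[2], d)
  if (dims[3] != cfg@inChannels)
    stop(sprintf("network expects %d input channel(s), got %d",
                 cfg@inChannels, dims[3]))
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  h <- x
  for (i in seq_len(d)) {
    bf <- blockForward(params$enc[[i]], state$enc[[i]], h, mode, useBn,
                       mcBatchnorm)
    state$enc[[i]] <- bf$state
    sdr <- dropoutForward(bf$y, p,
                          active && sprintf("enc%d.block", i) %in% sites)
    mp <- cpp_maxpool_fw(sdr$y)
    mdr <- dropoutForward(mp$y, p, active && sprintf("pool%d", i) %in% sites)
    cache$enc[[i]] <- list(block = bf$cache, sdropMask = sdr$mask,
                           poolIdx = mp$idx, inH = dim(sdr$y)[1],
                           inW = dim(sdr$y)[2], skip = sdr$y,
                           mdropMask = mdr$mask)
    h <- mdr$y
  }
  bf <- blockForward(params$bottleneck, state$bottleneck, h, mode, useBn,
                     mcBatchnorm)
  state$bottleneck <- bf$state
  bdr <- dropoutForward(bf$y, p, active && "bottleneck.block" %in% sites)
  cache$bottleneck <- list(block = bf$cache, dropMask = bdr$mask)
  h <- bdr$y
  for (i in rev(seq_len(d))) {
    dp <- params$dec[[i]]
    u <- cpp_upconv_fw(h, dp$upW, dp$upb)
    z <- concatChannels(u, cache$enc[[i]]$skip)
    bf <- blockForward(dp, state$dec[[i]], z, mode, useBn, mcBatchnorm)
    state$dec[[i]] <- bf$state
    ddr <- dropoutForward(bf$y, p,
                          active && sprintf("dec%d.block", i) %in% sites)
    cache$dec[[i]] <- list(upIn = h, block = bf$cache,
                           splitAt = dim(u)[3], dropMask = ddr$mask)
    h <- ddr$y
  }
  cache$headIn <- h
  logits <- cpp_conv_fw(h, params$head$W, params$head$b)
  list(probs = softmaxForward(logits), cache = cache, state = state)
}

# Backward pass from the gradient of the loss w.r.t. the logits.
# Returns gradients in the same nested shape as params.
unetBackward <- function(params, cfg, cache, dlogits) {
  d <- cfg@depth
  p <- cfg@dropoutRate
  useBn <- cfg@useBatchnorm
  g <- list(enc = vector("list", d), dec = vector("list", d))
  hr <- cpp_conv_bw(cache$headIn, params$head$W, dlogits)
  g$head <- list(W = hr$dw, b = hr$db)
  dh <- hr$dx
  dskip <- vector("list", d)
  for (i in seq_len(d)) {
    cc <- cache$dec[[i]]
    dh <- dropoutBackward(dh, cc$dropMask, p)
    bb <- blockBackward(params$dec[[i]], cc$block, dh, useBn)
    sp <- cc$splitAt
    nch <- dim(bb$dx)[3]
    du <- bb$dx[, , seq_len(sp), , drop = FALSE]
    dskip[[i]] <- bb$dx[, , (sp + 1L):nch, , drop = FALSE]
    ur <- cpp_upconv_bw(cc$upIn, params$dec[[i]]$upW, du)
    g$dec[[i]] <- c(list(upW = ur$dw, upb = ur$db), bb$grads)
    dh <- ur$dx
  }
  dh <- dropoutBackward(dh, cache$bottleneck$dropMask, p)
  bb <- blockBackward(params$bottleneck, cache$bottleneck$block, dh, useBn)
  g$bottleneck <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(d))) {
    cc <- cache$enc[[i]]
    dh <- dropoutBackward(dh, cc$mdropMask, p)
    da <- cpp_maxpool_bw(dh, cc$poolIdx, cc$inH, cc$inW) + dskip[[i]]
    da <- dropoutBackward(da, cc$sdropMask, p)
    bb <- blockBackward(params$enc[[i]], cc$block, da, useBn)
    g$enc[[i]] <- bb$grads
    dh <- bb$dx
  }
  g
}
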