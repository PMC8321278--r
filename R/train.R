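# Training: categorical cross-entropy, Adam, early stopping on the
# validation dice coefficient.

# mean cross-entropy over all pixels of a batch; masks (H, W, N) 0-based
ceLossGrad <- function(probs, masks) {
  d <- dim(probs)
  npx <- d[1] * d[2] * d[4]
  pm <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = d[3])
  lab <- as.vector(masks) + 1L
  idx <- cbind(seq_len(npx), lab)
  loss <- -mean(log(pmax(pm[idx], 1e-12)))
  dm <- pm
  dm[idx] <- dm[idx] - 1
  list(loss = loss, dlogits = unchmat(dm / npx, d))
}

adamInitLike <- function(p) rapply(p, function(a) a * 0, how = "replace")

# one Adam step; walks params/grads/moments by name
adamStep <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        r <- step(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
    }
    list(p = p, m = m, v = v)
  }
  step(p, g, m, v)
}

stackImages <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

stackMasks <- function(masks) {
  d <- dim(masks[[1]])
  y <- array(0L, c(d, length(masks)))
  for (i in seq_along(masks)) y[, , i] <- masks[[i]]
  y
}

#' Mean validation dice of the deterministic prediction
#'
#' @param model a [UNetModel-class].
#' @param validation a labelled [SegDataset-class].
#' @return mean multi-class dice over the validation images.
#' @export
validationDice <- function(model, validation) {
  ids <- names(validation@masks)
  mean(vapply(ids, function(id) {
    pm <- standardPredict(model, validation@images[[id]])
    diceMulticlass(maskLabels(probToMask(pm)), validation@masks[[id]])
  }, numeric(1)))
}

#' Monte-Carlo validation dice
#'
#' Dice of the argmax of the Monte-Carlo mean prediction against ground
#' truth, per validation image.
#'
#' @param model a [UNetModel-class].
#' @param validation a labelled [SegDataset-class].
#' @param T Monte-Carlo passes.
#' @param mcBatchnorm passed to [mcPredict()].
#' @return numeric vector of per-image dice values (named by id).
#' @export
mcValidationDice <- function(model, validation, T = 20L,
                             mcBatchnorm = FALSE) {
  ids <- names(validation@masks)
  vapply(ids, function(id) {
    mc <- mcPredict(model, validation@images[[id]], T = T,
                    mcBatchnorm = mcBatchnorm)
    diceMulticlass(maskLabels(probToMask(mc$mean)), validation@masks[[id]])
  }, numeric(1))
}

#' Train with early stopping on validation dice
#'
#' Minimizes the categorical cross-entropy with Adam, starting from the
#' given weights (warm start -- no re-initialization). After every epoch
#' the deterministic validation dice is computed; training stops when it
#' has not improved for `patience` epochs or when `maxEpochs` is reached,
#' and the weights snapshot with the best validation dice is returned.
#' `maxEpochs = 0` returns the input model untouched.
#'
#' @param model a [UNetModel-class] (the warm-start weights).
#' @param labeled a labelled [SegDataset-class]; the training set.
#' @param validation a labelled [SegDataset-class]; fixed held-out set.
#' @param maxEpochs epoch budget (default 60, the range within which
#'   average generalization sets in for this architecture).
#' @param patience epochs without validation-dice improvement before
#'   stopping (default 5).
#' @param lr Adam learning rate (default 0.001).
#' @param batchSize mini-batch size (default 4).
#' @param seed optional seed for shuffling and dropout masks.
#' @return list with `model` (best snapshot), `epochsRun`, and `history`
#'   (per-epoch data.frame with loss and validation dice).
#' @export
trainWithEarlyStopping <- function(model, labeled, validation,
                                   maxEpochs = 60L, patience = 5L,
                                   lr = 0.001, batchSize = 4L, seed = NULL) {
  stopifnot(is(model, "UNetModel"), is(labeled, "SegDataset"),
            is(validation, "SegDataset"))
  if (length(labeled@masks) == 0) stop("labelled set must not be empty")
  if (length(validation@masks) == 0) stop("validation set must not be empty")
  maxEpochs <- as.integer(maxEpochs)
  if (maxEpochs < 0L) stop("maxEpochs must be non-negative")
  if (maxEpochs == 0L)
    return(list(model = model, epochsRun = 0L,
                history = data.frame(epoch = integer(), loss = numeric(),
                                     val_dice = numeric())))
  withSeed(seed, {
    ids <- names(labeled@masks)
    cfg <- model@config
    params <- model@params
    state <- model@state
    mAdam <- adamInitLike(params)
    vAdam <- adamInitLike(params)
    bestDice <- -Inf
    bestParams <- params
    bestState <- state
    sinceBest <- 0L
    tAdam <- 0L
    hist <- vector("list", maxEpochs)
    epochsRun <- 0L
    for (ep in seq_len(maxEpochs)) {
      epochsRun <- ep
      ord <- sample(ids)
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = batchSize)) {
        bids <- ord[start:min(start + batchSize - 1L, length(ord))]
        x <- stackImages(labeled@images[bids])
        y <- stackMasks(labeled@masks[bids])
        fw <- unetForward(params, state, cfg, x, mode = "train")
        state <- fw$state
        lg <- ceLossGrad(fw$probs, y)
        grads <- unetBackward(params, cfg, fw$cache, lg$dlogits)
        tAdam <- tAdam + 1L
        upd <- adamStep(params, grads, mAdam, vAdam, lr, tAdam)
        params <- upd$p; mAdam <- upd$m; vAdam <- upd$v
        epochLoss <- epochLoss + lg$loss
        nb <- nb + 1L
      }
      cur <- new("UNetModel", config = cfg, params = params, state = state)
      vd <- validationDice(cur, validation)
      hist[[ep]] <- data.frame(epoch = ep, loss = epochLoss / nb,
                               val_dice = vd)
      if (vd > bestDice + 1e-9) {
        bestDice <- vd
        bestParams <- params
        bestState <- state
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= patience) break
      }
    }
    list(model = new("UNetModel", config = cfg, params = bestParams,
                     state = bestState),
         epochsRun = epochsRun,
         history = do.call(rbind, hist[seq_len(epochsRun)]))
  })
}
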