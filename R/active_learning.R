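# The pool-based active-learning loop: score the unlabelled pool, query the
# oracle for the top-k most informative images, grow the labelled set,
# warm-start retrain with early stopping, repeat.

#' Run the active-learning loop
#'
#' Starts from `initialSize` randomly drawn pool images whose labels are
#' requested from the oracle, trains the network, then iterates: draw a
#' scoring subset of the pool, score every image with the chosen
#' acquisition function (deterministic and Monte-Carlo predictions as
#' needed), select the top `k`, query the oracle for their masks, move them
#' from the pool to the labelled set and retrain from the current weights
#' (warm start) with early stopping on validation dice. The loop ends after
#' `iterations` rounds or when the pool is exhausted.
#'
#' The whole run is a deterministic function of `seed`: identical seeds
#' reproduce the selection sequence and history exactly.
#'
#' @param config a [ModelConfig-class] for the network.
#' @param pool a [SegDataset-class] of unlabelled images (masks, if
#'   present, are ignored -- the oracle owns the labels).
#' @param oracle an [Oracle] holding the ground-truth masks.
#' @param validation a fixed, labelled [SegDataset-class] used for early
#'   stopping and the reported Monte-Carlo validation dice.
#' @param acquisition `"entropy"`, `"bald"`, `"committee_kl"`,
#'   `"committee_jsd"`, or `"random"` (the control baseline).
#' @param k images queried per iteration.
#' @param iterations number of acquisition rounds.
#' @param initialSize size of the random initial labelled set.
#' @param subsampleSize optional size of the random pool subset scored each
#'   round (`NULL` scores the entire pool).
#' @param T Monte-Carlo passes for scoring and the reported dice.
#' @param seed integer seed governing every random draw of the run.
#' @param maxEpochs,patience,lr,batchSize training controls passed to
#'   [trainWithEarlyStopping()].
#' @param mcBatchnorm passed to [mcPredict()].
#' @param verbose print one line per iteration.
#' @return an [ALState-class]; its `history` has one row per iteration with
#'   columns iteration, n_labeled, acquisition, val_dice_mean, val_dice_sd,
#'   epochs_run.
#' @export
runActiveLearning <- function(config, pool, oracle, validation,
                              acquisition = "committee_jsd", k = 2L,
                              iterations = 15L, initialSize = 2L,
                              subsampleSize = NULL, T = 20L, seed = 1L,
                              maxEpochs = 60L, patience = 5L, lr = 0.001,
                              batchSize = 4L, mcBatchnorm = FALSE,
                              verbose = FALSE) {
  stopifnot(is(config, "ModelConfig"), is(pool, "SegDataset"),
            is(oracle, "Oracle"), is(validation, "SegDataset"))
  acquisition <- match.arg(acquisition, c(.acquisitionNames, "random"))
  initialSize <- as.integer(initialSize)
  if (initialSize < 1L) stop("initialSize must be at least 1")
  allIds <- datasetIds(pool)
  if (length(allIds) <= initialSize)
    stop("pool must be larger than the initial labelled set")
  withSeed(seed, {
    poolIds <- allIds
    init <- sample(poolIds, initialSize)
    poolIds <- setdiff(poolIds, init)
    labeledIds <- init
    labeled <- segDataset(pool@images[init], oracle$query(init),
                          nClasses = validation@nClasses)
    model <- buildUnet(config)
    tr <- trainWithEarlyStopping(model, labeled, validation,
                                 maxEpochs = maxEpochs, patience = patience,
                                 lr = lr, batchSize = batchSize)
    model <- tr$model
    hist <- vector("list", iterations)
    t0 <- 0L
    for (t in seq_len(iterations)) {
      if (length(poolIds) == 0L) break
      t0 <- t
      sub <- if (is.null(subsampleSize)) poolIds
             else sample(poolIds, min(subsampleSize, length(poolIds)))
      chosen <- if (acquisition == "random") {
        sort(sample(sub, min(k, length(sub))))
      } else {
        sc <- data.frame(
          image_id = sub,
          score = vapply(sub, function(id)
            acquireScore(model, pool@images[[id]], acquisition, T = T,
                         mcBatchnorm = mcBatchnorm), numeric(1)),
          function_name = acquisition)
        selectTopK(sc, k)
      }
      newMasks <- oracle$query(chosen)
      labeled <- segDataset(c(labeled@images, pool@images[chosen]),
                            c(labeled@masks, newMasks),
                            nClasses = validation@nClasses)
      labeledIds <- c(labeledIds, chosen)
      poolIds <- setdiff(poolIds, chosen)
      tr <- trainWithEarlyStopping(model, labeled, validation,
                                   maxEpochs = maxEpochs,
                                   patience = patience, lr = lr,
                                   batchSize = batchSize)
      model <- tr$model
      vd <- mcValidationDice(model, validation, T = T,
                             mcBatchnorm = mcBatchnorm)
      hist[[t]] <- data.frame(
        iteration = t, n_labeled = length(labeledIds),
        acquisition = acquisition, val_dice_mean = mean(vd),
        val_dice_sd = if (length(vd) > 1) sd(vd) else 0,
        epochs_run = tr$epochsRun)
      if (verbose)
        message(sprintf(
          "iteration %d: %d labelled, MC validation dice %.4f (sd %.4f), %d epoch(s)",
          t, length(labeledIds), mean(vd), sd(vd), tr$epochsRun))
    }
    new("ALState", iteration = t0, labeledIds = labeledIds,
        poolIds = poolIds, model = model,
        history = do.call(rbind, hist[seq_len(t0)]), oracle = oracle)
  })
}

#' Benchmark the four stochasticity variants
#'
#' For every combination of architecture variant, training-set size and
#' repeat: draw a training subset, train for a fixed epoch budget, and
#' record the deterministic validation dice, the Monte-Carlo validation
#' dice and the mean predictive variance. Results come back as a tidy
#' table.
#'
#' @param variants list of [ModelConfig-class] objects.
#' @param trainingSizes integer vector of labelled-set sizes.
#' @param repeats replicate runs per (variant, size).
#' @param epochs training epoch budget per fit (no early stopping).
#' @param T Monte-Carlo passes.
#' @param train a labelled [SegDataset-class] to subsample from.
#' @param validation a labelled [SegDataset-class].
#' @param seed integer seed.
#' @param lr,batchSize training parameters.
#' @return data.frame with columns variant, size, repeat, metric, value;
#'   metrics are `val_dice`, `mc_val_dice`, `pred_variance`.
#' @export
runVariantBenchmark <- function(variants, trainingSizes, repeats = 2L,
                                epochs = 10L, T = 10L, train, validation,
                                seed = 1L, lr = 0.001, batchSize = 4L) {
  stopifnot(is(train, "SegDataset"), is(validation, "SegDataset"),
            all(trainingSizes <= length(train@masks)))
  withSeed(seed, {
    rows <- list()
    for (vi in seq_along(variants)) {
      cfg <- variants[[vi]]
      vname <- cfg@variant
      for (size in trainingSizes) {
        for (r in seq_len(repeats)) {
          ids <- sample(names(train@masks), size)
          sub <- subsetDataset(train, ids)
          model <- buildUnet(cfg)
          tr <- trainWithEarlyStopping(model, sub, validation,
                                       maxEpochs = epochs,
                                       patience = epochs, lr = lr,
                                       batchSize = batchSize)
          vd <- validationDice(tr$model, validation)
          if (countStochasticSites(tr$model) > 0L) {
            mcd <- mean(mcValidationDice(tr$model, validation, T = T))
            pv <- mean(vapply(names(validation@masks), function(id) {
              mc <- mcPredict(tr$model, validation@images[[id]], T = T)
              mean(predictiveVariance(mc$stack))
            }, numeric(1)))
          } else {
            mcd <- vd
            pv <- 0
          }
          rows[[length(rows) + 1L]] <- data.frame(
            variant = vname, size = size, repeat_ = r,
            metric = c("val_dice", "mc_val_dice", "pred_variance"),
            value = c(vd, mcd, pv))
        }
      }
    }
    out <- do.call(rbind, rows)
    names(out)[names(out) == "repeat_"] <- "repeat"
    rownames(out) <- NULL
    out
  })
}
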