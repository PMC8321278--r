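makeSplit <- function(n = 6L, nTrain = 4L, H = 16L, seed = 31L,
                      nClasses = 3L) {
  ds <- generateDataset(syntheticSpec(nImages = n, height = H, width = H,
                                      nClasses = nClasses, noiseSd = 0.02,
                                      seed = seed))
  ids <- datasetIds(ds)
  list(train = subsetDataset(ds, ids[seq_len(nTrain)]),
       val = subsetDataset(ds, ids[(nTrain + 1L):n]))
}

test_that("the epoch budget is honoured", {
  sp <- makeSplit()
  m <- tinyModel(depth = 1L, baseFilters = 4L, seed = 1L)
  tr <- trainWithEarlyStopping(m, sp$train, sp$val, maxEpochs = 1L,
                               patience = 5L, seed = 2L)
  expect_identical(tr$epochsRun, 1L)
  tr3 <- trainWithEarlyStopping(m, sp$train, sp$val, maxEpochs = 3L,
                                patience = 1L, seed = 2L)
  expect_lte(tr3$epochsRun, 3L)
})

test_that("maxEpochs = 0 returns the warm-start weights untouched", {
  sp <- makeSplit()
  m <- tinyModel(depth = 1L, baseFilters = 4L, seed = 5L)
  tr <- trainWithEarlyStopping(m, sp$train, sp$val, maxEpochs = 0L)
  expect_identical(tr$model@params, m@params)
  expect_identical(tr$epochsRun, 0L)
})

test_that("training reduces the loss and is seed-reproducible", {
  sp <- makeSplit(H = 16L, nClasses = 2L, seed = 8L)
  m <- tinyModel(depth = 1L, baseFilters = 4L, nClasses = 2L, seed = 3L)
  tr <- trainWithEarlyStopping(m, sp$train, sp$val, maxEpochs = 8L,
                               patience = 8L, seed = 4L)
  expect_lt(tr$history$loss[nrow(tr$history)], tr$history$loss[1])
  tr2 <- trainWithEarlyStopping(m, sp$train, sp$val, maxEpochs = 8L,
                                patience = 8L, seed = 4L)
  expect_identical(tr$model@params, tr2$model@params)
  expect_identical(tr$history, tr2$history)
})

test_that("empty inputs are rejected", {
  sp <- makeSplit()
  m <- tinyModel(depth = 1L, baseFilters = 4L, seed = 1L)
  empty <- segDataset(list(), NULL, nClasses = 3L)
  expect_error(trainWithEarlyStopping(m, empty, sp$val), "labelled")
  expect_error(trainWithEarlyStopping(m, sp$train, empty), "validation")
})

test_that("variant benchmark produces tidy bookkeeping", {
  sp <- makeSplit(n = 5L, nTrain = 3L, H = 16L)
  variants <- list(tinyConfig("plain", depth = 1L, baseFilters = 2L),
                   tinyConfig("maxpool_dropout", depth = 1L,
                              baseFilters = 2L))
  res <- runVariantBenchmark(variants, trainingSizes = c(2L, 3L),
                             repeats = 2L, epochs = 1L, T = 2L,
                             train = sp$train, validation = sp$val,
                             seed = 6L)
  expect_identical(nrow(res), 2L * 2L * 2L * 3L)  # variants x sizes x reps x metrics
  for (v in c("plain", "maxpool_dropout"))
    for (s in c(2L, 3L))
      expect_identical(sum(res$variant == v & res$size == s &
                             res$metric == "mc_val_dice"), 2L)
  pv <- res$value[res$variant == "plain" & res$metric == "pred_variance"]
  expect_true(all(pv == 0))
})
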