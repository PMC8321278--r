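tinyALSetup <- function(nPool = 8L, nVal = 2L, H = 16L, seed = 41L) {
  ds <- generateDataset(syntheticSpec(nImages = nPool + nVal, height = H,
                                      width = H, nClasses = 3L,
                                      noiseSd = 0.02, seed = seed))
  ids <- datasetIds(ds)
  pool <- subsetDataset(ds, ids[seq_len(nPool)])
  list(cfg = tinyConfig(depth = 1L, baseFilters = 4L, nClasses = 3L),
       pool = pool, oracle = makeOracle(pool),
       val = subsetDataset(ds, ids[(nPool + 1L):(nPool + nVal)]))
}

runTiny <- function(s, ...) {
  runActiveLearning(s$cfg, s$pool, s$oracle, s$val, k = 2L,
                    iterations = 3L, initialSize = 2L, T = 2L, seed = 17L,
                    maxEpochs = 1L, patience = 1L, ...)
}

test_that("the loop keeps exact label bookkeeping", {
  s <- tinyALSetup()
  st <- runTiny(s, acquisition = "committee_jsd")
  expect_identical(st@iteration, 3L)
  expect_length(labeledIds(st), 2L + 3L * 2L)  # initial + iterations * k
  expect_identical(s$oracle$queryCount, 8L)
  expect_length(intersect(labeledIds(st), poolIds(st)), 0L)
  expect_length(union(labeledIds(st), poolIds(st)), 8L)
  h <- alHistory(st)
  expect_identical(nrow(h), 3L)
  expect_identical(h$n_labeled, c(4L, 6L, 8L))
})

test_that("the loop is deterministic under a fixed seed", {
  s1 <- tinyALSetup()
  s2 <- tinyALSetup()
  a <- runTiny(s1, acquisition = "bald")
  b <- runTiny(s2, acquisition = "bald")
  expect_identical(labeledIds(a), labeledIds(b))
  expect_identical(alHistory(a), alHistory(b))
  expect_identical(alModel(a)@params, alModel(b)@params)
})

test_that("pool exhaustion stops the loop cleanly", {
  s <- tinyALSetup(nPool = 5L)
  st <- runActiveLearning(s$cfg, s$pool, s$oracle, s$val,
                          acquisition = "entropy", k = 2L,
                          iterations = 10L, initialSize = 2L, T = 2L,
                          seed = 3L, maxEpochs = 1L, patience = 1L)
  expect_length(poolIds(st), 0L)
  expect_length(labeledIds(st), 5L)
  expect_identical(s$oracle$queryCount, 5L)
  expect_lte(st@iteration, 10L)
})

test_that("invalid arguments are rejected up front", {
  s <- tinyALSetup(nPool = 4L)
  expect_error(runTiny(s, acquisition = "newest_fad"))
  expect_error(runActiveLearning(s$cfg, s$pool, s$oracle, s$val,
                                 initialSize = 4L, seed = 1L),
               "larger")
  badOracle <- Oracle$new(masks = datasetMasks(s$pool)[1:2])
  expect_error(
    runActiveLearning(s$cfg, s$pool, badOracle, s$val, k = 2L,
                      iterations = 1L, initialSize = 3L, T = 2L, seed = 1L,
                      maxEpochs = 1L),
    "no label")
})

test_that("warm start carries weights across iterations", {
  s <- tinyALSetup(nPool = 6L)
  st <- runTiny(s, acquisition = "random")
  labeled <- segDataset(s$pool@images[labeledIds(st)],
                        s$oracle$masks[labeledIds(st)], nClasses = 3L)
  tr <- trainWithEarlyStopping(alModel(st), labeled, s$val, maxEpochs = 0L)
  expect_identical(tr$model@params, alModel(st)@params)
})

test_that("the oracle counts every label exactly once", {
  s <- tinyALSetup(nPool = 6L)
  expect_identical(s$oracle$queryCount, 0L)
  m <- s$oracle$query(c("img0001", "img0002"))
  expect_identical(s$oracle$queryCount, 2L)
  expect_named(m, c("img0001", "img0002"))
  expect_error(s$oracle$query("nope"), "no label")
  expect_identical(s$oracle$queryCount, 2L)
})
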