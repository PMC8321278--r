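test_that("generation is a deterministic function of the seed", {
  spec <- syntheticSpec(nImages = 4L, height = 32L, width = 32L, seed = 7L)
  a <- generateDataset(spec)
  b <- generateDataset(spec)
  expect_identical(datasetImages(a), datasetImages(b))
  expect_identical(datasetMasks(a), datasetMasks(b))
  expect_length(datasetImages(a), 4L)
})

test_that("masks use only valid labels and images stay in [0, 1]", {
  ds <- generateDataset(syntheticSpec(nImages = 6L, height = 32L,
                                      width = 32L, nClasses = 4L,
                                      noiseSd = 0.2, seed = 3L))
  for (m in datasetMasks(ds)) {
    expect_true(is.integer(m))
    expect_true(all(m >= 0L & m < 4L))
  }
  for (im in datasetImages(ds)) expect_true(all(im >= 0 & im <= 1))
})

test_that("intensity is a deterministic function of the label when clean", {
  ds <- generateDataset(syntheticSpec(nImages = 3L, height = 32L,
                                      width = 32L, noiseSd = 0,
                                      texture = FALSE, seed = 9L))
  for (id in datasetIds(ds)) {
    img <- datasetImages(ds)[[id]][, , 1]
    msk <- datasetMasks(ds)[[id]]
    for (k in sort(unique(as.vector(msk)))) {
      vals <- img[msk == k]
      expect_equal(max(vals), min(vals))
    }
  }
  # distinct classes map to distinct bands
  img1 <- datasetImages(ds)[[1]][, , 1]
  msk1 <- datasetMasks(ds)[[1]]
  bands <- tapply(as.vector(img1), as.vector(msk1), unique)
  expect_false(any(duplicated(unlist(bands))))
})

test_that("foreground fraction tracks the analytic expectation", {
  spec <- syntheticSpec(nImages = 100L, height = 64L, width = 64L,
                        noiseSd = 0, seed = 13L)
  ds <- generateDataset(spec)
  fg <- mean(vapply(datasetMasks(ds), function(m) mean(m > 0L), numeric(1)))
  expected <- expectedForegroundFraction(spec)
  expect_gt(fg, expected * 0.8)
  expect_lt(fg, expected * 1.2)
})

test_that("too many flat intensity bands is rejected", {
  expect_error(generateDataset(syntheticSpec(nImages = 1L, nClasses = 250L,
                                             texture = FALSE)),
               "distinguishable")
})

test_that("identity augmentation reproduces the pair exactly", {
  ds <- generateDataset(syntheticSpec(nImages = 1L, height = 32L,
                                      width = 32L, seed = 21L))
  img <- datasetImages(ds)[[1]]
  msk <- datasetMasks(ds)[[1]]
  idp <- augmentParams(rotationDeg = c(0, 0), shiftFrac = c(0, 0),
                       scale = c(1, 1), shearDeg = c(0, 0))
  out <- augmentPair(img, msk, idp, seed = 1L)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_identical(out$mask, msk)
})

test_that("augmented masks keep old labels plus background", {
  ds <- generateDataset(syntheticSpec(nImages = 2L, height = 32L,
                                      width = 32L, nClasses = 5L,
                                      seed = 22L))
  for (id in datasetIds(ds)) {
    msk <- datasetMasks(ds)[[id]]
    out <- augmentPair(datasetImages(ds)[[id]], msk, augmentParams(),
                       seed = 33L)
    expect_true(all(out$mask %in% c(0L, unique(as.vector(msk)))))
  }
})

test_that("two 180-degree rotations restore the interior", {
  ds <- generateDataset(syntheticSpec(nImages = 1L, height = 32L,
                                      width = 32L, noiseSd = 0, seed = 5L))
  img <- datasetImages(ds)[[1]]
  msk <- datasetMasks(ds)[[1]]
  rot <- augmentParams(rotationDeg = c(180, 180), shiftFrac = c(0, 0),
                       scale = c(1, 1), shearDeg = c(0, 0))
  once <- augmentPair(img, msk, rot, seed = 1L)
  twice <- augmentPair(once$image, once$mask, rot, seed = 1L)
  inner <- 5:28
  expect_equal(twice$image[inner, inner, 1], img[inner, inner, 1],
               tolerance = 1e-8)
  expect_identical(twice$mask[inner, inner], msk[inner, inner])
})

test_that("dataset augmentation grows the dataset consistently", {
  ds <- generateDataset(syntheticSpec(nImages = 3L, height = 32L,
                                      width = 32L, seed = 2L))
  aug <- augmentDataset(ds, times = 2L, seed = 4L)
  expect_length(datasetImages(aug), 9L)
  expect_length(datasetMasks(aug), 9L)
  expect_identical(nClasses(aug), nClasses(ds))
})
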