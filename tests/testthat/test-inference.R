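test_that("deterministic prediction is reproducible and dropout-free", {
  m <- tinyModel("both", seed = 2L)
  img <- randomImage(16L, 16L, seed = 3L)
  p1 <- probValues(standardPredict(m, img))
  p2 <- probValues(standardPredict(m, img))
  expect_identical(p1, p2)
})

test_that("Monte-Carlo prediction is seeded and degenerates correctly", {
  img <- randomImage(16L, 16L, seed = 6L)
  m <- tinyModel("maxpool_dropout", seed = 2L)
  a <- mcPredict(m, img, T = 4L, seed = 11L)
  b <- mcPredict(m, img, T = 4L, seed = 11L)
  expect_identical(stackPasses(a$stack), stackPasses(b$stack))
  # T = 1: the mean is the single stochastic pass
  one <- mcPredict(m, img, T = 1L, seed = 5L)
  expect_equal(probValues(one$mean), stackPasses(one$stack)[, , , 1])
  # mean of normalized passes is normalized
  sums <- rowSums(matrix(probValues(a$mean), 256, 3))
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_error(mcPredict(m, img, T = 0L), "positive")
})

test_that("a plain network has no stochasticity at inference", {
  m <- tinyModel("plain", seed = 4L)
  img <- randomImage(16L, 16L, seed = 7L)
  mc <- mcPredict(m, img, T = 3L, seed = 1L)
  s <- stackPasses(mc$stack)
  expect_identical(s[, , , 1], s[, , , 2])
  expect_identical(s[, , , 1], s[, , , 3])
  # standard prediction equals the MC mean exactly
  expect_equal(probValues(standardPredict(m, img)), probValues(mc$mean))
  expect_true(all(predictiveVariance(mc$stack) == 0))
})

test_that("predictive variance matches the direct variance formula", {
  # two passes whose top-class probability is 0.4 and 0.6 at every pixel:
  # population variance 0.01
  s <- array(0, c(2, 2, 2, 2))
  s[, , 1, 1] <- 0.6; s[, , 2, 1] <- 0.4
  s[, , 1, 2] <- 0.4; s[, , 2, 2] <- 0.6
  pv <- predictiveVariance(mcStack(s))
  expect_equal(pv, matrix(0.01, 2, 2))
  expect_true(all(predictiveVariance(randomStack(T = 6L)) >= 0))
  expect_error(predictiveVariance(mcStack(randomStack(T = 1L))), "T = 2")
})

test_that("the MC running average stabilizes as T grows", {
  # Law-of-large-numbers check on one Monte-Carlo chain: the running mean
  # after 256 passes is already within 0.01 (max-abs) of the mean over all
  # 512. On an untrained network a single dropped channel can swing a
  # softmax output by order 1, so the per-value deviation scales like
  # sqrt(p)/sqrt(T); the light dropout rate keeps that scale (and its
  # extreme over all 16*16*3 values) well inside the band.
  m <- tinyModel("maxpool_dropout", depth = 1L, baseFilters = 8L,
                 dropoutRate = 0.002, seed = 9L)
  img <- randomImage(16L, 16L, seed = 10L)
  s <- stackPasses(mcPredict(m, img, T = 512L, seed = 41L)$stack)
  m512 <- apply(s, 1:3, mean)
  m256 <- apply(s[, , , 1:256], 1:3, mean)
  expect_lt(max(abs(m256 - m512)), 0.01)
})
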