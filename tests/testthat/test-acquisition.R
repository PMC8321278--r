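test_that("pixel entropy matches closed forms and its bound", {
  expect_equal(pixelEntropyMap(pix(0.5, 0.5))[1, 1], log(2),
               tolerance = 1e-12)
  expect_equal(pixelEntropyMap(pix(1, 0, 0))[1, 1], 0, tolerance = 1e-12)
  expect_equal(pixelEntropyMap(pix(0.9, 0.1))[1, 1],
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    p <- randomProbArray(c = 4L)
    e <- pixelEntropyMap(p)
    expect_true(all(e >= -1e-12 & e <= log(4) + 1e-12))
  }
})

test_that("image entropy sums pixel entropies", {
  p <- array(0.5, c(2, 2, 2))
  expect_equal(scoreEntropy(p), 4 * log(2), tolerance = 1e-12)
  onehot <- array(rep(c(1, 0), each = 4), c(2, 2, 2))
  expect_equal(scoreEntropy(onehot), 0, tolerance = 1e-12)
  q <- randomProbArray(8L, 8L, 5L)
  expect_lte(scoreEntropy(q), 64 * log(5))
})

test_that("BALD matches its closed forms and bounds", {
  s <- array(0, c(1, 1, 2, 2))
  s[1, 1, , 1] <- c(1, 0)
  s[1, 1, , 2] <- c(0, 1)
  expect_equal(scoreBald(s), log(2), tolerance = 1e-12)
  same <- randomStack(T = 4L)
  for (t in 1:4) same[, , , t] <- same[, , , 1]
  expect_equal(scoreBald(same), 0, tolerance = 1e-10)
  set.seed(2)
  for (i in 1:50) {
    st <- randomStack(T = 5L)
    b <- scoreBald(st)
    mean3 <- array(apply(st, c(1, 2, 3), mean), dim(st)[1:3])
    expect_gte(b, 0)
    expect_lte(b, scoreEntropy(mean3) + 1e-10)
  }
})

test_that("committee divergences match closed forms, bounds and symmetry", {
  p <- randomProbArray()
  expect_equal(scoreCommitteeKL(p, p), 0, tolerance = 1e-9)
  expect_equal(scoreCommitteeJSD(p, p), 0, tolerance = 1e-9)
  expect_equal(scoreCommitteeKL(pix(1, 0), pix(0.5, 0.5)), log(2),
               tolerance = 1e-9)
  expect_equal(scoreCommitteeJSD(pix(1, 0), pix(0, 1)), log(2),
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:200) {
    a <- randomProbArray(); b <- randomProbArray()
    expect_gte(scoreCommitteeKL(a, b), 0)
    j <- scoreCommitteeJSD(a, b)
    expect_gte(j, 0)
    expect_lte(j, 16 * log(2) + 1e-9)  # 4x4 pixels, log 2 each
    expect_equal(j, scoreCommitteeJSD(b, a), tolerance = 1e-12)
  }
  expect_error(scoreCommitteeKL(randomProbArray(c = 3L),
                                randomProbArray(c = 4L)), "shape")
})

test_that("vectorized scores agree with the scalar-loop oracle", {
  set.seed(4)
  for (i in 1:10) {
    st <- randomStack(6L, 5L, 3L, T = 4L)
    mean3 <- array(apply(st, c(1, 2, 3), mean), dim(st)[1:3])
    std <- randomProbArray(6L, 5L, 3L)
    relEq <- function(a, b) expect_lt(abs(a - b) / max(abs(b), 1e-12), 1e-10)
    relEq(scoreEntropy(mean3), refEntropy(mean3))
    relEq(scoreBald(st), refBald(st))
    relEq(scoreCommitteeKL(std, mean3), refKL(std, mean3))
    relEq(scoreCommitteeJSD(std, mean3), refJSD(std, mean3))
  }
})

test_that("scores are invariant to a common class permutation", {
  set.seed(5)
  st <- randomStack(4L, 4L, 4L, T = 5L)
  mean3 <- array(apply(st, c(1, 2, 3), mean), dim(st)[1:3])
  std <- randomProbArray(4L, 4L, 4L)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(scoreEntropy(mean3[, , perm]), scoreEntropy(mean3))
  expect_equal(scoreBald(st[, , perm, ]), scoreBald(st))
  expect_equal(scoreCommitteeKL(std[, , perm], mean3[, , perm]),
               scoreCommitteeKL(std, mean3))
  expect_equal(scoreCommitteeJSD(std[, , perm], mean3[, , perm]),
               scoreCommitteeJSD(std, mean3))
})

test_that("top-k selection ranks, breaks ties by id, and clamps", {
  sc <- data.frame(image_id = c("id0", "id1", "id2"), score = c(3, 1, 2))
  expect_identical(selectTopK(sc, 1), "id0")
  expect_identical(selectTopK(sc, 2), c("id0", "id2"))
  tied <- data.frame(image_id = c("b", "a", "c"), score = c(1, 1, 1))
  expect_identical(selectTopK(tied, 2), c("a", "b"))
  expect_identical(sort(selectTopK(sc, 10)), c("id0", "id1", "id2"))
  expect_error(selectTopK(sc[0, ], 1), "non-empty")
  mixed <- data.frame(image_id = c("a", "b"), score = c(1, 2),
                      function_name = c("entropy", "bald"))
  expect_error(selectTopK(mixed, 1), "same acquisition")
})
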