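test_that("dropout sites follow the variant wiring", {
  counts <- vapply(c(plain = "plain", std = "standard_dropout",
                     mp = "maxpool_dropout", both = "both"),
                   function(v) countStochasticSites(tinyModel(v, depth = 3L)),
                   integer(1))
  expect_identical(counts[["plain"]], 0L)
  expect_identical(counts[["mp"]], 3L)         # one per max pool
  expect_identical(counts[["std"]], 7L)        # one per conv block
  expect_identical(counts[["both"]], counts[["std"]] + counts[["mp"]])
  expect_lt(counts[["plain"]], counts[["mp"]])
  expect_lte(counts[["mp"]], counts[["both"]])
  expect_identical(countStochasticSites(tinyModel("maxpool_dropout",
                                                  depth = 4L)), 4L)
})

test_that("output is a per-pixel distribution for every variant", {
  img <- randomImage(16L, 16L, seed = 4L)
  for (v in c("plain", "standard_dropout", "maxpool_dropout", "both")) {
    p <- probValues(standardPredict(tinyModel(v), img))
    sums <- rowSums(matrix(p, 256, 3))
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("incompatible input shapes raise errors naming the dimension", {
  m <- tinyModel()  # depth 2: needs multiples of 4
  expect_error(standardPredict(m, matrix(0.5, 18, 16)), "height 18")
  expect_error(standardPredict(m, matrix(0.5, 16, 30)), "width 30")
  expect_error(standardPredict(m, array(0.5, c(16, 16, 2))),
               "input channel")
})

test_that("a constant input is shift-equivariant away from borders", {
  # The network is equivariant to translations by the pooling period
  # (2^depth), so a constant input yields an output constant on each
  # parity sub-lattice of the interior: the 2x2 stride-2 up-convolution
  # assigns different kernel taps to the two parities, which makes exact
  # global constancy impossible by construction. depth-1 receptive field
  # stays ~10 px, so the centre of a 64 x 64 image never sees the border.
  m <- tinyModel("plain", depth = 1L)
  p <- probValues(standardPredict(m, matrix(0.7, 64, 64)))
  for (k in 1:3)
    for (pi in 0:1)
      for (pj in 0:1) {
        sub <- p[seq(25 + pi, 40, by = 2), seq(25 + pj, 40, by = 2), k]
        expect_lt(max(sub) - min(sub), 1e-8)
      }
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("bunet")
  cfg <- tinyConfig("both", depth = 2L, baseFilters = 2L,
                    dropoutRate = 0.4)
  model <- buildUnet(cfg, seed = 3L)
  set.seed(5)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(sample(0:2, 128, replace = TRUE), c(8, 8, 2))
  lossOf <- function(params) {
    set.seed(99)  # freeze the dropout masks across evaluations
    fw <- ns$unetForward(params, model@state, cfg, x, mode = "train")
    ns$ceLossGrad(fw$probs, y)$loss
  }
  set.seed(99)
  fw <- ns$unetForward(model@params, model@state, cfg, x, mode = "train")
  grads <- ns$unetBackward(model@params, cfg, fw$cache,
                           ns$ceLossGrad(fw$probs, y)$dlogits)
  leaves <- list(list("enc", 1L, "W1"), list("enc", 2L, "gamma"),
                 list("bottleneck", "W2"), list("dec", 1L, "upW"),
                 list("dec", 2L, "b2"), list("head", "W"))
  h <- 1e-5
  set.seed(7)
  for (path in leaves) {
    leaf <- model@params
    for (k in path) leaf <- leaf[[k]]
    i <- sample(length(leaf), 1L)
    bump <- function(delta) {
      p <- model@params
      setRec <- function(node, depth) {
        if (depth > length(path)) { node[i] <- node[i] + delta; return(node) }
        node[[path[[depth]]]] <- setRec(node[[path[[depth]]]], depth + 1)
        node
      }
      setRec(p, 1)
    }
    num <- (lossOf(bump(h)) - lossOf(bump(-h))) / (2 * h)
    ana <- grads
    for (k in path) ana <- ana[[k]]
    ana <- ana[i]
    expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-7), 1e-5)
  }
})

test_that("checkpoint round trip reproduces forward passes bit-identically", {
  m <- tinyModel("maxpool_dropout", seed = 8L)
  img <- randomImage(16L, 16L, seed = 9L)
  ref <- probValues(standardPredict(m, img))
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(probValues(standardPredict(m2, img)), ref)
})
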