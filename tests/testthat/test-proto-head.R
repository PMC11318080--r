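# Independent brute-force oracle for the weighted prototype: explicit loops,
# no shared code with the implementation.
protoOracle <- function(S, eps = 1e-8) {
  K <- nrow(S)
  distance <- numeric(K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      distance[i] <- distance[i] + sqrt(sum((S[i, ] - S[j, ])^2))
    }
  }
  if (all(distance < eps)) {
    a <- rep(1 / K, K)
  } else {
    w <- 1 / (distance + eps)
    a <- w / sum(w)
  }
  p <- numeric(ncol(S))
  for (i in seq_len(K)) p <- p + a[i] * S[i, ]
  list(prototype = p, weights = a, distances = distance)
}

test_that("weighted prototypes match the brute-force oracle", {
  # the worked K=3 case: (0,0), (1,0), (0,1)
  S <- rbind(c(0, 0), c(1, 0), c(0, 1))
  pr <- computePrototype(S)
  expect_equal(pr$distances, c(2, 1 + sqrt(2), 1 + sqrt(2)),
               tolerance = 1e-12)
  o <- protoOracle(S)
  expect_equal(pr$prototype, o$prototype, tolerance = 1e-9)
  expect_equal(pr$weights, o$weights, tolerance = 1e-9)
  # random support sets across shot counts
  for (rep in 1:40) {
    withr::with_seed(rep, {
      K <- sample(c(1L, 2L, 5L, 10L), 1L)
      S <- matrix(rnorm(K * 100), K, 100)
    })
    pr <- computePrototype(S)
    o <- protoOracle(S)
    expect_lt(max(abs(pr$prototype - o$prototype)), 1e-9)
    expect_lt(max(abs(pr$weights - o$weights)), 1e-9)
    expect_equal(sum(pr$weights), 1, tolerance = 1e-9)
    expect_true(all(pr$weights >= 0))
  }
})

test_that("degenerate supports fall back to uniform weights", {
  v <- c(1, 2, 3)
  pr <- computePrototype(rbind(v, v))
  expect_equal(pr$prototype, v)
  expect_equal(pr$weights, c(0.5, 0.5))
  one <- computePrototype(matrix(v, 1L))
  expect_equal(one$prototype, v)
  expect_equal(one$weights, 1)
  expect_error(computePrototype(matrix(numeric(), 0L, 3L)), "empty support")
})

test_that("prototypes are invariant to support order", {
  withr::with_seed(31, S <- matrix(rnorm(8 * 20), 8L, 20L))
  p1 <- computePrototype(S)$prototype
  for (rep in 1:5) {
    perm <- withr::with_seed(rep, sample(8L))
    expect_equal(computePrototype(S[perm, ])$prototype, p1,
                 tolerance = 1e-12)
  }
})

test_that("moving a support point away strictly decreases its weight", {
  withr::with_seed(17, S <- matrix(rnorm(5 * 10), 5L, 10L))
  w0 <- computePrototype(S)$weights[1L]
  S2 <- S
  S2[1L, ] <- S2[1L, ] + 3 * sign(S2[1L, ] - colMeans(S[-1L, ]))
  w1 <- computePrototype(S2)$weights[1L]
  expect_lt(w1, w0)
})

test_that("uniform-weight variant reduces to the arithmetic mean exactly", {
  withr::with_seed(23, S <- matrix(rnorm(6 * 12), 6L, 12L))
  pr <- computePrototype(S, weighted = FALSE)
  expect_identical(pr$weights, rep(1 / 6, 6L))
  expect_equal(pr$prototype, colMeans(S), tolerance = 1e-15)
})

test_that("query classification is a two-way softmax over similarities", {
  protos <- list(pos = computePrototype(matrix(c(1, 0), 1L)),
                 neg = computePrototype(matrix(c(0, 1), 1L)))
  # symmetric similarities give exactly 0.5
  expect_equal(classifyQuery(c(1, 1), protos, "dot"), 0.5)
  # query aligned with the positive prototype
  expect_gt(classifyQuery(c(1, 0), protos, "dot"), 0.5)
  # fixed numeric triple against hand-computed softmax
  z <- c(0.3, -0.2, 0.5)
  pp <- c(1, 0.5, -1)
  pn <- c(-0.4, 0.2, 0.1)
  protos2 <- list(pos = computePrototype(matrix(pp, 1L)),
                  neg = computePrototype(matrix(pn, 1L)))
  sp <- sum(z * pp); sn <- sum(z * pn)
  expect_equal(classifyQuery(z, protos2, "dot"),
               exp(sp) / (exp(sp) + exp(sn)), tolerance = 1e-12)
  # neg-L2 similarity prefers the nearer prototype
  expect_gt(classifyQuery(pp, protos2, "neg_L2"), 0.5)
  expect_lt(classifyQuery(pn, protos2, "neg_L2"), 0.5)
  expect_error(classifyQuery(c(1, 2), protos2), "dimension")
})

test_that("episode loss matches its closed forms and clips", {
  expect_equal(episodeLoss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  expect_equal(episodeLoss(c(0.9, 0.2), c(1, 0)),
               (-log(0.9) - log(0.8)) / 2, tolerance = 1e-12)
  # exact predictions hit the clip floor, not 0 or Inf
  expect_equal(episodeLoss(c(1, 0), c(1, 0)), -log(1 - 1e-7),
               tolerance = 1e-12)
  expect_true(is.finite(episodeLoss(c(0, 1), c(1, 0))))
  expect_error(episodeLoss(c(0.5), c(1, 0)), "length")
})

test_that("the loss is minimized where predictions equal labels", {
  grid <- seq(0.01, 0.99, by = 0.01)
  lossAt <- vapply(grid, function(p) episodeLoss(p, 1), numeric(1))
  expect_equal(grid[which.min(lossAt)], 0.99)
  lossAt0 <- vapply(grid, function(p) episodeLoss(p, 0), numeric(1))
  expect_equal(grid[which.min(lossAt0)], 0.01)
})

test_that("threshold rule: 0.5 predicts positive", {
  expect_identical(predictLabels(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
})
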