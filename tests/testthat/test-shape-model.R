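test_that("standardization yields zero mean, unit sd and applies signs", {
  st <- standardizePhenotypes(cbind(a = c(1, 2, 3)))
  expect_equal(as.vector(st$Z), c(-1, 0, 1))
  expect_equal(unname(st$scale), 1) # sample sd of 1:3

  set.seed(4)
  X <- matrix(rnorm(200, mean = 5, sd = 3), ncol = 4)
  colnames(X) <- letters[1:4]
  st2 <- standardizePhenotypes(X)
  expect_lt(max(abs(colMeans(st2$Z))), 1e-9)
  expect_lt(max(abs(apply(st2$Z, 2, sd) - 1)), 1e-9)

  # negative indicator: standardization of the negated column
  stn <- standardizePhenotypes(X, signs = c(-1, 1, 1, 1))
  expect_equal(stn$Z[, 1], standardizePhenotypes(-X[, 1, drop = FALSE])$Z[, 1],
               ignore_attr = TRUE)

  Xz <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(standardizePhenotypes(Xz), "b")
})

test_that("correlation PCA satisfies the trace identity", {
  Z <- standardizePhenotypes(cbind(a = 1:10, b = 2 * (1:10)))$Z
  pc <- correlationPCA(Z)
  expect_equal(pc$values, c(2, 0), tolerance = 1e-9)

  set.seed(5)
  Z2 <- standardizePhenotypes(matrix(rnorm(7 * 500), ncol = 7))$Z
  pc2 <- correlationPCA(Z2)
  expect_equal(sum(pc2$values), 7, tolerance = 1e-6)
  expect_false(is.unsorted(rev(pc2$values)))
})

test_that("component selection hits the threshold boundary cases", {
  expect_equal(chooseComponents(c(2, 0)), 1L)
  expect_equal(chooseComponents(rep(1, 5)), 4L) # 4/5 = 0.8 exactly
  expect_equal(chooseComponents(c(5, 3, 2, 1), threshold = 1), 4L)
  expect_equal(chooseComponents(c(10, 1), threshold = 0.5), 1L)
})

test_that("near-duplicate traits get near-equal weights summing to one", {
  set.seed(20)
  base <- rnorm(1000)
  X <- sapply(1:11, function(i) base + rnorm(1000, sd = 0.05))
  colnames(X) <- sprintf("t%02d", 1:11)
  m <- buildShapeModel(X)
  w <- modelWeights(m)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_lt(max(abs(w - 1 / 11)), 0.02)
  expect_equal(modelComponents(m), 1L)
  ev <- modelEigenvalues(m)
  expect_gte(sum(ev[seq_len(modelComponents(m))]) / sum(ev), 0.8)
})

test_that("a dominant trait receives the largest weight", {
  set.seed(21)
  n <- 400
  driver <- rnorm(n)
  X <- cbind(strong = driver + rnorm(n, sd = 0.1),
             echo1 = driver + rnorm(n, sd = 0.4),
             echo2 = driver + rnorm(n, sd = 0.6),
             noise1 = rnorm(n), noise2 = rnorm(n))
  m <- buildShapeModel(X)
  expect_equal(names(which.max(modelWeights(m))), "strong")
})

test_that("weights are invariant to column scaling and equivariant to permutation", {
  set.seed(22)
  X <- matrix(rnorm(600), ncol = 6) %*% (diag(6) + 0.4)
  colnames(X) <- letters[1:6]
  w1 <- modelWeights(buildShapeModel(X))
  Xs <- X
  Xs[, 3] <- 10 * Xs[, 3]
  w2 <- modelWeights(buildShapeModel(Xs))
  expect_lt(max(abs(w1 - w2)), 1e-9)

  perm <- c(4, 1, 6, 2, 5, 3)
  w3 <- modelWeights(buildShapeModel(X[, perm]))
  expect_equal(w3, w1[perm], tolerance = 1e-12)
})

test_that("weights of any built model are non-negative and sum to one", {
  set.seed(23)
  for (rep in 1:5) {
    p <- sample(3:12, 1)
    A <- matrix(rnorm(p * p), p)
    X <- matrix(rnorm(200 * p), ncol = p) %*% A
    m <- buildShapeModel(X)
    expect_true(all(m@weights >= 0))
    expect_equal(sum(m@weights), 1, tolerance = 1e-9)
    ev <- modelEigenvalues(m)
    expect_gte(sum(ev[seq_len(modelComponents(m))]) / sum(ev),
               0.8 - 1e-12)
  }
})

test_that("composite scores are centred, normalized and linear", {
  set.seed(24)
  X <- matrix(rnorm(500), ncol = 5)
  colnames(X) <- letters[1:5]
  m <- buildShapeModel(X)
  mu <- setNames(m@center * m@signs, m@columns)
  expect_equal(compositeScore(m, mu), 0, tolerance = 1e-12)
  oneUp <- setNames((m@center + m@scale) * m@signs, m@columns)
  expect_equal(compositeScore(m, oneUp), 1, tolerance = 1e-12)

  r1 <- X[1, ]; r2 <- X[2, ]
  al <- 0.3
  expect_equal(compositeScore(m, al * r1 + (1 - al) * r2),
               al * compositeScore(m, r1) + (1 - al) * compositeScore(m, r2),
               tolerance = 1e-12)
  expect_error(compositeScore(m, c(a = 1)), "missing trait")
})

test_that("shape models survive a JSON round-trip", {
  set.seed(25)
  X <- matrix(rnorm(400), ncol = 4)
  colnames(X) <- c("V", "S", "L", "W")
  m <- buildShapeModel(X)
  f <- tempfile(fileext = ".json")
  writeShapeModel(m, f)
  back <- readShapeModel(f)
  expect_equal(modelWeights(back), modelWeights(m), tolerance = 1e-12)
  expect_equal(back@m, m@m)
  expect_equal(back@loadings, m@loadings, tolerance = 1e-12)
  expect_equal(compositeScore(back, X[3, ]), compositeScore(m, X[3, ]),
               tolerance = 1e-12)
})

test_that("underdetermined matrices warn", {
  set.seed(26)
  X <- matrix(rnorm(5 * 11), ncol = 11)
  expect_warning(buildShapeModel(X), "unstable")
})
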