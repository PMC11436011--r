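test_that("RANSAC keeps exactly the off-plane points of a known construction", {
  set.seed(3)
  tab <- planeCloud(side = 30, spacing = 0.4)
  outliers <- matrix(runif(300, -10, 10), ncol = 3)
  outliers[, 2] <- runif(100, 3, 12) # all well above the plane
  scene <- pointCloud(rbind(cloudPoints(tab), outliers))
  kept <- removeTableRansac(scene)
  expect_equal(nPoints(kept), 100L)
  expect_equal(cloudMetadata(kept)$keptIndices, nPoints(tab) + 1:100)
  pl <- cloudMetadata(kept)$plane
  expect_equal(abs(pl$normal[2]), 1, tolerance = 1e-6)
})

test_that("a plane-free cloud is returned unchanged with a warning", {
  s <- sphereCloud(1500, radius = 4)
  expect_warning(out <- removeTableRansac(s), "unchanged")
  expect_equal(nPoints(out), nPoints(s))
})

test_that("plane removal on a synthetic scene is near-perfect by labels", {
  sc <- makeScene(9, rngSeed = 21)
  labs <- sceneLabels(sc)
  kept <- removeTableRansac(sceneCloud(sc))
  ki <- cloudMetadata(kept)$keptIndices
  tableKept <- sum(labs[ki] == 0L) / sum(labs == 0L)
  seedLost <- 1 - sum(labs[ki] > 0L) / sum(labs > 0L)
  expect_lt(tableKept, 0.01) # >= 99% of table removed
  expect_lt(seedLost, 0.01)  # < 1% of seed points removed
})

test_that("region growing separates disconnected surfaces", {
  a <- sphereCloud(1200, radius = 4, center = c(0, 0, 0))
  b <- sphereCloud(1200, radius = 4, center = c(20, 0, 0))
  cl2 <- regionGrow(pointCloud(rbind(cloudPoints(a), cloudPoints(b))))
  expect_length(cl2, 2L)
  expect_length(regionGrow(a), 1L)
  expect_equal(sort(unlist(regionGrow(a))), 1:1200)

  # sphere + detached planar strip -> 2 clusters, one planar
  strip <- planeCloud(side = 8, spacing = 0.2, level = -15)
  both <- pointCloud(rbind(cloudPoints(a), cloudPoints(strip)))
  cls <- regionGrow(both)
  expect_length(cls, 2L)
  classes <- vapply(cls, function(ix)
    classifyCluster(dimensionalityFeatures(both[ix])), "")
  expect_setequal(classes, c("volumetric", "planar"))
})

test_that("dimensionality features follow the eigenvalue identity", {
  # perfect line
  line <- pointCloud(cbind(seq(0, 10, length.out = 50), 0, 0))
  fl <- dimensionalityFeatures(line)
  expect_equal(fl$a1d, 1, tolerance = 1e-12)
  expect_equal(fl$a2d, 0, tolerance = 1e-12)
  expect_equal(fl$a3d, 0, tolerance = 1e-12)

  # planar disc
  th <- runif(4000, 0, 2 * pi); r <- sqrt(runif(4000)) * 5
  disc <- pointCloud(cbind(r * cos(th), 0, r * sin(th)))
  fd <- dimensionalityFeatures(disc)
  expect_lt(fd$a1d, 0.05)
  expect_gt(fd$a2d, 0.9)
  expect_equal(fd$a3d, 0, tolerance = 1e-12)

  # isotropic Gaussian ball
  set.seed(10)
  ball <- pointCloud(matrix(rnorm(3e4), ncol = 3))
  fb <- dimensionalityFeatures(ball)
  expect_equal(fb$a3d, 1, tolerance = 0.05)

  # identity a1D + a2D + a3D = 1 on arbitrary clusters
  for (rep in 1:20) {
    X <- matrix(rnorm(150), ncol = 3) %*% matrix(rnorm(9), 3, 3)
    f <- dimensionalityFeatures(pointCloud(X))
    expect_equal(f$a1d + f$a2d + f$a3d, 1, tolerance = 1e-9)
    expect_true(all(c(f$a1d, f$a2d, f$a3d) >= -1e-12))
  }
  expect_error(dimensionalityFeatures(pointCloud(matrix(1, 5, 3))),
               "degenerate")
})

test_that("cluster classification uses the arg-max rule with fixed tie-break", {
  mk <- function(a1, a2, a3) structure(list(a1d = a1, a2d = a2, a3d = a3),
                                       class = "seedscan_dimfeat")
  expect_equal(classifyCluster(mk(0.8, 0.15, 0.05)), "linear")
  expect_equal(classifyCluster(mk(0.05, 0.9, 0.05)), "planar")
  expect_equal(classifyCluster(mk(0.3, 0.3, 0.4)), "volumetric")
  expect_equal(classifyCluster(mk(0.4, 0.4, 0.2)), "planar")   # planar > linear
  expect_equal(classifyCluster(mk(0.4, 0.2, 0.4)), "volumetric") # vol > linear
})

test_that("extractSeeds recovers every seed of a scene with pure clusters", {
  sc <- makeScene(9, rngSeed = 33)
  labs <- sceneLabels(sc)
  ex <- extractSeeds(sceneCloud(sc), nInputSeeds = 9)
  expect_equal(ex$report$rSeg, 100)
  expect_length(ex$seeds, 9L)

  majors <- integer(0)
  for (ix in ex$clusterIndices) {
    l <- labs[ix]
    tab <- table(l)
    maj <- as.integer(names(tab)[which.max(tab)])
    expect_gt(mean(l == maj), 0.95) # purity
    majors <- c(majors, maj)
  }
  expect_setequal(majors, 1:9)

  # no planar cluster is ever returned
  for (ft in ex$features)
    expect_false(classifyCluster(ft) == "planar")

  # a table-only scene yields no seeds
  tab <- planeCloud(side = 25, spacing = 0.3, sd = 0.005)
  ex0 <- extractSeeds(tab)
  expect_length(ex0$seeds, 0L)
})

test_that("cluster count is invariant to a rigid rotation of the scene", {
  sc <- makeScene(6, rngSeed = 55)
  set.seed(99)
  R <- randomRotation()
  ex1 <- extractSeeds(sceneCloud(sc))
  ex2 <- extractSeeds(rotateCloud(sceneCloud(sc), R))
  expect_equal(length(ex2$seeds), length(ex1$seeds))
})
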