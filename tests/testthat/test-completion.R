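test_that("slicing partitions the cloud into equal-width slabs", {
  set.seed(2)
  x <- runif(100, 0, 20)
  cl <- pointCloud(cbind(x, rnorm(100), rnorm(100)))
  ss <- sliceCloud(cl, 20)
  sizes <- vapply(ss$slabs, function(s) length(s$idx), 1L)
  expect_equal(sum(sizes), 100L)
  expect_identical(sort(unlist(lapply(ss$slabs, `[[`, "idx"))), 1:100)
  widths <- diff(ss$breaks)
  expect_lt(max(abs(widths - diff(range(x)) / 20)), 1e-9)
  # membership: every point inside its slab interval
  for (i in seq_along(ss$slabs)) {
    s <- ss$slabs[[i]]
    if (length(s$idx))
      expect_true(all(x[s$idx] >= s$low - 1e-12 & x[s$idx] <= s$high + 1e-12))
  }
  # degenerate: all x equal -> single slab
  cl0 <- pointCloud(cbind(0, rnorm(10), rnorm(10)))
  ss0 <- sliceCloud(cl0, 20)
  expect_equal(ss0$nSlices, 1L)
  expect_error(sliceCloud(cl, 1), "nSlices")
})

test_that("a full ring profile needs no fill", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  ring <- cbind(0.5, 3 * cos(th), 3 * sin(th))
  out <- completeSlice(ring, densityTarget = 10)
  expect_equal(nrow(out), nrow(ring))
})

test_that("a half ring is filled on the missing side at the right radius", {
  th <- seq(0, pi, length.out = 90) # upper half in (y, z)
  ring <- cbind(0.5, 3 * cos(th), 3 * sin(th))
  out <- completeSlice(ring, densityTarget = 5)
  added <- out[-seq_len(nrow(ring)), , drop = FALSE]
  expect_gt(nrow(added), 10)
  expect_true(all(added[, 3] < 1e-6)) # lower half-plane
  r <- sqrt(added[, 2]^2 + added[, 3]^2)
  expect_lt(max(abs(r - 3) / 3), 0.02)
  expect_equal(unique(added[, 1]), 0.5) # degenerate x-range: slab mean
})

test_that("completing an un-occluded cloud adds almost nothing", {
  s <- makeSeedCloud(seedSpec(c(6, 4, 3), noiseSigma = 0.005, spacing = 0.2,
                              rngSeed = 31))
  np <- normalizePose(s$full)$cloud
  comp <- completeCloud(np)
  expect_lt(cloudMetadata(comp)$nFilled, 0.02 * nPoints(np))
})

test_that("completion restores an occluded ellipsoid below the error budget", {
  s <- makeSeedCloud(seedSpec(c(8, 5, 3), irregularity = 0.05,
                              noiseSigma = 0.005, spacing = 0.1, rngSeed = 42))
  occ <- occludeBottom(s$full, 30)
  np <- normalizePose(occ)
  comp <- completeCloud(np$cloud)
  tr <- applyPose(s$truth, np$pose)

  # original points preserved verbatim ahead of the fill
  expect_identical(cloudPoints(comp)[seq_len(nPoints(np$cloud)), ],
                   cloudPoints(np$cloud))

  er <- completionError(comp, tr)$er
  er0 <- completionError(np$cloud, tr)$er
  expect_lt(er, 0.017)
  expect_lt(er, er0) # completion never hurts
})

test_that("noise-free ellipsoid fills stay near the analytic surface", {
  s <- makeSeedCloud(seedSpec(c(6, 4, 2), noiseSigma = 0, spacing = 0.1,
                              rngSeed = 5))
  occ <- occludeBottom(s$full, 30)
  np <- normalizePose(occ)
  comp <- completeCloud(np$cloud)
  n0 <- cloudMetadata(comp)$nOriginal
  fill <- cloudPoints(comp)[-seq_len(n0), , drop = FALSE]
  expect_gt(nrow(fill), 100)
  # map the fill back into the generator frame (p0 = R^T (p - t)) and
  # measure the radial distance to the analytic ellipsoid surface
  R <- np$pose$rotation
  fill0 <- sweep(fill, 2, np$pose$translation) %*% R
  rdir <- sqrt(rowSums(fill0^2))
  rell <- rdir / sqrt((fill0[, 1] / 6)^2 + (fill0[, 2] / 2)^2 +
                      (fill0[, 3] / 4)^2)
  expect_lt(mean(abs(rdir - rell)), 0.03)
  expect_lt(max(abs(rdir - rell)), 0.15)
})

test_that("doubling the slab count changes the error by less than 50%", {
  s <- makeSeedCloud(seedSpec(c(7, 5, 3), irregularity = 0.05,
                              noiseSigma = 0.005, spacing = 0.12, rngSeed = 77))
  occ <- occludeBottom(s$full, 30)
  np <- normalizePose(occ)
  tr <- applyPose(s$truth, np$pose)
  e20 <- completionError(completeCloud(np$cloud, 20), tr)$er
  e40 <- completionError(completeCloud(np$cloud, 40), tr)$er
  expect_lt(abs(e40 - e20) / e20, 0.5)
})

test_that("completion never increases the error across random seeds", {
  for (k in 1:20) {
    ax <- sort(c(runif(1, 4, 9), runif(1, 3, 6), runif(1, 2, 4)),
               decreasing = TRUE)
    s <- makeSeedCloud(seedSpec(ax, irregularity = 0.05, noiseSigma = 0.005,
                                spacing = 0.25, rngSeed = 1000 + k))
    occ <- occludeBottom(s$full, 30)
    np <- normalizePose(occ)
    tr <- applyPose(s$truth, np$pose)
    er <- completionError(completeCloud(np$cloud), tr)$er
    er0 <- completionError(np$cloud, tr)$er
    expect_lt(er, er0)
  }
})

test_that("gaussian smoothing behaves like a local weighted mean", {
  expect_equal(cloudPoints(gaussianSmooth(pointCloud(rbind(c(1, 2, 3))),
                                          radius = 1, sigma = 0.5)),
               rbind(c(1, 2, 3)), ignore_attr = TRUE)

  # noisy sphere: RMS radial deviation strictly decreases
  set.seed(6)
  noisy <- sphereCloud(4000, radius = 5, sd = 0.02)
  sm <- gaussianSmooth(noisy)
  dev0 <- sqrt(mean((sqrt(rowSums(cloudPoints(noisy)^2)) - 5)^2))
  dev1 <- sqrt(mean((sqrt(rowSums(cloudPoints(sm)^2)) - 5)^2))
  expect_lt(dev1, dev0)
  expect_equal(nPoints(sm), nPoints(noisy))

  # a noise-free plane is a fixed point
  pl <- planeCloud(side = 10, spacing = 0.5)
  smp <- gaussianSmooth(pl, radius = 1.5, sigma = 0.75)
  expect_lt(max(abs(cloudPoints(smp)[, 2])), 1e-9)
})

test_that("completion error matches its definition and a brute-force oracle", {
  a <- pointCloud(rbind(c(0, 0, 0)))
  b <- pointCloud(rbind(c(0, 0, 1)))
  expect_equal(completionError(b, a)$er, 1)
  s <- sphereCloud(500, radius = 3)
  expect_equal(completionError(s, s)$er, 0)

  set.seed(15)
  comp <- pointCloud(matrix(runif(900, -5, 5), ncol = 3))
  tru <- pointCloud(matrix(runif(600, -5, 5), ncol = 3))
  rep <- completionError(comp, tru)
  oracle <- bruteNN(cloudPoints(tru), cloudPoints(comp))
  expect_equal(rep$perPoint, unname(oracle), tolerance = 1e-12)
  expect_equal(rep$er, mean(oracle), tolerance = 1e-12)
  expect_equal(rep$np, 200L)

  rep2 <- completionError(comp, tru, direction = "completed_to_truth")
  oracle2 <- bruteNN(cloudPoints(comp), cloudPoints(tru))
  expect_equal(rep2$perPoint, unname(oracle2), tolerance = 1e-12)

  ch <- completionError(comp, tru, direction = "chamfer")
  expect_equal(ch$er, mean(c(oracle, oracle2)), tolerance = 1e-12)
})
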