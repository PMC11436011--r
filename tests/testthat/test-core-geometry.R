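test_that("PLY and XYZ round-trips preserve coordinates and order", {
  set.seed(11)
  P <- matrix(runif(3000, -10, 10), ncol = 3)
  pc <- pointCloud(P)
  ply <- tempfile(fileext = ".ply")
  xyz <- tempfile(fileext = ".xyz")
  writePointCloud(pc, ply)
  writePointCloud(pc, xyz)
  expect_equal(cloudPoints(readPointCloud(ply)), P, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(cloudPoints(readPointCloud(xyz)), P, tolerance = 1e-6,
               ignore_attr = TRUE)

  # explicit tiny fixtures: content echoed verbatim, order preserved
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0 0", "0 1 0"), f)
  expect_equal(cloudPoints(readPointCloud(f)),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".xyz")
  writeLines("1.5 2.5 3.5", f2)
  expect_equal(cloudPoints(readPointCloud(f2)), rbind(c(1.5, 2.5, 3.5)),
               ignore_attr = TRUE)
})

test_that("binary little-endian PLY is read", {
  f <- tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 2", "property float x", "property float y",
               "property float z", "end_header"), con)
  writeBin(as.numeric(c(1, 2, 3, 4, 5, 6)), con, size = 4, endian = "little")
  close(con)
  expect_equal(cloudPoints(readPointCloud(f)), rbind(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("malformed and empty cloud files raise parse errors", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("noply", "stuff"), f)
  expect_error(readPointCloud(f), "malformed")
  f2 <- tempfile(fileext = ".xyz")
  writeLines(c("1.0 2.0 not-a-number"), f2)
  expect_error(readPointCloud(f2), "line 1")
  f3 <- tempfile(fileext = ".xyz")
  writeLines(character(), f3)
  expect_error(readPointCloud(f3), "empty")
  expect_error(readPointCloud(tempfile(fileext = ".xyz")), "exist")
})

test_that("mesh formats round-trip", {
  ico <- seedscan:::icosphere(1L)
  mesh <- triangleMesh(ico$vertices * 3, ico$faces)
  for (ext in c(".ply", ".obj", ".stl")) {
    f <- tempfile(fileext = ext)
    writeMesh(mesh, f)
    back <- readMesh(f)
    expect_equal(meshVolume(back), meshVolume(mesh), tolerance = 1e-6)
    expect_equal(meshSurfaceArea(back), meshSurfaceArea(mesh), tolerance = 1e-6)
  }
})

test_that("exact conics are recovered from circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  cn <- fitEllipseDirect(cbind(3 * cos(th), 3 * sin(th)))
  el <- conicToEllipse(cn)
  expect_equal(el$semiMajor, 3, tolerance = 1e-6)
  expect_equal(el$semiMinor, 3, tolerance = 1e-6)
  expect_equal(el$center, c(0, 0), tolerance = 1e-6)

  el0 <- seedscan:::ellipseParams(c(1, 2), 4, 2, 30 * pi / 180)
  fit <- conicToEllipse(fitEllipseDirect(sampleEllipse(el0, th)))
  expect_equal(fit$center, c(1, 2), tolerance = 1e-6)
  expect_equal(fit$semiMajor, 4, tolerance = 1e-6)
  expect_equal(fit$semiMinor, 2, tolerance = 1e-6)
  expect_equal(fit$angle, 30 * pi / 180, tolerance = 1e-6)
})

test_that("half-arc data still recover the ellipse axes within 1%", {
  el0 <- seedscan:::ellipseParams(c(0, 0), 4, 2, 0)
  fit <- conicToEllipse(fitEllipseDirect(sampleEllipse(el0, seq(0, pi, length.out = 50))))
  expect_lt(abs(fit$semiMajor - 4) / 4, 0.01)
  expect_lt(abs(fit$semiMinor - 2) / 2, 0.01)
})

test_that("fitted conics always satisfy the ellipse constraint", {
  set.seed(42)
  for (rep in 1:25) {
    el <- seedscan:::ellipseParams(runif(2, -5, 5), runif(1, 2, 6),
                                   runif(1, 0.5, 2), runif(1, 0, pi))
    pts <- sampleEllipse(el, runif(30, 0, 2 * pi)) +
      matrix(rnorm(60, sd = 0.05), ncol = 2)
    cn <- fitEllipseDirect(pts)
    expect_equal(4 * cn$a * cn$c - cn$b^2, 1, tolerance = 1e-9)
    expect_lt(cn$b^2 - 4 * cn$a * cn$c, 0)
  }
})

test_that("degenerate ellipse-fit inputs are rejected", {
  expect_error(fitEllipseDirect(matrix(runif(10), ncol = 2)), "6 points")
  line <- cbind(1:20, 2 * (1:20) + 3)
  expect_error(fitEllipseDirect(line), "degenerate")
})

test_that("conic <-> params round-trip is the identity", {
  set.seed(7)
  for (rep in 1:20) {
    el <- seedscan:::ellipseParams(runif(2, -10, 10), runif(1, 1, 8),
                                   runif(1, 0.2, 1), runif(1, 0, pi))
    back <- conicToEllipse(ellipseToConic(el))
    expect_equal(back$center, el$center, tolerance = 1e-8)
    expect_equal(back$semiMajor, el$semiMajor, tolerance = 1e-8)
    expect_equal(back$semiMinor, el$semiMinor, tolerance = 1e-8)
    expect_equal(back$angle, el$angle, tolerance = 1e-6)
  }
})

test_that("fit -> dense sample -> fit is idempotent", {
  el0 <- seedscan:::ellipseParams(c(2, -1), 5, 2.5, 1.1)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  fit1 <- conicToEllipse(fitEllipseDirect(sampleEllipse(el0, th)))
  fit2 <- conicToEllipse(fitEllipseDirect(sampleEllipse(fit1, th)))
  expect_equal(fit2$center, fit1$center, tolerance = 1e-6)
  expect_equal(fit2$semiMajor, fit1$semiMajor, tolerance = 1e-6)
  expect_equal(fit2$semiMinor, fit1$semiMinor, tolerance = 1e-6)
})

test_that("sampled ellipse points satisfy the conic and trace the perimeter", {
  el <- seedscan:::ellipseParams(c(0, 0), 3, 1, 0)
  pts <- sampleEllipse(el, c(0, pi / 2, pi))
  expect_equal(pts[1, ], c(3, 0), tolerance = 1e-12)
  expect_equal(pts[3, ], c(-3, 0), tolerance = 1e-12)
  circ <- seedscan:::ellipseParams(c(0, 0), 2, 2, 0)
  expect_equal(sampleEllipse(circ, c(0, pi / 2)),
               rbind(c(2, 0), c(0, 2)), tolerance = 1e-12)

  cn <- ellipseToConic(el)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  res <- seedscan:::conicResidual(cn, sampleEllipse(el, th))
  expect_lt(max(abs(res)), 1e-9)

  # polygon perimeter vs numeric elliptic-integral oracle
  poly <- sampleEllipse(el, seq(0, 2 * pi, length.out = 361)[-361])
  per <- sum(sqrt(rowSums((poly - poly[c(2:360, 1), ])^2)))
  expect_lt(abs(per - ellipsePerimeter(3, 1)) / ellipsePerimeter(3, 1), 0.001)
})
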