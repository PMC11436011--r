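test_that("bounding-box dimensions scale homogeneously", {
  s <- makeSeedCloud(seedSpec(c(6, 4, 2), noiseSigma = 0, spacing = 0.2))
  cl <- normalizePose(s$full)$cloud
  d1 <- aabbDims(cl)
  expect_equal(unname(d1), c(12, 8, 4), tolerance = 0.1)
  d2 <- aabbDims(pointCloud(2 * cloudPoints(cl)))
  expect_equal(unname(d2), 2 * unname(d1), tolerance = 1e-12)
})

test_that("principal sections of a sphere match the closed forms", {
  s <- makeSeedCloud(seedSpec(c(5, 5, 5), noiseSigma = 0, spacing = 0.15))
  mesh <- reconstructSurface(s$full)
  secs <- principalSections(mesh)
  for (sec in secs) {
    expect_lt(abs(sec$perimeter - 2 * pi * 5) / (2 * pi * 5), 0.01)
    expect_lt(abs(sec$area - pi * 25) / (pi * 25), 0.01)
  }
  expect_equal(radiusRatio(mesh), 1, tolerance = 0.01)
})

test_that("principal sections of an ellipsoid match the profile ellipses", {
  s <- makeSeedCloud(seedSpec(c(6, 4, 2), noiseSigma = 0, spacing = 0.12,
                              rngSeed = 2))
  mesh <- reconstructSurface(normalizePose(s$full)$cloud)
  secs <- principalSections(mesh)
  # horizontal profile spans L x W: ellipse with semi-axes 6 and 4
  expect_lt(abs(secs$horizontal$area - pi * 24) / (pi * 24), 0.01)
  expect_lt(abs(secs$horizontal$perimeter - ellipsePerimeter(6, 4)) /
            ellipsePerimeter(6, 4), 0.01)
  # transverse spans L x T, longitudinal spans W x T
  expect_lt(abs(secs$transverse$area - pi * 12) / (pi * 12), 0.015)
  expect_lt(abs(secs$longitudinal$area - pi * 8) / (pi * 8), 0.015)
  expect_equal(radiusRatio(mesh), 3, tolerance = 0.02)
})

test_that("shape phenotype formulas reproduce the analytic identities", {
  r <- 3
  sizes <- list(V = 4 / 3 * pi * r^3, S = 4 * pi * r^2, L = 2 * r, W = 2 * r,
                T = 2 * r, C1 = 2 * pi * r, C2 = 2 * pi * r, C3 = 2 * pi * r,
                A1 = pi * r^2, A2 = pi * r^2, A3 = pi * r^2)
  shp <- shapePhenotypes(sizes, RR = 1)
  expect_equal(unname(shp[c("ND", "F", "SF", "SP", "R")]), rep(1, 5))
  expect_equal(unname(shp[c("E1", "E2", "E3")]), rep(0, 3))
  expect_equal(unname(shp[c("CR1", "CR2", "CR3")]), rep(1, 3))
  expect_equal(unname(shp[c("CP1", "CP2", "CP3")]), rep(4 / pi, 3))
  expect_equal(unname(shp["D"]), 2 * r)

  # square profile: compactness exactly one
  sq <- shapePhenotypes(list(V = 1, S = 6, L = 1, W = 1, T = 1,
                             C1 = 4, C2 = 4, C3 = 4, A1 = 1, A2 = 1, A3 = 1),
                        RR = 1)
  expect_identical(unname(sq["CP1"]), 1)

  # rectangular (convex) profile: bounding-rectangle-to-perimeter exactly one
  L <- 3; W <- 2; T <- 1
  rect <- shapePhenotypes(list(V = L * W * T, S = 22, L = L, W = W, T = T,
                               C1 = 2 * (L + W), C2 = 2 * (L + T),
                               C3 = 2 * (T + W), A1 = L * W, A2 = L * T,
                               A3 = W * T), RR = 2)
  expect_identical(unname(rect[c("BP1", "BP2", "BP3")]), c(1, 1, 1))
  expect_identical(unname(rect[c("BR1", "BR2", "BR3")]), c(1, 1, 1))

  expect_error(shapePhenotypes(list(V = 1, S = 1, L = 0, W = 1, T = 1,
                                    C1 = 1, C2 = 1, C3 = 1, A1 = 1, A2 = 1,
                                    A3 = 1), RR = 1), "positive")
})

test_that("a full record is scale-equivariant in sizes, invariant in shapes", {
  s <- makeSeedCloud(seedSpec(c(6, 4, 3), irregularity = 0.05,
                              noiseSigma = 0, spacing = 0.15, rngSeed = 8))
  cl <- normalizePose(s$full)$cloud
  mesh <- reconstructSurface(cl)
  rec1 <- phenotypeRecord(cl, mesh)
  cl2 <- pointCloud(2 * cloudPoints(cl))
  rec2 <- phenotypeRecord(cl2, reconstructSurface(cl2))

  linear <- c("L", "W", "T", "C1", "C2", "C3", "D")
  quad <- c("S", "A1", "A2", "A3")
  shape <- setdiff(names(rec1), c(linear, quad, "V"))
  expect_equal(unlist(rec2[linear]) / unlist(rec1[linear]), rep(2, 7),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(unlist(rec2[quad]) / unlist(rec1[quad]), rep(4, 4),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(rec2$V / rec1$V, 8, tolerance = 0.01)
  expect_equal(unlist(rec2[shape]), unlist(rec1[shape]), tolerance = 0.01)
})

test_that("isoperimetric bounds hold for measured cross-sections", {
  for (seed in c(3, 17)) {
    set.seed(seed)
    s <- makeSeedCloud(seedSpec(sort(runif(3, 2.5, 7), decreasing = TRUE),
                                irregularity = 0.1, noiseSigma = 0.005,
                                spacing = 0.2, rngSeed = seed))
    cl <- normalizePose(s$full)$cloud
    rec <- phenotypeRecord(cl, reconstructSurface(cl))
    expect_true(all(unlist(rec[c("CR1", "CR2", "CR3")]) >= 1 - 0.01))
    expect_true(all(unlist(rec[c("CP1", "CP2", "CP3")]) <= 4 / pi + 0.01))
    expect_gte(rec$ND, 1)
    expect_lte(rec$F, 1 + 1e-9)
    expect_gte(rec$RR, 1)
    expect_false(anyNA(rec))
  }
})

test_that("phenotype variable codes cover all 33 traits", {
  v <- phenotypeVariables()
  expect_length(v, 33L)
  expect_identical(unname(v[1:11]),
                   c("V", "S", "L", "W", "T", "C1", "C2", "C3", "A1", "A2", "A3"))
  expect_false(anyDuplicated(v) > 0)
})
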