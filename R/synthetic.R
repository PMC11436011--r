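#' @name synthetic-seeds
#' @title Synthetic seed and table-scene generator
#'
#' @description
#' Emulates what a handheld table-top laser scanner delivers, so every
#' downstream stage can be exercised and validated without hardware: seeds are
#' ellipsoid-like closed surfaces (optionally perturbed by a smooth low-order
#' radial field), sampled quasi-uniformly at a target spacing, with Gaussian
#' coordinate noise, resting on a table plane with an angular cap of points
#' missing on the table-facing side. Every generator is reproducible from an
#' integer seed.
NULL

# run expr with a temporary RNG state seeded from `seed`
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a SeedSpec
#'
#' @param semiAxes three positive lengths in mm, descending (a >= b >= c).
#' @param irregularity amplitude in [0, 0.3] of the smooth low-order radial
#'   perturbation (fraction of the local ellipsoid radius).
#' @param noiseSigma Gaussian coordinate noise sd in mm.
#' @param spacing target inter-point surface distance in mm.
#' @param rngSeed integer generator seed.
#' @return a \linkS4class{SeedSpec}.
#' @examples
#' seedSpec(c(6, 4, 2), irregularity = 0.05, rngSeed = 7)
#' @export
seedSpec <- function(semiAxes, irregularity = 0, noiseSigma = 0.005,
                     spacing = 0.1, rngSeed = 1L) {
  new("SeedSpec", semiAxes = as.numeric(semiAxes),
      irregularity = as.numeric(irregularity),
      noiseSigma = as.numeric(noiseSigma), spacing = as.numeric(spacing),
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SeedSpec", function(object) {
  cat(sprintf("SeedSpec: semi-axes (%.3g, %.3g, %.3g) mm, irregularity %.3g,\n",
              object@semiAxes[1], object@semiAxes[2], object@semiAxes[3],
              object@irregularity))
  cat(sprintf("  noise %.4g mm, spacing %.3g mm, seed %d\n",
              object@noiseSigma, object@spacing, object@rngSeed))
})

# Knud Thomsen approximation of the ellipsoid surface area
ellipsoidArea <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Fibonacci lattice of n quasi-uniform directions on the unit sphere,
# lattice poles along the X axis
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  x <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - x^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(x, r * sin(phi), r * cos(phi))
}

# smooth band-limited radial perturbation field: a random (seeded upstream)
# combination of polynomial harmonics of degree <= 4 on the sphere,
# normalized to unit maximum amplitude
perturbationField <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  B <- cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
             x * y * z, x * (y^2 - z^2), y * (z^2 - x^2), z * (x^2 - y^2),
             (x^2 - y^2) * z^2, x * y * (x^2 - y^2),
             x^4 + y^4 + z^4 - 0.6)
  co <- stats::rnorm(ncol(B))
  p <- as.vector(B %*% co)
  m <- max(abs(p))
  if (m > 0) p / m else p
}

#' Generate one synthetic seed cloud
#'
#' Samples the closed surface
#' \eqn{r(u) = r_{ell}(u) (1 + irregularity \cdot P(u))} quasi-uniformly at
#' the requested spacing, where \eqn{r_{ell}} is the radius of the ellipsoid
#' with semi-axes (a, b, c) mapped to the (X, Z, Y) axes (length along X,
#' thickness along Y: the resting orientation) and P is a smooth band-limited
#' perturbation. Returns the noisy cloud (\code{full}) and the noise-free
#' surface sampling (\code{truth}).
#'
#' @param spec a \linkS4class{SeedSpec}.
#' @return list with elements \code{full} and \code{truth}
#'   (\linkS4class{PointCloud}s).
#' @examples
#' s <- makeSeedCloud(seedSpec(c(5, 5, 5), spacing = 0.4, noiseSigma = 0))
#' range(sqrt(rowSums(cloudPoints(s$truth)^2)))
#' @export
makeSeedCloud <- function(spec) {
  stopifnot(is(spec, "SeedSpec"))
  ax <- spec@semiAxes
  if (spec@spacing > min(ax))
    stop("spacing exceeds the smallest semi-axis: surface would be undersampled")
  area <- ellipsoidArea(ax[1], ax[2], ax[3])
  n <- max(64L, as.integer(round(area * 2 / (sqrt(3) * spec@spacing^2))))
  withLocalSeed(spec@rngSeed, {
    dirs <- fibonacciDirections(n)
    # semi-axes: a -> X, c -> Y (thickness), b -> Z (width)
    rell <- 1 / sqrt((dirs[, 1] / ax[1])^2 + (dirs[, 2] / ax[3])^2 +
                     (dirs[, 3] / ax[2])^2)
    r <- if (spec@irregularity > 0)
      rell * (1 + spec@irregularity * perturbationField(dirs)) else rell
    truth <- dirs * r
    full <- if (spec@noiseSigma > 0)
      truth + matrix(stats::rnorm(3 * n, sd = spec@noiseSigma), n, 3) else truth
    list(full = pointCloud(full, label = "seed"),
         truth = pointCloud(truth, label = "seed_truth"))
  })
}

#' Remove the bottom angular cap of a cloud
#'
#' Emulates the unscanned table-facing side: every point whose direction from
#' the cloud centroid lies within \code{capAngle} of the -Y axis is removed.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param capAngle half-opening angle of the removed cap in degrees,
#'   in (0, 90).
#' @return the occluded \linkS4class{PointCloud} (an order-preserving subset).
#' @export
occludeBottom <- function(cloud, capAngle) {
  if (capAngle <= 0 || capAngle >= 90)
    stop("'capAngle' must lie strictly between 0 and 90 degrees")
  P <- cloudPoints(cloud)
  ctr <- colMeans(P)
  d <- sweep(P, 2, ctr)
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  cosang <- -d[, 2] / nrm # cosine of the angle to -Y
  keep <- cosang <= cos(capAngle * pi / 180)
  if (!any(keep)) stop("occlusion would remove every point")
  cloud[keep]
}

#' Default sampler of scene seeds
#'
#' Draws roundish bean-like seeds (market soybean / black bean / red bean /
#' mung bean span): semi-axis a uniform in [aRange], b and c as moderate
#' fractions of a, so clusters carry the three-dimensional scatter signature
#' the segmentation filter keeps.
#'
#' @param aRange range of the longest semi-axis in mm.
#' @param spacing surface sampling spacing in mm (scene scale).
#' @param irregularity,noiseSigma forwarded to \code{\link{seedSpec}}.
#' @return a function(rngSeed) returning a \linkS4class{SeedSpec}.
#' @export
defaultSeedSampler <- function(aRange = c(3.5, 5.5), spacing = 0.3,
                               irregularity = 0.03, noiseSigma = 0.005) {
  function(rngSeed) {
    a <- stats::runif(1, aRange[1], aRange[2])
    b <- a * stats::runif(1, 0.82, 0.95)
    c <- b * stats::runif(1, 0.85, 0.98)
    seedSpec(c(a, b, c), irregularity = irregularity,
             noiseSigma = noiseSigma, spacing = spacing, rngSeed = rngSeed)
  }
}

#' Generate a labelled synthetic table scene
#'
#' Seeds are drawn from \code{specSampler}, occluded by their resting cap,
#' dropped so their lowest surface point touches the table plane y = 0 and
#' placed on a jittered grid with disjoint bounding boxes. The table is
#' sampled as a y = 0 plane patch at the same spacing with the same
#' coordinate noise. Label 0 marks table points; labels 1..nSeeds mark seeds.
#'
#' @param nSeeds number of seeds (>= 1).
#' @param specSampler function(rngSeed) -> \linkS4class{SeedSpec}; defaults to
#'   \code{\link{defaultSeedSampler}()}.
#' @param tableSize optional side length of the square table patch in mm; by
#'   default the patch covers the seed grid plus a margin. An explicit size
#'   too small for the grid is a placement error.
#' @param rngSeed integer scene seed.
#' @param capAngle resting occlusion cap in degrees.
#' @param margin clearance between seed bounding boxes in mm.
#' @return a \linkS4class{SeedScene}.
#' @examples
#' sc <- makeScene(2, rngSeed = 11)
#' table(sceneLabels(sc) > 0)
#' @export
makeScene <- function(nSeeds, specSampler = NULL, tableSize = NULL,
                      rngSeed = 1L, capAngle = 30, margin = 3) {
  if (nSeeds < 1) stop("'nSeeds' must be >= 1")
  if (is.null(specSampler)) specSampler <- defaultSeedSampler()
  withLocalSeed(rngSeed, {
    seedSeeds <- sample.int(.Machine$integer.max %/% 2L, nSeeds)
    specs <- lapply(seedSeeds, specSampler)

    clouds <- vector("list", nSeeds)
    truths <- vector("list", nSeeds)
    halfw <- numeric(nSeeds) # half extent in x/z
    for (k in seq_len(nSeeds)) {
      sk <- makeSeedCloud(specs[[k]])
      occ <- occludeBottom(sk$full, capAngle)
      lift <- -min(cloudPoints(sk$truth)[, 2])
      clouds[[k]] <- list(occ = occ, truth = sk$truth, lift = lift)
      halfw[k] <- max(abs(cloudPoints(sk$truth)[, c(1, 3)]))
    }

    cell <- 2 * max(halfw) + margin
    ncol <- ceiling(sqrt(nSeeds))
    nrow <- ceiling(nSeeds / ncol)
    gridSpan <- c(ncol, nrow) * cell
    span <- if (is.null(tableSize)) max(gridSpan) + cell else tableSize
    if (span < max(gridSpan))
      stop(sprintf("placement error: %d seeds need a table of at least %.1f mm",
                   nSeeds, max(gridSpan)))

    ord <- sample.int(nSeeds) # shuffle grid slots
    centers <- matrix(NA_real_, nSeeds, 2)
    for (k in seq_len(nSeeds)) {
      slot <- ord[k] - 1L
      gx <- slot %% ncol
      gz <- slot %/% ncol
      jit <- stats::runif(2, -margin / 4, margin / 4)
      centers[k, ] <- c((gx - (ncol - 1) / 2) * cell + jit[1],
                        (gz - (nrow - 1) / 2) * cell + jit[2])
    }

    spacing <- specs[[1]]@spacing
    noise <- specs[[1]]@noiseSigma
    gx <- seq(-span / 2, span / 2, by = spacing)
    gz <- seq(-span / 2, span / 2, by = spacing)
    tab <- cbind(rep(gx, times = length(gz)), 0, rep(gz, each = length(gx)))
    if (noise > 0)
      tab[, 2] <- stats::rnorm(nrow(tab), sd = noise)

    seedPts <- vector("list", nSeeds)
    for (k in seq_len(nSeeds)) {
      shift <- c(centers[k, 1], clouds[[k]]$lift, centers[k, 2])
      seedPts[[k]] <- sweep(cloudPoints(clouds[[k]]$occ), 2, -shift)
      truths[[k]] <- pointCloud(sweep(cloudPoints(clouds[[k]]$truth), 2, -shift),
                                label = sprintf("seed_%03d_truth", k))
    }

    allPts <- rbind(tab, do.call(rbind, seedPts))
    labels <- c(rep(0L, nrow(tab)),
                rep(seq_len(nSeeds), vapply(seedPts, nrow, 1L)))
    new("SeedScene",
        cloud = pointCloud(allPts, label = "scene"),
        labels = labels, truthClouds = truths,
        metadata = list(specs = specs, centers = centers, capAngle = capAngle,
                        spacing = spacing, tableNoise = noise, span = span,
                        rngSeed = rngSeed))
  })
}

#' @rdname SeedScene-class
#' @export
setMethod("sceneCloud", "SeedScene", function(x) x@cloud)

#' @rdname SeedScene-class
#' @export
setMethod("sceneLabels", "SeedScene", function(x) x@labels)

#' @rdname SeedScene-class
#' @export
setMethod("sceneTruth", "SeedScene", function(x) x@truthClouds)

setMethod("show", "SeedScene", function(object) {
  n <- max(object@labels)
  cat(sprintf("SeedScene: %d seeds, %d points (%d table / %d seed)\n",
              n, length(object@labels), sum(object@labels == 0L),
              sum(object@labels > 0L)))
})

#' Write a scene as PLY plus a per-point label CSV and per-seed truth PLYs
#'
#' @param scene a \linkS4class{SeedScene}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePointCloud(sceneCloud(scene), file.path(dir, "scene.ply"))
  utils::write.csv(data.frame(label = sceneLabels(scene)),
                   file.path(dir, "scene_labels.csv"), row.names = FALSE)
  for (k in seq_along(sceneTruth(scene)))
    writePointCloud(sceneTruth(scene)[[k]],
                    file.path(dir, sprintf("truth_%04d.ply", k)))
  invisible(dir)
}
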