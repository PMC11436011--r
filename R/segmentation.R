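#' @name segmentation
#' @title Single-seed segmentation of a table scene
#'
#' @description
#' Extracts individual seed clouds from a raw scene: (1) RANSAC detection and
#' removal of the table plane (distance threshold 0.05 mm), (2) smoothness and
#' curvature based region growing into clusters, (3) classification of each
#' cluster by its covariance-eigenvalue dimensionality features -- the linear
#' feature \eqn{a_{1D} = (\lambda_1-\lambda_2)/\lambda_1}, planar feature
#' \eqn{a_{2D} = (\lambda_2-\lambda_3)/\lambda_1} and three-dimensional
#' scatter feature \eqn{a_{3D} = \lambda_3/\lambda_1}, whose sum is exactly
#' one -- keeping scattered (volumetric) clusters and discarding planar table
#' remnants.
NULL

#' Remove the dominant plane from a scene by RANSAC
#'
#' Detects the single best-supported plane and drops every point within
#' \code{distThreshold} of it. If no plane reaches \code{minInlierFraction}
#' support, the scene is returned unchanged with a warning.
#'
#' @param scene a \linkS4class{PointCloud} with >= 3 points.
#' @param distThreshold inlier distance in mm (default 0.05).
#' @param iterations RANSAC iterations.
#' @param minInlierFraction minimum fraction of points a plane must explain.
#' @param seed RNG seed for the (reproducible) plane sampling.
#' @return the filtered \linkS4class{PointCloud}; metadata gains
#'   \code{keptIndices} (indices into the input), \code{plane}
#'   (\code{list(normal, offset)} or NULL) and \code{inlierFraction}.
#' @export
removeTableRansac <- function(scene, distThreshold = 0.05, iterations = 1000L,
                              minInlierFraction = 0.2, seed = 0L) {
  P <- cloudPoints(scene)
  n <- nrow(P)
  if (n < 3) stop("scene must contain at least 3 points")

  bestPlane <- withLocalSeed(seed, {
    sub <- if (n > 30000L) P[sample.int(n, 30000L), , drop = FALSE] else P
    bestCount <- -1L
    best <- NULL
    chunk <- 100L
    done <- 0L
    while (done < iterations) {
      m <- min(chunk, iterations - done)
      done <- done + m
      normals <- matrix(NA_real_, m, 3)
      offsets <- numeric(m)
      for (t in seq_len(m)) {
        tri <- P[sample.int(n, 3L), , drop = FALSE]
        nv <- crossProduct3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        nn <- sqrt(sum(nv^2))
        if (nn < 1e-12) next
        normals[t, ] <- nv / nn
        offsets[t] <- sum(normals[t, ] * tri[1, ])
      }
      ok <- which(is.finite(normals[, 1]))
      if (!length(ok)) next
      D <- abs(sub %*% t(normals[ok, , drop = FALSE]) -
                 matrix(offsets[ok], nrow(sub), length(ok), byrow = TRUE))
      counts <- colSums(D < distThreshold)
      w <- which.max(counts)
      if (counts[w] > bestCount) {
        bestCount <- counts[w]
        best <- list(normal = normals[ok[w], ], offset = offsets[ok[w]])
      }
    }
    best
  })
  if (is.null(bestPlane)) {
    warning("RANSAC found no candidate plane; scene returned unchanged")
    return(setCloudMetadata(scene, plane = NULL, keptIndices = seq_len(n),
                            inlierFraction = 0))
  }
  # refine on inliers with a total-least-squares plane, twice
  for (r in 1:2) {
    d <- abs(P %*% bestPlane$normal - bestPlane$offset)
    inl <- which(d < distThreshold)
    if (length(inl) >= 3) {
      Q <- P[inl, , drop = FALSE]
      ctr <- colMeans(Q)
      sv <- svd(sweep(Q, 2, ctr), nu = 0, nv = 3)
      nv <- sv$v[, 3]
      bestPlane <- list(normal = nv, offset = sum(nv * ctr))
    }
  }
  d <- abs(P %*% bestPlane$normal - bestPlane$offset)
  inlier <- d < distThreshold
  frac <- mean(inlier)
  if (frac < minInlierFraction) {
    warning(sprintf(
      "no plane reaches %.0f%% support (best %.1f%%); scene returned unchanged",
      100 * minInlierFraction, 100 * frac))
    return(setCloudMetadata(scene, plane = NULL, keptIndices = seq_len(n),
                            inlierFraction = frac))
  }
  kept <- which(!inlier)
  if (!length(kept)) stop("plane removal would empty the scene")
  out <- scene[kept]
  setCloudMetadata(out, plane = bestPlane, keptIndices = kept,
                   inlierFraction = frac)
}

#' Region growing segmentation
#'
#' Estimates per-point normals and surface-variation curvature from k-NN
#' neighbourhoods, then grows clusters from low-curvature seed points:
#' a neighbour joins when its normal deviates by at most
#' \code{smoothnessDeg} from the current point's normal, and itself spreads
#' the region when its curvature is below \code{curvatureThreshold}.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param smoothnessDeg smoothness threshold in degrees.
#' @param curvatureThreshold surface-variation threshold (dimensionless).
#' @param k neighbourhood size for normals and connectivity.
#' @param minClusterSize clusters below this size are rejected.
#' @return list of integer index vectors (into the cloud), largest first.
#' @export
regionGrow <- function(cloud, smoothnessDeg = 15, curvatureThreshold = 0.4,
                       k = 30L, minClusterSize = 30L) {
  P <- cloudPoints(cloud)
  n <- nrow(P)
  if (n < 1) stop("empty cloud")
  if (n <= k) stop(sprintf("cloud has %d points but k-NN size is %d", n, k))
  kn <- cpp_knn(P, P, as.integer(k) + 1L)
  nc <- cpp_normals(P, kn$idx)
  labels <- cpp_region_grow(kn$idx, nc$normals, nc$curvature,
                            cos(smoothnessDeg * pi / 180), curvatureThreshold)
  cl <- unname(split(seq_len(n), labels))
  cl <- cl[vapply(cl, length, 1L) >= minClusterSize]
  cl[order(vapply(cl, length, 1L), decreasing = TRUE)]
}

#' Covariance dimensionality features of a cluster
#'
#' Eigenvalues of the 3 x 3 covariance of the centred points, in descending
#' order, and the derived linear / planar / scatter features. Their sum is
#' identically one.
#'
#' @param cluster a \linkS4class{PointCloud} with >= 4 points.
#' @return record with fields \code{lambda} (descending eigenvalues, mm^2),
#'   \code{a1d}, \code{a2d}, \code{a3d}.
#' @export
dimensionalityFeatures <- function(cluster) {
  P <- cloudPoints(cluster)
  if (nrow(P) < 4) stop("cluster must contain at least 4 points")
  ev <- eigen(stats::cov(P), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1] <= 0) stop("degenerate cluster: all points identical")
  structure(list(lambda = ev,
                 a1d = (ev[1] - ev[2]) / ev[1],
                 a2d = (ev[2] - ev[3]) / ev[1],
                 a3d = ev[3] / ev[1]),
            class = "seedscan_dimfeat")
}

#' @export
print.seedscan_dimfeat <- function(x, ...) {
  cat(sprintf("dimensionality features: a1D %.3f  a2D %.3f  a3D %.3f (%s)\n",
              x$a1d, x$a2d, x$a3d, classifyCluster(x)))
  invisible(x)
}

#' Classify a cluster as linear, planar or volumetric
#'
#' Arg-max rule over (a1D, a2D, a3D) with deterministic tie-break
#' volumetric > planar > linear.
#'
#' @param feat a record from \code{\link{dimensionalityFeatures}}.
#' @return one of \code{"linear"}, \code{"planar"}, \code{"volumetric"}.
#' @export
classifyCluster <- function(feat) {
  m <- max(feat$a1d, feat$a2d, feat$a3d)
  if (feat$a3d == m) "volumetric" else if (feat$a2d == m) "planar" else "linear"
}

# segmentation accuracy report
segmentationReport <- function(nInputSeeds, nExtracted) {
  rSeg <- if (is.null(nInputSeeds) || is.na(nInputSeeds)) NA_real_
          else 100 * nExtracted / nInputSeeds
  structure(list(nInputSeeds = nInputSeeds, nExtracted = nExtracted,
                 rSeg = rSeg), class = "seedscan_segreport")
}

#' @export
print.seedscan_segreport <- function(x, ...) {
  cat(sprintf("segmentation: %d cluster(s) extracted", x$nExtracted))
  if (!is.na(x$rSeg))
    cat(sprintf(" of %d seeds  (R_seg = %.2f%%)", x$nInputSeeds, x$rSeg))
  cat("\n")
  invisible(x)
}

#' Extract single-seed clouds from a scene
#'
#' Composition of \code{\link{removeTableRansac}}, \code{\link{regionGrow}}
#' and the dimensionality filter: clusters whose feature class is in
#' \code{keep} (default volumetric only; planar table remnants are always
#' discarded) and that meet the minimum size become seed clouds.
#'
#' @param scene a \linkS4class{PointCloud} (raw scene).
#' @param distThreshold,smoothnessDeg,curvatureThreshold,k,minClusterSize
#'   stage parameters, see the individual operations.
#' @param keep feature classes to retain.
#' @param nInputSeeds optional ground-truth seed count; enables the
#'   segmentation accuracy R_seg = 100 * extracted / input in the report.
#' @param ransacSeed RNG seed for plane detection.
#' @return list with \code{seeds} (list of \linkS4class{PointCloud}),
#'   \code{clusterIndices} (indices into the input scene), \code{features}
#'   (per-cluster dimensionality records) and \code{report}.
#' @export
extractSeeds <- function(scene, distThreshold = 0.05, smoothnessDeg = 15,
                         curvatureThreshold = 0.4, k = 30L,
                         minClusterSize = 30L,
                         keep = "volumetric", nInputSeeds = NULL,
                         ransacSeed = 0L) {
  noTable <- tryCatch(
    removeTableRansac(scene, distThreshold = distThreshold, seed = ransacSeed),
    error = function(e) {
      if (grepl("empty the scene", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(noTable)) { # pure-plane scene: nothing left to segment
    return(list(seeds = list(), clusterIndices = list(), features = list(),
                report = segmentationReport(nInputSeeds, 0L)))
  }
  keptIdx <- cloudMetadata(noTable)$keptIndices
  if (nPoints(noTable) <= k) {
    return(list(seeds = list(), clusterIndices = list(), features = list(),
                report = segmentationReport(nInputSeeds, 0L)))
  }
  clusters <- regionGrow(noTable, smoothnessDeg = smoothnessDeg,
                         curvatureThreshold = curvatureThreshold, k = k,
                         minClusterSize = minClusterSize)
  seeds <- list()
  idxList <- list()
  feats <- list()
  for (cl in clusters) {
    sub <- noTable[cl]
    ft <- dimensionalityFeatures(sub)
    if (classifyCluster(ft) %in% keep) {
      seeds[[length(seeds) + 1L]] <- sub
      idxList[[length(idxList) + 1L]] <- keptIdx[cl]
      feats[[length(feats) + 1L]] <- ft
    }
  }
  list(seeds = seeds, clusterIndices = idxList, features = feats,
       report = segmentationReport(nInputSeeds, length(seeds)))
}
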