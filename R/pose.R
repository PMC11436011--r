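#' @name pose
#' @title PCA pose normalization
#'
#' @description
#' Every seed is moved into a canonical measurement frame before completion
#' and trait estimation: the centroid sits at the origin and the principal
#' axes of the point covariance, in descending eigenvalue order, are mapped
#' to length -> X, width -> Z and thickness -> Y. In that frame the
#' axis-aligned bounding box directly yields L >= W >= T. Eigenvector signs
#' are fixed by requiring non-negative coordinate skewness along each axis
#' (falling back to a positive first non-zero component), and the rotation is
#' forced to be proper (det = +1) by flipping the thickness axis if needed.
NULL

poseTransform <- function(rotation, translation) {
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "seedscan_pose")
}

#' @export
print.seedscan_pose <- function(x, ...) {
  cat("rigid pose transform: p -> R p + t\n")
  print(round(x$rotation, 6))
  cat("t =", paste(signif(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize the pose of a seed cloud
#'
#' @param cloud a \linkS4class{PointCloud} with >= 4 points and
#'   non-degenerate covariance.
#' @return list with the normalized \code{cloud} and the rigid \code{pose}
#'   (rotation rows are the chosen eigenvector basis; applying it to the
#'   input reproduces the output exactly).
#' @examples
#' pc <- makeSeedCloud(seedSpec(c(6, 4, 2), spacing = 0.4, noiseSigma = 0))$full
#' aabbDims(normalizePose(pc)$cloud)
#' @export
normalizePose <- function(cloud) {
  P <- cloudPoints(cloud)
  if (nrow(P) < 4) stop("need at least 4 points for pose normalization")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  C <- crossprod(Q) / (nrow(P) - 1)
  eg <- eigen(C, symmetric = TRUE) # eigenvalues descending
  if (eg$values[1] <= 0) stop("degenerate covariance")
  E <- eg$vectors
  for (j in 1:3) {
    t <- Q %*% E[, j]
    sk <- mean(t^3)
    if (abs(sk) > 1e-9 * max(eg$values[1], 1)^1.5) {
      if (sk < 0) E[, j] <- -E[, j]
    } else {
      nz <- which(abs(E[, j]) > 1e-12)[1]
      if (E[nz, j] < 0) E[, j] <- -E[, j]
    }
  }
  # eigenvector order (descending variance) onto axes: e1->X, e3->Y, e2->Z
  R <- rbind(E[, 1], E[, 3], E[, 2])
  if (det(R) < 0) R[2, ] <- -R[2, ] # keep a proper rotation: flip thickness
  out <- Q %*% t(R)
  normals <- cloudNormals(cloud)
  if (!is.null(normals)) normals <- normals %*% t(R)
  pose <- poseTransform(R, -as.vector(R %*% ctr))
  list(cloud = pointCloud(out, normals = normals, label = cloud@label,
                          metadata = cloud@metadata),
       pose = pose)
}

#' Apply a rigid pose transform to a cloud
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param pose a transform from \code{\link{normalizePose}}.
#' @return the transformed \linkS4class{PointCloud}.
#' @export
applyPose <- function(cloud, pose) {
  P <- cloudPoints(cloud)
  out <- P %*% t(pose$rotation) +
    matrix(pose$translation, nrow(P), 3, byrow = TRUE)
  normals <- cloudNormals(cloud)
  if (!is.null(normals)) normals <- normals %*% t(pose$rotation)
  pointCloud(out, normals = normals, label = cloud@label,
             metadata = cloud@metadata)
}
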