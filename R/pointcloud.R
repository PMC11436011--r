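#' Construct a PointCloud
#'
#' @param points numeric N x 3 matrix (or coercible) of coordinates in mm.
#' @param normals optional N x 3 matrix of unit normals.
#' @param label optional single character tag.
#' @param metadata optional list of annotations.
#' @return a \linkS4class{PointCloud}.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), ncol = 3))
#' nPoints(pc)
#' @export
pointCloud <- function(points, normals = NULL, label = character(),
                       metadata = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
  }
  new("PointCloud", points = points, normals = normals,
      label = as.character(label), metadata = metadata)
}

#' @rdname PointCloud-class
#' @export
setMethod("cloudPoints", "PointCloud", function(x) x@points)

#' @rdname PointCloud-class
#' @export
setMethod("cloudNormals", "PointCloud", function(x) x@normals)

#' @rdname PointCloud-class
#' @export
setMethod("cloudLabel", "PointCloud", function(x)
  if (length(x@label)) x@label else NA_character_)

#' @rdname PointCloud-class
#' @export
setMethod("cloudMetadata", "PointCloud", function(x) x@metadata)

#' @rdname PointCloud-class
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@points))

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud with %d points (mm)%s\n", nrow(object@points),
              if (length(object@label)) paste0(" [", object@label, "]") else ""))
  cat(sprintf("  normals: %s\n", if (is.null(object@normals)) "absent" else "present"))
  rg <- apply(object@points, 2, range)
  cat(sprintf("  extent:  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Subset a point cloud by point index (order preserving)
#'
#' @param x a \linkS4class{PointCloud}.
#' @param i integer or logical index into the points.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  pointCloud(x@points[i, , drop = FALSE],
             normals = if (!is.null(x@normals)) x@normals[i, , drop = FALSE],
             label = x@label, metadata = x@metadata)
})

# internal: replace metadata entries non-destructively
setCloudMetadata <- function(x, ...) {
  md <- x@metadata
  upd <- list(...)
  md[names(upd)] <- upd
  initialize(x, metadata = md)
}

#' Median nearest-neighbour spacing of a cloud
#'
#' The median over all points of the distance to the closest other point;
#' used as the automatic density scale for completion and smoothing.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @return spacing in mm.
#' @export
medianSpacing <- function(cloud) {
  P <- cloudPoints(cloud)
  if (nrow(P) < 2) stop("need at least two points to estimate spacing")
  kn <- cpp_knn(P, P, 2L)
  stats::median(kn$dist[, 2])
}

#' Axis-aligned bounding-box dimensions of a pose-normalized cloud
#'
#' In the canonical frame the X extent is the length L, the Z extent the
#' width W and the Y extent the thickness T.
#'
#' @param cloud a pose-normalized \linkS4class{PointCloud}.
#' @return named numeric vector \code{c(L=, W=, T=)} in mm.
#' @export
aabbDims <- function(cloud) {
  P <- cloudPoints(cloud)
  if (nrow(P) < 1) stop("empty cloud")
  ext <- apply(P, 2, function(v) diff(range(v)))
  c(L = ext[1], W = ext[3], T = ext[2])
}
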