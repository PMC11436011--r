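#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PointCloud: a set of 3D points in millimetres
#'
#' The universal currency between pipeline stages: an N x 3 coordinate matrix
#' with optional unit normals, an optional text label and a free-form metadata
#' list used by operations to attach provenance (e.g. indices kept by plane
#' removal, the fitted table plane, counts of filled points).
#'
#' @slot points numeric N x 3 matrix of coordinates (mm).
#' @slot normals \code{NULL} or an N x 3 matrix of unit vectors.
#' @slot label character vector of length 0 or 1.
#' @slot metadata list of optional stage annotations.
#' @export
setClass("PointCloud",
  representation(points = "matrix", normals = "matrixOrNULL",
                 label = "character", metadata = "list"),
  prototype(points = matrix(numeric(), 0, 3), normals = NULL,
            label = character(), metadata = list())
)

setValidity("PointCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L)
    return("'points' must be a numeric matrix with 3 columns")
  if (nrow(p) < 1L)
    return("a PointCloud must contain at least one point")
  if (!all(is.finite(p)))
    return("all coordinates must be finite")
  nm <- object@normals
  if (!is.null(nm)) {
    if (!is.numeric(nm) || ncol(nm) != 3L || nrow(nm) != nrow(p))
      return("'normals' must be an N x 3 matrix matching 'points'")
    nn <- sqrt(rowSums(nm^2))
    if (any(abs(nn - 1) > 1e-6))
      return("normals must have unit Euclidean norm (tolerance 1e-6)")
  }
  if (length(object@label) > 1L)
    return("'label' must have length 0 or 1")
  TRUE
})

#' TriangleMesh: a triangulated surface
#'
#' Vertices in millimetres and 1-based triangular faces. Volume and centroid
#' computations require the mesh to be closed (every edge shared by exactly
#' two faces) and consistently oriented; \code{\link{isWatertight}} checks
#' this.
#'
#' @slot vertices numeric V x 3 matrix (mm).
#' @slot faces integer F x 3 matrix of 1-based vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  prototype(vertices = matrix(numeric(), 0, 3),
            faces = matrix(integer(), 0, 3))
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L)
    return("'vertices' must be a numeric matrix with 3 columns")
  if (!all(is.finite(v)))
    return("all vertex coordinates must be finite")
  if (ncol(f) != 3L)
    return("'faces' must have 3 columns")
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > nrow(v)))
      return("face indices must lie in [1, nrow(vertices)]")
  }
  TRUE
})

#' SeedSpec: parameters of one synthetic seed
#'
#' Describes an ellipsoid-like closed surface with semi-axes a >= b >= c (mm),
#' an optional smooth low-order radial perturbation (irregularity, amplitude
#' as a fraction of the local radius), Gaussian coordinate noise and a target
#' surface sampling spacing. Generation is fully reproducible from
#' \code{rngSeed}.
#'
#' @slot semiAxes numeric length-3, descending, positive (mm).
#' @slot irregularity numeric in [0, 0.3].
#' @slot noiseSigma numeric >= 0 (mm).
#' @slot spacing numeric > 0 (mm), target inter-point distance.
#' @slot rngSeed integer seed.
#' @export
setClass("SeedSpec",
  representation(semiAxes = "numeric", irregularity = "numeric",
                 noiseSigma = "numeric", spacing = "numeric",
                 rngSeed = "integer"))

setValidity("SeedSpec", function(object) {
  ax <- object@semiAxes
  if (length(ax) != 3L || any(!is.finite(ax)) || any(ax <= 0))
    return("'semiAxes' must be 3 positive finite lengths")
  if (is.unsorted(rev(ax)))
    return("'semiAxes' must be in descending order a >= b >= c")
  if (object@irregularity < 0 || object@irregularity > 0.3)
    return("'irregularity' must lie in [0, 0.3]")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  if (object@spacing <= 0) return("'spacing' must be > 0")
  TRUE
})

#' SeedScene: a labelled synthetic table scene
#'
#' A scene cloud (table plane plus resting, bottom-occluded seeds), a
#' per-point integer label (0 = table, k >= 1 = seed k) and the full
#' un-occluded ground-truth cloud of every seed in scene coordinates.
#'
#' @slot cloud a \linkS4class{PointCloud}.
#' @slot labels integer vector, one entry per point.
#' @slot truthClouds list of \linkS4class{PointCloud}, one per seed.
#' @slot metadata list (seed specs, placements, generator parameters).
#' @export
setClass("SeedScene",
  representation(cloud = "PointCloud", labels = "integer",
                 truthClouds = "list", metadata = "list"),
  prototype(truthClouds = list(), metadata = list()))

setValidity("SeedScene", function(object) {
  if (length(object@labels) != nrow(object@cloud@points))
    return("'labels' must have one entry per scene point")
  ids <- sort(unique(object@labels[object@labels > 0L]))
  if (length(object@truthClouds) != length(ids))
    return("one truth cloud per seed id is required")
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("seed ids must be consecutive integers starting at 1")
  TRUE
})

#' ShapeModel: a PCA-based statistical shape model
#'
#' Built from an n x p phenotype matrix: standardization constants, the
#' correlation-matrix eigen spectrum, the retained component count m (smallest
#' m whose cumulative explained variance reaches the threshold), loadings
#' scaled by sqrt(eigenvalue), per-phenotype importance and normalized
#' weights summing to one.
#'
#' @slot columns character, phenotype column names.
#' @slot signs numeric (+1/-1) indicator directions applied before scaling.
#' @slot center,scale numeric p-vectors of standardization constants.
#' @slot eigenvalues numeric descending p-vector.
#' @slot m integer retained component count.
#' @slot threshold numeric cumulative-variance threshold used to choose m.
#' @slot loadings numeric p x m matrix.
#' @slot importance numeric p-vector of composite importances.
#' @slot weights numeric p-vector, non-negative, summing to 1.
#' @export
setClass("ShapeModel",
  representation(columns = "character", signs = "numeric", center = "numeric",
                 scale = "numeric", eigenvalues = "numeric", m = "integer",
                 threshold = "numeric", loadings = "matrix",
                 importance = "numeric", weights = "numeric"))

setValidity("ShapeModel", function(object) {
  p <- length(object@columns)
  if (length(object@weights) != p || length(object@center) != p ||
      length(object@scale) != p || length(object@eigenvalues) != p)
    return("inconsistent dimensions")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be descending")
  if (any(object@eigenvalues < -1e-9))
    return("eigenvalues must be non-negative")
  if (any(object@weights < 0))
    return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  ev <- object@eigenvalues
  if (sum(ev[seq_len(object@m)]) / sum(ev) < object@threshold - 1e-12)
    return("retained components fail the cumulative-variance threshold")
  TRUE
})
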