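#' @rdname PointCloud-class
#' @param object,x a \linkS4class{PointCloud}.
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname PointCloud-class
#' @export
setGeneric("cloudNormals", function(x) standardGeneric("cloudNormals"))

#' @rdname PointCloud-class
#' @export
setGeneric("cloudLabel", function(x) standardGeneric("cloudLabel"))

#' @rdname PointCloud-class
#' @export
setGeneric("cloudMetadata", function(x) standardGeneric("cloudMetadata"))

#' @rdname PointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname SeedScene-class
#' @export
setGeneric("sceneCloud", function(x) standardGeneric("sceneCloud"))

#' @rdname SeedScene-class
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname SeedScene-class
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname ShapeModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname ShapeModel-class
#' @export
setGeneric("modelLoadings", function(x) standardGeneric("modelLoadings"))

#' @rdname ShapeModel-class
#' @export
setGeneric("modelEigenvalues", function(x) standardGeneric("modelEigenvalues"))

#' @rdname ShapeModel-class
#' @export
setGeneric("modelComponents", function(x) standardGeneric("modelComponents"))
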