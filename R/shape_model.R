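#' @name shape-model
#' @title PCA-based statistical shape models with normalized trait weights
#'
#' @description
#' A seed population's phenotype matrix (n seeds x p traits) is turned into a
#' composite shape model: indicator signs are applied, columns are
#' standardized to zero mean and unit sample sd, the correlation matrix
#' R = Z'Z/(n-1) is eigendecomposed, the smallest m components reaching the
#' cumulative explained-variance threshold (default 80\%) are retained, and
#' per-trait weights are derived from the variance-proportion-weighted
#' absolute loadings and normalized to sum to one. Two models are typically
#' built per population: one over the 11 size-related traits and one over
#' the 22 shape-related traits.
NULL

#' Standardize a phenotype matrix
#'
#' Applies the indicator signs (negative indicators are negated before
#' scaling) and standardizes every column to mean 0, sample sd 1.
#'
#' @param x numeric matrix or data frame (n x p), no missing values.
#' @param signs length-p vector of +1/-1 indicator directions (default all
#'   +1).
#' @return list with \code{Z} (standardized matrix), \code{center},
#'   \code{scale} and \code{signs}.
#' @export
standardizePhenotypes <- function(x, signs = NULL) {
  X <- as.matrix(x)
  if (any(!is.finite(X))) stop("phenotype matrix contains missing values")
  p <- ncol(X)
  if (is.null(signs)) signs <- rep(1, p)
  if (length(signs) != p || !all(signs %in% c(-1, 1)))
    stop("'signs' must be a length-p vector of +1/-1")
  Y <- sweep(X, 2, signs, `*`)
  ctr <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(X)[sdv == 0] %||% which(sdv == 0)
    stop(sprintf("zero-variance column(s): %s", paste(bad, collapse = ", ")))
  }
  Z <- sweep(sweep(Y, 2, ctr), 2, sdv, `/`)
  list(Z = Z, center = ctr, scale = sdv, signs = signs)
}

#' Eigendecomposition of the sample correlation matrix
#'
#' R = Z'Z/(n-1) of the standardized matrix; eigenvalues descending. Their
#' sum equals p (the trace of a correlation matrix).
#'
#' @param Z a standardized matrix from \code{\link{standardizePhenotypes}}.
#' @return list with \code{values} and \code{vectors}.
#' @export
correlationPCA <- function(Z) {
  Z <- as.matrix(Z)
  R <- crossprod(Z) / (nrow(Z) - 1)
  eg <- eigen(R, symmetric = TRUE)
  list(values = pmax(eg$values, 0), vectors = eg$vectors)
}

#' Number of components reaching a cumulative-variance threshold
#'
#' @param eigenvalues descending non-negative eigenvalues.
#' @param threshold required information utilization rate (default 0.8).
#' @return the smallest m with cumulative variance >= threshold.
#' @export
chooseComponents <- function(eigenvalues, threshold = 0.8) {
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Build a statistical shape model from a phenotype matrix
#'
#' @param x numeric matrix or data frame (n seeds x p traits) with column
#'   names.
#' @param threshold cumulative explained-variance threshold for retaining
#'   components.
#' @param signs indicator directions, see
#'   \code{\link{standardizePhenotypes}}.
#' @return a \linkS4class{ShapeModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3) %*% matrix(c(1, .5, .2, 0, 1, .4, 0, 0, 1), 3)
#' colnames(X) <- c("a", "b", "c")
#' m <- buildShapeModel(X)
#' sum(modelWeights(m))
#' @export
buildShapeModel <- function(x, threshold = 0.8, signs = NULL) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n < p)
    warning(sprintf("only %d samples for %d traits: model may be unstable", n, p))
  st <- standardizePhenotypes(X, signs)
  pca <- correlationPCA(st$Z)
  m <- chooseComponents(pca$values, threshold)
  lam <- pca$values[seq_len(m)]
  # loadings: eigenvector components scaled by sqrt(eigenvalue)
  U <- pca$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m, m)
  # composite importance: variance-proportion weighted absolute loadings
  prop <- lam / sum(lam)
  a <- as.vector(abs(U) %*% prop)
  w <- a / sum(a)
  new("ShapeModel", columns = colnames(X), signs = st$signs,
      center = st$center, scale = st$scale, eigenvalues = pca$values,
      m = m, threshold = threshold, loadings = U, importance = a,
      weights = w)
}

#' @rdname ShapeModel-class
#' @export
setMethod("modelWeights", "ShapeModel", function(x)
  stats::setNames(x@weights, x@columns))

#' @rdname ShapeModel-class
#' @export
setMethod("modelLoadings", "ShapeModel", function(x) {
  L <- x@loadings
  rownames(L) <- x@columns
  L
})

#' @rdname ShapeModel-class
#' @export
setMethod("modelEigenvalues", "ShapeModel", function(x) x@eigenvalues)

#' @rdname ShapeModel-class
#' @export
setMethod("modelComponents", "ShapeModel", function(x) x@m)

setMethod("show", "ShapeModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("ShapeModel over %d traits: %d component(s) retained (%.1f%% variance)\n",
              length(object@columns), object@m,
              100 * sum(ev[seq_len(object@m)]) / sum(ev)))
  w <- sort(modelWeights(object), decreasing = TRUE)
  top <- utils::head(w, 5)
  cat("  top weights:", paste(sprintf("%s %.3f", names(top), top),
                              collapse = ", "), "\n")
})

#' Composite evaluation score of a phenotype record under a model
#'
#' The weighted sum of the record's standardized, sign-adjusted trait values
#' with the model's normalized weights: zero for a record at the training
#' mean, one for a record one sd above the mean on every trait.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param record named numeric vector, one-row data frame, or matrix of
#'   records covering the model's columns.
#' @return numeric score(s).
#' @export
compositeScore <- function(model, record) {
  if (is.data.frame(record)) record <- as.matrix(record)
  if (is.null(dim(record))) record <- matrix(record, 1,
                                             dimnames = list(NULL, names(record)))
  if (!all(model@columns %in% colnames(record)))
    stop(sprintf("record is missing trait(s): %s",
                 paste(setdiff(model@columns, colnames(record)), collapse = ", ")))
  X <- record[, model@columns, drop = FALSE]
  Y <- sweep(X, 2, model@signs, `*`)
  Z <- sweep(sweep(Y, 2, model@center), 2, model@scale, `/`)
  as.vector(Z %*% model@weights)
}

#' Serialize a shape model to JSON
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeShapeModel <- function(model, path) {
  obj <- list(columns = model@columns, signs = model@signs,
              mean = model@center, sd = model@scale,
              eigenvalues = model@eigenvalues, m = model@m,
              threshold = model@threshold,
              loadings = unname(apply(model@loadings, 1, as.numeric,
                                      simplify = FALSE)),
              importance = model@importance, weights = model@weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model from JSON
#'
#' @param path file written by \code{\link{writeShapeModel}}.
#' @return a \linkS4class{ShapeModel}.
#' @export
readShapeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- if (is.matrix(obj$loadings)) obj$loadings else
    do.call(rbind, lapply(obj$loadings, as.numeric))
  if (!is.matrix(L)) L <- matrix(L, nrow = length(obj$columns))
  new("ShapeModel", columns = obj$columns, signs = as.numeric(obj$signs),
      center = as.numeric(obj$mean), scale = as.numeric(obj$sd),
      eigenvalues = as.numeric(obj$eigenvalues), m = as.integer(obj$m),
      threshold = as.numeric(obj$threshold), loadings = L,
      importance = as.numeric(obj$importance),
      weights = as.numeric(obj$weights))
}
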