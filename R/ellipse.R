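#' @name ellipse-fitting
#' @title Constrained direct least-squares ellipse fitting
#'
#' @description
#' The completion stage represents every cross-sectional profile by the conic
#' \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} fitted by minimizing the
#' algebraic distance subject to the ellipticity constraint
#' \eqn{4ac - b^2 = 1}, solved through a generalized eigensystem. The
#' constraint makes the fit ellipse-specific: even heavily scattered or
#' partial arcs always return an ellipse. The numerically stable
#' block-partitioned formulation is used on centred, RMS-scaled coordinates
#' and the conic is mapped back to the data frame, then rescaled so the
#' constraint holds exactly.
NULL

# conic record constructor; coefficients normalized so 4ac - b^2 = 1
conic <- function(a, b, c, d, e, f) {
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f),
            class = "seedscan_conic")
}

#' @export
print.seedscan_conic <- function(x, ...) {
  cat(sprintf("conic: %.6g x^2 + %.6g xy + %.6g y^2 + %.6g x + %.6g y + %.6g = 0\n",
              x$a, x$b, x$c, x$d, x$e, x$f))
  cat(sprintf("  4ac - b^2 = %.12f\n", 4 * x$a * x$c - x$b^2))
  invisible(x)
}

# ellipse parameter record: centre (mm), semi-axes (mm), rotation in [0, pi)
ellipseParams <- function(center, semiMajor, semiMinor, angle) {
  if (semiMinor > semiMajor) {
    tmp <- semiMajor; semiMajor <- semiMinor; semiMinor <- tmp
    angle <- angle + pi / 2
  }
  angle <- angle %% pi
  if (semiMinor <= 0) stop("semi-axes must be positive")
  structure(list(center = as.numeric(center), semiMajor = semiMajor,
                 semiMinor = semiMinor, angle = angle),
            class = "seedscan_ellipse")
}

#' @export
print.seedscan_ellipse <- function(x, ...) {
  cat(sprintf("ellipse: centre (%.4g, %.4g), semi-axes %.4g / %.4g mm, angle %.4g rad\n",
              x$center[1], x$center[2], x$semiMajor, x$semiMinor, x$angle))
  invisible(x)
}

#' Fit an ellipse-specific conic to 2D points
#'
#' @param points2d M x 2 numeric matrix (mm), M >= 6, not all collinear.
#' @return a conic coefficient record (class \code{seedscan_conic}) with
#'   \eqn{4ac - b^2 = 1} exactly after normalization.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 37)[-37]
#' cn <- fitEllipseDirect(cbind(3 * cos(th), 3 * sin(th)))
#' conicToEllipse(cn)
#' @rdname ellipse-fitting
#' @export
fitEllipseDirect <- function(points2d) {
  P <- as.matrix(points2d)
  if (ncol(P) != 2) stop("'points2d' must have two columns")
  if (nrow(P) < 6) stop("degenerate input: at least 6 points are required")
  if (!all(is.finite(P))) stop("coordinates must be finite")

  x0 <- mean(P[, 1]); y0 <- mean(P[, 2])
  s <- sqrt(mean((P[, 1] - x0)^2 + (P[, 2] - y0)^2))
  if (s < .Machine$double.eps^0.5) stop("degenerate input: zero spread")
  u <- (P[, 1] - x0) / s
  v <- (P[, 2] - y0) / s

  D1 <- cbind(u * u, u * v, v * v)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate input: rank-deficient design matrix"))
  M <- S1 + S2 %*% Tm
  # apply inverse constraint matrix C1^-1 for constraint 4ac - b^2 = 1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("degenerate input: no ellipse solution")
  a1 <- V[, ok[1]]
  co <- c(a1, as.vector(Tm %*% a1)) # (A, B, C, D, E, F) in scaled frame
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Fc <- co[6]

  # map back to the original frame: u = (x - x0)/s, v = (y - y0)/s
  a <- A / s^2
  b <- B / s^2
  cc <- C / s^2
  d <- D / s - (2 * A * x0 + B * y0) / s^2
  e <- E / s - (B * x0 + 2 * C * y0) / s^2
  f <- Fc + (A * x0^2 + B * x0 * y0 + C * y0^2) / s^2 - (D * x0 + E * y0) / s

  disc <- 4 * a * cc - b^2
  if (disc <= 0) stop("degenerate input: fitted conic is not an ellipse")
  k <- 1 / sqrt(disc)
  conic(a * k, b * k, cc * k, d * k, e * k, f * k)
}

#' Convert a conic to geometric ellipse parameters
#'
#' @param cn a \code{seedscan_conic}.
#' @return an ellipse parameter record (centre, semi-axes, rotation).
#' @rdname ellipse-fitting
#' @export
conicToEllipse <- function(cn) {
  a <- cn$a; b <- cn$b; cc <- cn$c; d <- cn$d; e <- cn$e; f <- cn$f
  if (b^2 - 4 * a * cc >= 0) stop("conic is not an ellipse")
  M <- matrix(c(a, b / 2, b / 2, cc), 2, 2)
  cen <- solve(2 * M, -c(d, e))
  F0 <- as.numeric(t(cen) %*% M %*% cen) + d * cen[1] + e * cen[2] + f
  eg <- eigen(M, symmetric = TRUE) # values descending
  ax2 <- -F0 / eg$values
  if (any(ax2 <= 0)) stop("conic has no real ellipse locus")
  # smaller eigenvalue -> larger semi-axis
  semiMajor <- sqrt(ax2[2])
  semiMinor <- sqrt(ax2[1])
  vmaj <- eg$vectors[, 2]
  ellipseParams(cen, semiMajor, semiMinor, atan2(vmaj[2], vmaj[1]))
}

#' Convert ellipse parameters to a normalized conic
#'
#' @param el a \code{seedscan_ellipse}.
#' @rdname ellipse-fitting
#' @export
ellipseToConic <- function(el) {
  ct <- cos(el$angle); st <- sin(el$angle)
  R <- matrix(c(ct, st, -st, ct), 2, 2)
  M <- R %*% diag(c(1 / el$semiMajor^2, 1 / el$semiMinor^2)) %*% t(R)
  a <- M[1, 1]; b <- 2 * M[1, 2]; cc <- M[2, 2]
  de <- -2 * as.vector(M %*% el$center)
  f <- as.numeric(t(el$center) %*% M %*% el$center) - 1
  k <- 1 / sqrt(4 * a * cc - b^2)
  conic(a * k, b * k, cc * k, de[1] * k, de[2] * k, f * k)
}

#' Sample points on an ellipse at given parametric angles
#'
#' The parametric angle t maps to
#' centre + semiMajor cos(t) u + semiMinor sin(t) v where u is the major-axis
#' direction.
#'
#' @param el a \code{seedscan_ellipse}.
#' @param angles numeric vector of parametric angles (radians).
#' @return length(angles) x 2 matrix.
#' @rdname ellipse-fitting
#' @export
sampleEllipse <- function(el, angles) {
  if (!all(is.finite(angles))) stop("angles must be finite")
  ct <- cos(el$angle); st <- sin(el$angle)
  xa <- el$semiMajor * cos(angles)
  yb <- el$semiMinor * sin(angles)
  cbind(el$center[1] + xa * ct - yb * st,
        el$center[2] + xa * st + yb * ct)
}

# radius of the ellipse boundary along polar angle phi measured from the
# ellipse centre (not the parametric angle)
ellipseRadiusAt <- function(el, phi) {
  psi <- phi - el$angle
  A <- el$semiMajor; B <- el$semiMinor
  A * B / sqrt((B * cos(psi))^2 + (A * sin(psi))^2)
}

# evaluate the implicit conic at 2D points
conicResidual <- function(cn, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  cn$a * x^2 + cn$b * x * y + cn$c * y^2 + cn$d * x + cn$e * y + cn$f
}
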