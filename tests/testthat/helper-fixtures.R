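# Shared fixture builders. Everything is generated in code at test time.

# quasi-uniform unit-sphere directions (independent of the package generator)
fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), z, r * sin(phi))
}

sphereCloud <- function(n = 2000, radius = 5, center = c(0, 0, 0), sd = 0) {
  P <- fibSphere(n) * radius
  P <- sweep(P, 2, center, `+`)
  if (sd > 0) P <- P + matrix(rnorm(3 * n, sd = sd), n, 3)
  pointCloud(P)
}

# dense plane patch in the y = level plane
planeCloud <- function(side = 20, spacing = 0.5, level = 0, sd = 0) {
  g <- seq(-side / 2, side / 2, by = spacing)
  P <- cbind(rep(g, times = length(g)), level, rep(g, each = length(g)))
  if (sd > 0) P[, 2] <- P[, 2] + rnorm(nrow(P), sd = sd)
  pointCloud(P)
}

randomRotation <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotateCloud <- function(cloud, R) {
  pointCloud(cloudPoints(cloud) %*% t(R))
}

# closed-form ellipse perimeter by numerical quadrature of the arc length
ellipsePerimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# Knud Thomsen ellipsoid surface area approximation (oracle for meshes)
ktArea <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# O(N^2) brute-force nearest-neighbour distances (oracle for E_r)
bruteNN <- function(query, ref) {
  apply(query, 1, function(q)
    sqrt(min(colSums((t(ref) - q)^2))))
}
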