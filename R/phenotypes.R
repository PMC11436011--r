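#' @name phenotypes
#' @title Size- and shape-related seed phenotypes
#'
#' @description
#' From the completed cloud and its watertight mesh, 11 size-related traits
#' are measured: volume V, surface area S, the bounding-box dimensions
#' L >= W >= T, and the perimeters C1..C3 and areas A1..A3 of the three
#' mutually perpendicular principal-component profiles through the seed
#' centre (horizontal L x W, transverse L x T, longitudinal W x T). From
#' them, 22 dimensionless shape traits are derived: radius ratio, geometric
#' mean diameter, roundness, needle degree, flatness, shape factor,
#' sphericity, three elongations, three circularities, three compactnesses,
#' three bounding-rectangle ratios and three bounding-rectangle-to-perimeter
#' ratios.
NULL

# cross-section of a mesh with a coordinate plane axis = level.
# in-plane 2D frames: normal Y -> (x, z); normal Z -> (x, y); normal X -> (z, y)
meshCrossSection <- function(mesh, axis, level) {
  V <- mesh@vertices
  Fc <- mesh@faces
  planes <- c(x = 1L, y = 2L, z = 3L)
  ai <- planes[[axis]]
  d <- V[, ai] - level
  # nudge the plane off any vertex it passes through exactly
  if (any(abs(d) < 1e-12)) {
    scale <- max(abs(d), 1)
    level <- level + 1e-9 * scale
    d <- V[, ai] - level
  }
  dv <- matrix(d[Fc], nrow(Fc), 3)
  sg <- dv > 0
  ns <- rowSums(sg)
  crossing <- which(ns == 1L | ns == 2L)
  if (!length(crossing)) stop("plane does not intersect the mesh")

  inplane <- switch(axis, y = c(1L, 3L), z = c(1L, 2L), x = c(3L, 2L))
  nv <- nrow(V)
  segs <- matrix(NA_real_, length(crossing), 4) # (p1, p2) in 2D
  keys <- matrix(NA_real_, length(crossing), 2) # crossed-edge ids per endpoint
  for (s in seq_along(crossing)) {
    f <- Fc[crossing[s], ]
    pts <- matrix(NA_real_, 2, 2)
    ek <- numeric(2)
    got <- 0L
    for (e in 1:3) {
      i <- f[e]; j <- f[if (e == 3) 1 else e + 1]
      di <- d[i]; dj <- d[j]
      if ((di > 0) != (dj > 0)) {
        t <- di / (di - dj)
        p <- V[i, ] + t * (V[j, ] - V[i, ])
        got <- got + 1L
        pts[got, ] <- p[inplane]
        # identify the endpoint by the undirected mesh edge it lies on:
        # exact integer matching across the two incident faces
        ek[got] <- (min(i, j) - 1) * as.double(nv) + max(i, j)
      }
    }
    if (got == 2L) {
      segs[s, ] <- c(pts[1, ], pts[2, ])
      keys[s, ] <- ek
    }
  }
  ok <- stats::complete.cases(segs)
  segs <- segs[ok, , drop = FALSE]
  keys <- keys[ok, , drop = FALSE]
  if (!nrow(segs)) stop("plane does not intersect the mesh")

  # chain segments into closed loops by matching crossed-edge ids
  k1 <- sprintf("%.0f", keys[, 1])
  k2 <- sprintf("%.0f", keys[, 2])
  ends <- data.frame(key = c(k1, k2), seg = rep(seq_len(nrow(segs)), 2),
                     end = rep(1:2, each = nrow(segs)),
                     stringsAsFactors = FALSE)
  lookup <- split(seq_len(nrow(ends)), ends$key)
  used <- logical(nrow(segs))
  loops <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    used[s0] <- TRUE
    loop <- rbind(segs[s0, 1:2], segs[s0, 3:4])
    startKey <- k1[s0]
    curKey <- k2[s0]
    while (curKey != startKey) {
      cand <- ends[lookup[[curKey]], , drop = FALSE]
      cand <- cand[!used[cand$seg], , drop = FALSE]
      if (!nrow(cand)) break # open chain: numerically unmatched endpoint
      nxt <- cand$seg[1]
      entry <- cand$end[1]
      used[nxt] <- TRUE
      loop <- rbind(loop, if (entry == 1L) segs[nxt, 3:4] else segs[nxt, 1:2])
      curKey <- if (entry == 1L) k2[nxt] else k1[nxt]
    }
    loops[[length(loops) + 1L]] <- loop
  }

  polyArea <- function(L) {
    x <- L[, 1]; y <- L[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  areas <- vapply(loops, polyArea, 1)
  L <- loops[[which.max(areas)]]
  # drop duplicated consecutive vertices introduced by the chain walk
  dup <- c(FALSE, rowSums(abs(diff(L))) < 1e-12)
  L <- L[!dup, , drop = FALSE]
  if (sum(abs(L[nrow(L), ] - L[1, ])) < 1e-12) L <- L[-nrow(L), , drop = FALSE]
  per <- sum(sqrt(rowSums((L - L[c(2:nrow(L), 1), ])^2)))
  structure(list(axis = axis, level = level, polygon = L,
                 perimeter = per, area = polyArea(L)),
            class = "seedscan_section")
}

#' @export
print.seedscan_section <- function(x, ...) {
  cat(sprintf("cross-section (normal %s at %.4g mm): C = %.4g mm, A = %.4g mm^2, %d vertices\n",
              toupper(x$axis), x$level, x$perimeter, x$area, nrow(x$polygon)))
  invisible(x)
}

#' The three principal-component profiles of a seed mesh
#'
#' Cross-sections with the three coordinate planes through the seed centre in
#' the pose-normalized frame: profile 1 (horizontal, plane normal Y) spans
#' length x width, profile 2 (transverse, normal Z) spans length x
#' thickness, profile 3 (longitudinal, normal X) spans width x thickness.
#' Each profile is the largest closed intersection loop.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh} in the normalized
#'   frame.
#' @param centroid centre point; defaults to the mesh volume centroid.
#' @return list of three cross-section records (perimeter mm, area mm^2).
#' @export
principalSections <- function(mesh, centroid = meshCentroid(mesh)) {
  list(horizontal = meshCrossSection(mesh, "y", centroid[2]),
       transverse = meshCrossSection(mesh, "z", centroid[3]),
       longitudinal = meshCrossSection(mesh, "x", centroid[1]))
}

#' Radius ratio of a mesh
#'
#' Ratio of the maximum to minimum vertex distance from the volume centroid.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param centroid centre point; defaults to the mesh volume centroid.
#' @return RR >= 1.
#' @export
radiusRatio <- function(mesh, centroid = meshCentroid(mesh)) {
  d <- sqrt(rowSums(sweep(mesh@vertices, 2, centroid)^2))
  max(d) / min(d)
}

#' Derive the 22 shape-related phenotypes from the size phenotypes
#'
#' Evaluates the dimensionless trait formulas: geometric mean
#' D = (LWT)^(1/3), roundness R = L/sqrt(WT), needle degree ND = L/W,
#' flatness F = T/W, shape factor SF = TL/W^2, sphericity
#' SP = (WT/L^2)^(1/3), elongations E1 = |(L-W)/L|, E2 = |(L-T)/L|,
#' E3 = |(T-W)/W|, circularities CRi = Ci^2/(4 pi Ai), compactnesses
#' CPi = 16 Ai / Ci^2, bounding-rectangle ratios BR1 = A1/(LW),
#' BR2 = A2/(LT), BR3 = A3/(WT) and bounding-rectangle-to-perimeter ratios
#' BP1 = C1/(2(L+W)), BP2 = C2/(2(L+T)), BP3 = C3/(2(T+W)).
#'
#' @param sizes named list or vector with V, S, L, W, T, C1..C3, A1..A3.
#' @param RR radius ratio (from \code{\link{radiusRatio}}).
#' @return named numeric vector of the 22 shape phenotypes.
#' @export
shapePhenotypes <- function(sizes, RR) {
  s <- as.list(sizes)
  L <- s$L; W <- s$W; T <- s$T
  if (any(unlist(s[c("L", "W", "T", "C1", "C2", "C3", "A1", "A2", "A3")]) <= 0))
    stop("all size phenotypes must be positive")
  c(RR = RR,
    D = (L * W * T)^(1 / 3),
    R = L / sqrt(W * T),
    ND = L / W,
    F = T / W,
    SF = T * L / W^2,
    SP = (W * T / L^2)^(1 / 3),
    E1 = abs((L - W) / L),
    E2 = abs((L - T) / L),
    E3 = abs((T - W) / W),
    CR1 = s$C1^2 / (4 * pi * s$A1),
    CR2 = s$C2^2 / (4 * pi * s$A2),
    CR3 = s$C3^2 / (4 * pi * s$A3),
    CP1 = 16 * s$A1 / s$C1^2,
    CP2 = 16 * s$A2 / s$C2^2,
    CP3 = 16 * s$A3 / s$C3^2,
    BR1 = s$A1 / (L * W),
    BR2 = s$A2 / (L * T),
    BR3 = s$A3 / (W * T),
    BP1 = s$C1 / (2 * (L + W)),
    BP2 = s$C2 / (2 * (L + T)),
    BP3 = s$C3 / (2 * (T + W)))
}

#' Phenotype column names and their variable codes
#'
#' The 33 phenotypes in canonical order together with their variable codes
#' (X_01..X_011 for the size set, X_1..X_22 for the shape set).
#'
#' @return named character vector: names are variable codes, values are
#'   trait symbols.
#' @export
phenotypeVariables <- function() {
  c(X_01 = "V", X_02 = "S", X_03 = "L", X_04 = "W", X_05 = "T",
    X_06 = "C1", X_07 = "C2", X_08 = "C3", X_09 = "A1", X_010 = "A2",
    X_011 = "A3",
    X_1 = "RR", X_2 = "D", X_3 = "R", X_4 = "ND", X_5 = "F", X_6 = "SF",
    X_7 = "SP", X_8 = "E1", X_9 = "E2", X_10 = "E3", X_11 = "CR1",
    X_12 = "CR2", X_13 = "CR3", X_14 = "CP1", X_15 = "CP2", X_16 = "CP3",
    X_17 = "BR1", X_18 = "BR2", X_19 = "BR3", X_20 = "BP1", X_21 = "BP2",
    X_22 = "BP3")
}

#' All 33 phenotypes of one seed
#'
#' Measures the full trait record from a pose-normalized completed cloud and
#' its watertight mesh: V and S from the mesh, L/W/T from the cloud's
#' axis-aligned bounding box, C1..C3 and A1..A3 from the principal sections,
#' and the 22 derived shape phenotypes.
#'
#' @param cloud the pose-normalized completed \linkS4class{PointCloud}.
#' @param mesh the reconstructed watertight \linkS4class{TriangleMesh}.
#' @return one-row \code{data.frame} with 33 named columns.
#' @export
phenotypeRecord <- function(cloud, mesh) {
  dims <- aabbDims(cloud)
  ctr <- meshCentroid(mesh)
  secs <- principalSections(mesh, ctr)
  sizes <- list(V = meshVolume(mesh), S = meshSurfaceArea(mesh),
                L = dims[["L"]], W = dims[["W"]], T = dims[["T"]],
                C1 = secs$horizontal$perimeter,
                C2 = secs$transverse$perimeter,
                C3 = secs$longitudinal$perimeter,
                A1 = secs$horizontal$area,
                A2 = secs$transverse$area,
                A3 = secs$longitudinal$area)
  shp <- shapePhenotypes(sizes, radiusRatio(mesh, ctr))
  as.data.frame(c(sizes, as.list(shp)))
}
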