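#' @name cloud-io
#' @title Point-cloud and mesh file input/output
#'
#' @description
#' Readers and writers for the plain formats used by scanners and mesh tools:
#' PLY (ASCII and binary little-endian on input, ASCII on output for
#' diffability), whitespace-separated XYZ for clouds, and PLY/OBJ/STL for
#' triangle meshes. All coordinates are in millimetres; point order is
#' preserved.
NULL

# parse a PLY header; returns list(format, elements = list(name, count, props))
parsePlyHeader <- function(con, path) {
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply"))
    stop(sprintf("malformed PLY '%s': missing 'ply' magic at line 1", path))
  fmt <- NULL
  elements <- list()
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (!length(ln))
      stop(sprintf("malformed PLY '%s': header not terminated (line %d)", path, lineno))
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (!length(elements))
        stop(sprintf("malformed PLY '%s': property before element (line %d)", path, lineno))
      i <- length(elements)
      elements[[i]]$props[[length(elements[[i]]$props) + 1L]] <-
        if (tok[2] == "list") list(list = TRUE, countType = tok[3],
                                   itemType = tok[4], name = tok[5])
        else list(list = FALSE, type = tok[2], name = tok[3])
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop(sprintf("malformed PLY '%s': unexpected token '%s' (line %d)",
                   path, tok[1], lineno))
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s' in '%s'", fmt %||% "<none>", path))
  list(format = fmt, elements = elements, headerLines = lineno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plyTypeSize <- function(type) {
  switch(type,
         char = , int8 = , uchar = , uint8 = 1L,
         short = , int16 = , ushort = , uint16 = 2L,
         int = , int32 = , uint = , uint32 = , float = , float32 = 4L,
         double = , float64 = 8L,
         stop(sprintf("unsupported PLY type '%s'", type)))
}

plyReadBin <- function(con, type, n) {
  sz <- plyTypeSize(type)
  what <- if (type %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  readBin(con, what, n = n, size = sz, endian = "little", signed = signed)
}

readPlyFile <- function(path, needFaces = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- parsePlyHeader(con, path)
  vertices <- NULL; normals <- NULL; faces <- NULL
  for (el in hd$elements) {
    pnames <- vapply(el$props, function(p) p$name, "")
    if (hd$format == "ascii") {
      if (el$name == "vertex") {
        dat <- matrix(scan(con, what = numeric(), n = el$count * length(el$props),
                           quiet = TRUE), ncol = length(el$props), byrow = TRUE)
        if (nrow(dat) != el$count)
          stop(sprintf("malformed PLY '%s': expected %d vertex records", path, el$count))
        colnames(dat) <- pnames
        vertices <- dat
      } else if (el$name == "face") {
        faces <- matrix(NA_integer_, el$count, 3)
        for (i in seq_len(el$count)) {
          cnt <- scan(con, what = integer(), n = 1, quiet = TRUE)
          idx <- scan(con, what = integer(), n = cnt, quiet = TRUE)
          if (cnt != 3L)
            stop(sprintf("malformed PLY '%s': non-triangular face record %d", path, i))
          faces[i, ] <- idx + 1L
        }
      } else {
        # skip unknown ascii element line-wise
        readLines(con, n = el$count)
      }
    } else { # binary little endian
      if (el$name == "vertex") {
        if (any(vapply(el$props, function(p) p$list, TRUE)))
          stop(sprintf("unsupported list property in vertex element of '%s'", path))
        types <- vapply(el$props, function(p) p$type, "")
        dat <- matrix(NA_real_, el$count, length(types))
        # row-wise records: read one full record block per vertex
        for (i in seq_len(el$count))
          for (j in seq_along(types))
            dat[i, j] <- plyReadBin(con, types[j], 1L)
        colnames(dat) <- pnames
        vertices <- dat
      } else if (el$name == "face") {
        faces <- matrix(NA_integer_, el$count, 3)
        p <- el$props[[1]]
        for (i in seq_len(el$count)) {
          cnt <- plyReadBin(con, p$countType, 1L)
          idx <- plyReadBin(con, p$itemType, cnt)
          if (cnt != 3L)
            stop(sprintf("malformed PLY '%s': non-triangular face record %d", path, i))
          faces[i, ] <- idx + 1L
        }
      } else {
        sz <- sum(vapply(el$props, function(p) plyTypeSize(p$type), 1L))
        invisible(readBin(con, "raw", n = el$count * sz))
      }
    }
  }
  if (is.null(vertices)) stop(sprintf("PLY '%s' contains no vertex element", path))
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vertices)))
    stop(sprintf("PLY '%s' lacks x/y/z vertex properties", path))
  pts <- vertices[, need, drop = FALSE]
  if (all(c("nx", "ny", "nz") %in% colnames(vertices))) {
    normals <- vertices[, c("nx", "ny", "nz"), drop = FALSE]
    nn <- sqrt(rowSums(normals^2))
    if (any(nn == 0) || any(abs(nn - 1) > 1e-3)) normals <- NULL
    else normals <- normals / nn
  }
  list(points = pts, normals = normals, faces = faces)
}

#' Read a point cloud from PLY or XYZ
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"ply"} or \code{"xyz"}.
#' @return a \linkS4class{PointCloud} with coordinates as stored, order
#'   preserved.
#' @rdname cloud-io
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (format == "ply") {
    dat <- readPlyFile(path)
    if (nrow(dat$points) == 0) stop(sprintf("empty point cloud in '%s'", path))
    pointCloud(dat$points, normals = dat$normals,
               label = sub("\\.[^.]*$", "", basename(path)))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop(sprintf("empty point cloud in '%s'", path))
    rows <- lapply(seq_along(lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) < 3 || any(is.na(v[1:3])))
        stop(sprintf("malformed XYZ '%s': cannot parse line %d", path, i))
      v
    })
    ncolz <- min(vapply(rows, length, 1L))
    M <- do.call(rbind, lapply(rows, function(v) v[seq_len(ncolz)]))
    normals <- NULL
    if (ncolz >= 6) {
      normals <- M[, 4:6, drop = FALSE]
      nn <- sqrt(rowSums(normals^2))
      normals <- if (any(nn == 0) || any(abs(nn - 1) > 1e-3)) NULL else normals / nn
    }
    pointCloud(M[, 1:3, drop = FALSE], normals = normals,
               label = sub("\\.[^.]*$", "", basename(path)))
  }
}

#' Write a point cloud to PLY (ASCII) or XYZ
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @rdname cloud-io
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  P <- cloudPoints(cloud)
  N <- cloudNormals(cloud)
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(P)),
             "property float x", "property float y", "property float z")
    if (!is.null(N))
      hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
    hdr <- c(hdr, "end_header")
    body <- if (is.null(N)) P else cbind(P, N)
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(body, digits = 9, scientific = FALSE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    body <- if (is.null(N)) P else cbind(P, N)
    utils::write.table(format(body, digits = 9, scientific = FALSE, trim = TRUE),
                       path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a triangle mesh (PLY, OBJ or ASCII STL)
#'
#' @rdname cloud-io
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("ply", "obj", "stl")) ext else
      stop(sprintf("cannot infer mesh format of '%s'", path))
  }
  if (format == "ply") {
    dat <- readPlyFile(path, needFaces = TRUE)
    if (is.null(dat$faces)) stop(sprintf("PLY '%s' contains no face element", path))
    triangleMesh(dat$points, dat$faces)
  } else if (format == "obj") {
    lines <- readLines(path)
    vs <- grep("^v\\s", lines, value = TRUE)
    fs <- grep("^f\\s", lines, value = TRUE)
    if (!length(vs) || !length(fs))
      stop(sprintf("malformed OBJ '%s': missing v/f records", path))
    V <- do.call(rbind, lapply(vs, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
    Fc <- do.call(rbind, lapply(fs, function(l) {
      tok <- strsplit(trimws(l), "\\s+")[[1]][-1]
      as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
    }))
    triangleMesh(V, Fc)
  } else { # ascii stl: merge duplicate vertices
    lines <- readLines(path)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3 != 0)
      stop(sprintf("malformed STL '%s'", path))
    V <- do.call(rbind, lapply(vl, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
    key <- apply(round(V, 9), 1, paste, collapse = "/")
    uid <- !duplicated(key)
    map <- match(key, key[uid])
    triangleMesh(V[uid, , drop = FALSE], matrix(map, ncol = 3, byrow = TRUE))
  }
}

#' Write a triangle mesh (ASCII PLY, OBJ or STL)
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @rdname cloud-io
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("ply", "obj", "stl")) ext else
      stop(sprintf("cannot infer mesh format of '%s'", path))
  }
  V <- meshVertices(mesh)
  Fc <- meshFaces(mesh)
  con <- file(path, "wt")
  on.exit(close(con))
  fmtV <- format(V, digits = 9, scientific = FALSE, trim = TRUE)
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(Fc)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(fmtV, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, Fc - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (format == "obj") {
    utils::write.table(cbind("v", fmtV), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    utils::write.table(cbind("f", Fc), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    writeLines("solid seedscan", con)
    for (i in seq_len(nrow(Fc))) {
      tri <- V[Fc[i, ], , drop = FALSE]
      nrm <- crossProduct3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(nrm^2))
      if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid seedscan", con)
  }
  invisible(path)
}

crossProduct3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
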