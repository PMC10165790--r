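#' Read a triangulated surface mesh
#'
#' Reads STL (binary or ASCII, auto-detected), PLY (ASCII or
#' binary-little-endian) or OBJ (geometry only). After parsing, duplicate
#' vertices within 1e-6 mm are merged and degenerate faces dropped; counts are
#' recorded in the mesh metadata (`mergedVertices`, `droppedFaces`).
#' Coordinates are taken to be millimetres; no unit autodetection is
#' attempted.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"stl"`, `"ply"` or `"obj"`.
#' @return a [SurfaceMesh-class].
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(tolower(format[1]), c("auto", "stl", "ply", "obj"))
  if (!file.exists(path)) stop("readMesh: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("readMesh: cannot infer format from extension '", ext, "'")
    format <- ext
  }
  raw <- switch(format,
    stl = readSTL(path),
    ply = readPLY(path),
    obj = readOBJ(path))
  m <- surfaceMesh(raw$vertices, raw$faces, clean = TRUE,
                   metadata = list(source = path, format = format))
  if (nFaces(m) == 0L)
    stop("readMesh: mesh is empty after cleaning: ", path)
  m
}

#' Write a triangulated surface mesh
#'
#' STL is written in the binary format (32-bit float coordinates, so
#' round-trip accuracy is about 1e-5 mm at torso scale); PLY and OBJ are
#' written as ASCII with full double precision.
#'
#' @param mesh a [SurfaceMesh-class]; must be non-empty.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"stl"`, `"ply"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nFaces(mesh) == 0L || nVertices(mesh) == 0L)
    stop("writeMesh: refusing to write an empty mesh")
  format <- match.arg(tolower(format[1]), c("auto", "stl", "ply", "obj"))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("writeMesh: cannot infer format from extension '", ext, "'")
    format <- ext
  }
  switch(format,
    stl = writeSTL(mesh, path),
    ply = writePLY(mesh, path),
    obj = writeOBJ(mesh, path))
  invisible(path)
}

## ---- STL ----

readSTL <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 320)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  isAscii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (isAscii) readSTLascii(path) else readSTLbinary(path)
}

readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("readMesh: malformed ASCII STL: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  V <- do.call(rbind, nums)
  if (any(!is.finite(V))) stop("readMesh: non-numeric vertex in STL: ", path)
  n <- nrow(V) / 3L
  F <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  list(vertices = V, faces = F)
}

readSTLbinary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0 || sz < 84 + 50 * as.numeric(ntri))
    stop("readMesh: corrupt binary STL: ", path)
  body <- readBin(con, "raw", 50 * ntri)
  if (length(body) < 50 * ntri) stop("readMesh: truncated binary STL: ", path)
  body <- matrix(body, nrow = 50)
  coords <- readBin(as.raw(body[13:48, ]), "numeric", 9L * ntri,
                    size = 4, endian = "little")
  V <- matrix(coords, ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = V, faces = F)
}

writeSTL <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  ntri <- nrow(F)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("writeMesh: cannot open ", path))
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  # per-facet normal from winding
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  block <- t(cbind(nrm, a, b, c3))  # 12 floats per facet
  floats <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  floats <- matrix(floats, nrow = 48)
  out <- rbind(floats, matrix(as.raw(0), 2, ntri))
  writeBin(as.vector(out), con)
}

## ---- PLY ----

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readPLYline(con)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 500) stop("readMesh: PLY header not terminated")
  }
  if (!grepl("^ply", header[1])) stop("readMesh: not a PLY file: ", path)
  fmtLine <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmtLine)
  if (!binary && !grepl("ascii", fmtLine))
    stop("readMesh: unsupported PLY format: ", fmtLine)

  # parse element/property structure
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <-
          list(name = tok[5], list = TRUE, countType = tok[3], type = tok[4])
      } else {
        elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("readMesh: PLY lacks vertex/face elements: ", path)

  if (binary) readPLYbinary(con, elems) else readPLYascii(con, elems)
}

readPLYline <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("readMesh: unexpected EOF in PLY header")
    if (b == as.raw(10)) break
    chars <- c(chars, b)
  }
  sub("\r$", "", rawToChar(chars))
}

plySizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
              short = 2, ushort = 2, int16 = 2, uint16 = 2,
              int = 4, uint = 4, int32 = 4, uint32 = 4,
              float = 4, float32 = 4, double = 8, float64 = 8)
plyIsFloat <- function(t) t %in% c("float", "float32", "double", "float64")

readPLYbinary <- function(con, elems) {
  readOne <- function(type) {
    sz <- plySizes[[type]]
    if (is.null(sz)) stop("readMesh: unsupported PLY type ", type)
    if (plyIsFloat(type))
      readBin(con, "numeric", 1, size = sz, endian = "little")
    else
      readBin(con, "integer", 1, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  nv <- elems$vertex$count
  vp <- elems$vertex$props
  V <- matrix(NA_real_, nv, 3)
  cols <- vapply(vp, function(p) p$name, "")
  xyz <- match(c("x", "y", "z"), cols)
  if (any(is.na(xyz))) stop("readMesh: PLY vertex element lacks x/y/z")
  # fast path: all scalar vertex props, identical float type
  allScalar <- all(!vapply(vp, function(p) p$list, TRUE))
  types <- vapply(vp, function(p) p$type, "")
  if (allScalar && length(unique(types)) == 1L && plyIsFloat(types[1])) {
    sz <- plySizes[[types[1]]]
    dat <- readBin(con, "numeric", nv * length(vp), size = sz,
                   endian = "little")
    dat <- matrix(dat, ncol = length(vp), byrow = TRUE)
    V <- dat[, xyz, drop = FALSE]
  } else {
    for (i in seq_len(nv)) {
      row <- vapply(vp, function(p) {
        if (p$list) {
          k <- readOne(p$countType)
          for (j in seq_len(k)) readOne(p$type)
          NA_real_
        } else as.numeric(readOne(p$type))
      }, 0)
      V[i, ] <- row[xyz]
    }
  }
  nf <- elems$face$count
  fp <- elems$face$props
  Flist <- vector("list", nf)
  for (i in seq_len(nf)) {
    poly <- NULL
    for (p in fp) {
      if (p$list) {
        k <- readOne(p$countType)
        idx <- vapply(seq_len(k), function(j) as.numeric(readOne(p$type)), 0)
        if (p$name %in% c("vertex_indices", "vertex_index")) poly <- idx
      } else readOne(p$type)
    }
    Flist[[i]] <- poly
  }
  list(vertices = V, faces = triangulateFans(Flist))
}

readPLYascii <- function(con, elems) {
  body <- readLines(con, warn = FALSE)
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$count; nf <- elems$face$count
  if (length(body) < nv + nf) stop("readMesh: truncated ASCII PLY")
  cols <- vapply(elems$vertex$props, function(p) p$name, "")
  xyz <- match(c("x", "y", "z"), cols)
  if (any(is.na(xyz))) stop("readMesh: PLY vertex element lacks x/y/z")
  vdat <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                   function(x) as.numeric(x[xyz]), numeric(3)))
  Flist <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                  function(x) {
                    k <- as.integer(x[1])
                    as.numeric(x[1 + seq_len(k)])
                  })
  list(vertices = vdat, faces = triangulateFans(Flist))
}

# 0-based polygon index vectors -> 1-based triangle fan matrix
triangulateFans <- function(polys) {
  tris <- lapply(polys, function(p) {
    if (is.null(p) || length(p) < 3) return(NULL)
    p <- p + 1
    cbind(p[1], p[2:(length(p) - 1)], p[3:length(p)])
  })
  out <- do.call(rbind, tris)
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

writePLY <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("writeMesh: cannot open ", path))
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

## ---- OBJ ----

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("readMesh: OBJ without geometry: ", path)
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  nv <- nrow(V)
  Flist <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- vapply(x[-1], function(tok) {
      i <- as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1])
      if (is.na(i)) stop("readMesh: bad OBJ face token: ", tok)
      if (i < 0) nv + i + 1L else i
    }, 0L)
    idx - 1  # triangulateFans expects 0-based
  })
  list(vertices = V, faces = triangulateFans(Flist))
}

writeOBJ <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("writeMesh: cannot open ", path))
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
}
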