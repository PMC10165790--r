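#' Construct a SurfaceMesh
#'
#' Builds a [SurfaceMesh-class] from raw vertex and face arrays, optionally
#' applying the standard cleaning pass: duplicate vertices within
#' `mergeTol` mm are merged and degenerate faces (repeated indices or area
#' below `areaTol` mm^2) are dropped. The counts of merges and drops are
#' recorded in the mesh metadata.
#'
#' @param vertices numeric matrix n x 3 (mm).
#' @param faces integer matrix m x 3, 1-based vertex indices.
#' @param clean merge duplicate vertices and drop degenerate faces
#'   (default `TRUE`).
#' @param mergeTol vertex merge tolerance in mm (default `1e-6`).
#' @param areaTol degenerate-face area threshold in mm^2 (default `1e-12`).
#' @param metadata optional list of extra metadata.
#' @return a [SurfaceMesh-class].
#' @examples
#' m <- surfaceMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)),
#'                  matrix(c(1L, 2L, 3L), 1))
#' nFaces(m)
#' @export
surfaceMesh <- function(vertices, faces, clean = TRUE,
                        mergeTol = 1e-6, areaTol = 1e-12,
                        metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0, 3)
  if (length(faces) == 0L) faces <- matrix(integer(0), 0, 3)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  merged <- 0L; dropped <- 0L
  if (clean && nrow(vertices) > 0L) {
    # snap to a mergeTol grid; coincident vertices collapse to one index
    key <- paste(round(vertices[, 1] / mergeTol),
                 round(vertices[, 2] / mergeTol),
                 round(vertices[, 3] / mergeTol))
    first <- !duplicated(key)
    merged <- sum(!first)
    map <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    if (nrow(faces) > 0L) {
      faces <- matrix(map[faces], ncol = 3L)
      storage.mode(faces) <- "integer"
    }
    if (nrow(faces) > 0L) {
      degenIdx <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
        faces[, 1] == faces[, 3]
      areas <- cpp_face_areas(vertices, faces)
      degen <- degenIdx | areas < areaTol
      dropped <- sum(degen)
      faces <- faces[!degen, , drop = FALSE]
    }
  }
  metadata$mergedVertices <- merged
  metadata$droppedFaces <- dropped
  new("SurfaceMesh", vertices = vertices, faces = faces, metadata = metadata)
}

#' Construct a Plane3
#'
#' @param point a point on the plane (length-3, mm).
#' @param normal plane normal; normalised to unit length.
#' @return a [Plane3-class].
#' @examples
#' plane3(c(0, 0, 0), c(2, 0, 0))  # x = 0 plane
#' @export
plane3 <- function(point, normal) {
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("plane normal must be non-zero")
  new("Plane3", point = as.numeric(point), normal = as.numeric(normal) / n)
}

#' Construct a RigidTransform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#'   (default identity).
#' @param translation length-3 translation in mm (default zero).
#' @return a [RigidTransform-class].
#' @examples
#' rigidTransform(translation = c(10, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = unname(as.matrix(rotation)),
      translation = as.numeric(translation))
}

#' Rotation matrix about a coordinate axis
#'
#' @param angleDeg rotation angle in degrees.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return 3x3 rotation matrix.
#' @examples
#' axisRotation(90, "z") %*% c(1, 0, 0)  # ~ (0, 1, 0)
#' @export
axisRotation <- function(angleDeg, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  a <- angleDeg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, c2, -s2), c(0, s2, c2)),
    y = rbind(c(c2, 0, s2), c(0, 1, 0), c(-s2, 0, c2)),
    z = rbind(c(c2, -s2, 0), c(s2, c2, 0), c(0, 0, 1)))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeRigid <- function(second, first) {
  rigidTransform(second@rotation %*% first@rotation,
                 as.numeric(second@rotation %*% first@translation) +
                   second@translation)
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertRigid <- function(t) {
  Rt <- t(t@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% t@translation))
}

#' Construct an ICP configuration
#'
#' @param maxIterations maximum iterations (default 100).
#' @param convergenceTol RMS-residual change threshold in mm (default 1e-4).
#' @param sampleSize area-weighted surface samples (default 5000).
#' @param seed integer RNG seed (required; sampling is otherwise random).
#' @return an [IcpConfig-class].
#' @export
icpConfig <- function(maxIterations = 100L, convergenceTol = 1e-4,
                      sampleSize = 5000L, seed) {
  if (missing(seed)) stop("icpConfig: an explicit seed is required")
  new("IcpConfig", maxIterations = as.integer(maxIterations),
      convergenceTol = as.numeric(convergenceTol),
      sampleSize = as.integer(sampleSize), seed = as.integer(seed))
}
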