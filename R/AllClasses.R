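#' @useDynLib BraceMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SurfaceMesh: a triangulated 3D surface
#'
#' The carrier for torso scans and brace models. Vertices are 3D points in
#' millimetres; faces are triangles given as 1-based vertex-index triples with
#' consistent winding (outward normals for watertight meshes, i.e. signed
#' volume > 0). The coordinate convention used throughout the package is
#' +x = patient left, +y = anterior, +z = superior.
#'
#' @slot vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @slot metadata list; cleaning reports (`mergedVertices`, `droppedFaces`)
#'   and provenance attached by [readMesh()] and the generators.
#'
#' @seealso [surfaceMesh()], [readMesh()], [isWatertight()], [enclosedVolume()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", metadata = "list"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            metadata = list())
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (!is.numeric(v)) return("vertices must be numeric")
  if (nrow(f) > 0L) {
    if (any(!is.finite(f))) return("face indices must be finite")
    if (any(f < 1L) || any(f > nrow(v)))
      return("face indices out of range")
  }
  if (nrow(v) > 0L && any(!is.finite(v)))
    return("vertex coordinates must be finite")
  TRUE
})

#' Plane in 3D
#'
#' A plane defined by a point on it and a unit normal. Used for the mirroring
#' (mid-sagittal) plane and for the coronal/sagittal segment midplanes.
#'
#' @slot point numeric length-3, a point on the plane (mm).
#' @slot normal numeric length-3, unit normal.
#' @export
setClass("Plane3",
  representation(point = "numeric", normal = "numeric"),
  prototype(point = c(0, 0, 0), normal = c(1, 0, 0))
)

setValidity("Plane3", function(object) {
  if (length(object@point) != 3L || length(object@normal) != 3L)
    return("point and normal must have length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length (within 1e-9)")
  TRUE
})

#' Rigid-body transform
#'
#' Rotation (proper orthonormal 3x3 matrix) followed by translation; the
#' output of ICP registration.
#'
#' @slot rotation 3x3 numeric matrix, orthonormal with determinant +1.
#' @slot translation numeric length-3 (mm).
#' @seealso [rigidTransform()], [composeRigid()], [invertRigid()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0))
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (within 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (determinant +1)")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  TRUE
})

#' ICP configuration
#'
#' Parameters of the point-to-point iterative closest point registration.
#'
#' @slot maxIterations maximum iterations (>= 1).
#' @slot convergenceTol stop when the change in RMS residual falls below this
#'   value (mm, > 0).
#' @slot sampleSize number of area-weighted surface sample points (>= 100).
#' @slot seed integer RNG seed for the surface sampling.
#' @seealso [icpConfig()], [icpRegister()]
#' @export
setClass("IcpConfig",
  representation(maxIterations = "integer", convergenceTol = "numeric",
                 sampleSize = "integer", seed = "integer"),
  prototype(maxIterations = 100L, convergenceTol = 1e-4,
            sampleSize = 5000L, seed = 1L)
)

setValidity("IcpConfig", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@convergenceTol <= 0) return("convergenceTol must be > 0")
  if (object@sampleSize < 100L) return("sampleSize must be >= 100")
  if (is.na(object@seed)) return("seed is required")
  TRUE
})

#' Result of the asymmetry-index pipeline
#'
#' Holds the asymmetry percentage together with all intermediates of the
#' mirror -> register -> trim -> volume chain.
#'
#' @slot asymmetryPercent 100 * interSurfaceVolume / totalVolume.
#' @slot interSurfaceVolume volume of the Boolean symmetric difference of the
#'   trimmed original and registered mirror solids (mm^3).
#' @slot totalVolume enclosed volume of the trimmed original (mm^3).
#' @slot mirrorPlane the mirroring [Plane3-class] used.
#' @slot icpTransform cumulative [RigidTransform-class] from ICP.
#' @slot icpRmsResidual final RMS point-to-surface residual (mm).
#' @slot icpIterations iterations used.
#' @slot trimInterval numeric length-2, (zmin, zmax) of the common slab (mm).
#' @slot voxelPitch voxel pitch used for the symmetric difference (mm).
#' @seealso [asymmetryIndex()]
#' @export
setClass("AsymmetryResult",
  representation(asymmetryPercent = "numeric", interSurfaceVolume = "numeric",
                 totalVolume = "numeric", mirrorPlane = "Plane3",
                 icpTransform = "RigidTransform", icpRmsResidual = "numeric",
                 icpIterations = "integer", trimInterval = "numeric",
                 voxelPitch = "numeric")
)

setValidity("AsymmetryResult", function(object) {
  if (object@totalVolume <= 0) return("totalVolume must be positive")
  expect <- 100 * object@interSurfaceVolume / object@totalVolume
  if (abs(object@asymmetryPercent - expect) > 1e-9 * max(1, abs(expect)))
    return("asymmetryPercent inconsistent with volume ratio")
  if (object@asymmetryPercent < 0) return("asymmetryPercent must be >= 0")
  TRUE
})

#' Signed torso-to-brace displacement field
#'
#' One signed distance per torso vertex: positive where the brace surface lies
#' inside the torso (pressure zone), negative where it lies outside
#' (expansion zone), zero on contact.
#'
#' @slot values numeric, one signed distance (mm) per torso vertex.
#' @slot mesh the torso [SurfaceMesh-class] the field lives on.
#' @seealso [signedDisplacementField()], [segmentPeaks()]
#' @export
setClass("DisplacementField",
  representation(values = "numeric", mesh = "SurfaceMesh")
)

setValidity("DisplacementField", function(object) {
  if (length(object@values) != nrow(object@mesh@vertices))
    return("one value per torso vertex required")
  TRUE
})

#' Per-segment peak displacements
#'
#' Peak positive and peak negative displacement for each of the 12 torso
#' segments (ALU ... PRL). Peaks default to 0 when a segment holds no value of
#' that sign.
#'
#' @slot peaks data.frame with columns `segment`, `peakPositive`,
#'   `peakNegative`, `nVertices`, `empty`.
#' @seealso [segmentPeaks()], [segmentCodes()]
#' @export
setClass("SegmentPeaks", representation(peaks = "data.frame"))

setValidity("SegmentPeaks", function(object) {
  p <- object@peaks
  need <- c("segment", "peakPositive", "peakNegative", "nVertices", "empty")
  if (!all(need %in% names(p))) return("missing peak table columns")
  if (nrow(p) != 12L) return("exactly 12 segments required")
  if (!identical(as.character(p$segment), segmentCodes()))
    return("segments must be the 12 codes in canonical order")
  if (any(p$peakPositive < 0) || any(p$peakNegative > 0))
    return("peakPositive must be >= 0 and peakNegative <= 0")
  TRUE
})
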