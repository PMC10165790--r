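#' @describeIn BraceMorph-generics vertex matrix of a SurfaceMesh
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @describeIn BraceMorph-generics face index matrix of a SurfaceMesh
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' @describeIn BraceMorph-generics number of vertices
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @describeIn BraceMorph-generics number of faces
#' @export
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))

#' @describeIn BraceMorph-generics metadata list (cleaning report etc.)
#' @export
setMethod("meshMetadata", "SurfaceMesh", function(x) x@metadata)

#' @describeIn BraceMorph-generics signed per-vertex displacement values (mm)
#' @export
setMethod("fieldValues", "DisplacementField", function(x) x@values)

#' @describeIn BraceMorph-generics torso mesh carried by a displacement field
#' @export
setMethod("meshVertices", "DisplacementField", function(x) x@mesh@vertices)

#' @describeIn BraceMorph-generics 12-row per-segment peak table
#' @export
setMethod("peaksTable", "SegmentPeaks", function(x) x@peaks)

#' @describeIn BraceMorph-generics asymmetry percentage of an AsymmetryResult
#' @export
setMethod("asymmetryPercent", "AsymmetryResult", function(x) x@asymmetryPercent)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices) > 0) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    wt <- tryCatch(isWatertight(object), error = function(e) NA)
    cat(sprintf("  watertight: %s\n", ifelse(isTRUE(wt), "yes",
                                             ifelse(isFALSE(wt), "no", "?"))))
  }
  invisible(NULL)
})

setMethod("show", "Plane3", function(object) {
  cat(sprintf("Plane3: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              object@point[1], object@point[2], object@point[3],
              object@normal[1], object@normal[2], object@normal[3]))
  invisible(NULL)
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
  invisible(NULL)
})

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf("AsymmetryResult: %.3f %%\n", object@asymmetryPercent))
  cat(sprintf("  inter-surface volume: %.1f mm^3 / total volume %.1f mm^3\n",
              object@interSurfaceVolume, object@totalVolume))
  cat(sprintf("  ICP: rms %.4f mm in %d iterations; trim z [%.1f, %.1f] mm; pitch %.1f mm\n",
              object@icpRmsResidual, object@icpIterations,
              object@trimInterval[1], object@trimInterval[2],
              object@voxelPitch))
  invisible(NULL)
})

setMethod("show", "DisplacementField", function(object) {
  v <- object@values
  cat(sprintf("DisplacementField on %d vertices: %.1f%% pressure (+), %.1f%% expansion (-)\n",
              length(v), 100 * mean(v > 0), 100 * mean(v < 0)))
  cat(sprintf("  range [%.2f, %.2f] mm\n", min(v), max(v)))
  invisible(NULL)
})

setMethod("show", "SegmentPeaks", function(object) {
  cat("SegmentPeaks (mm):\n")
  print(object@peaks, row.names = FALSE, digits = 4)
  invisible(NULL)
})

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return rotation angle in degrees, in \[0, 180\].
#' @keywords internal
rotationAngleDeg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}
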