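#' The 12 canonical torso segment codes
#'
#' (A|P)(L|R)(U|M|L): anterior/posterior x patient-left/right x
#' upper/mid/lower, in the conventional reporting order.
#'
#' @return character vector of 12 codes (ALU ... PRL).
#' @export
segmentCodes <- function() {
  c("ALU", "ARU", "ALM", "ARM", "ALL", "ARL",
    "PLU", "PRU", "PLM", "PRM", "PLL", "PRL")
}

#' Signed torso-to-brace displacement field
#'
#' For every torso vertex, the Euclidean distance to the closest point on the
#' brace surface, signed by where that closest point lies relative to the
#' torso solid: inside the torso means the brace presses in (+, pressure
#' zone); outside means the brace gives the torso room (-, expansion zone);
#' within `tol` of the torso surface means contact (0). No registration is
#' performed - the meshes are assumed to share a coordinate frame (in the
#' clinical workflow the orthotist aligns the brace model on the scan); set
#' `preAlign` to run a rigid ICP of the brace onto the torso first.
#'
#' @param torso a watertight [SurfaceMesh-class] (watertightness is needed
#'   for the sign).
#' @param brace a non-empty [SurfaceMesh-class].
#' @param tol contact tolerance in mm (default 1e-6).
#' @param preAlign optional [IcpConfig-class]; if supplied, the brace is
#'   rigidly pre-registered onto the torso (off by default).
#' @return a [DisplacementField-class] on the torso vertices.
#' @export
signedDisplacementField <- function(torso, brace, tol = 1e-6,
                                    preAlign = NULL) {
  if (nFaces(brace) == 0L) stop("signedDisplacementField: empty brace mesh")
  open <- openEdgeCount(torso)
  if (open > 0L)
    stop("signedDisplacementField: torso is not watertight (", open,
         " open edges)")
  if (!is.null(preAlign)) {
    reg <- icpRegister(brace, torso, preAlign)
    brace <- applyRigid(brace, reg$transform)
  }
  cp <- cpp_closest_points(brace@vertices, brace@faces, torso@vertices)
  q <- cp[, 1:3, drop = FALSE]
  d <- cp[, 4]
  w <- cpp_winding_number(torso@vertices, torso@faces, q)
  sgn <- ifelse(d <= tol, 0, ifelse(abs(w) > 0.5, 1, -1))
  new("DisplacementField", values = sgn * d, mesh = torso)
}

#' Partition torso vertices into the 12 segments
#'
#' The torso z-range is split into equal-height upper/mid/lower bands at 1/3
#' and 2/3; a coronal midplane through the vertex centroid (normal +y)
#' separates anterior from posterior; the sagittal midplane (given, or
#' through the centroid with normal +x) separates patient-left from right.
#' Band and plane boundaries are assigned to the lower / posterior / right
#' side (half-open convention), so every vertex receives exactly one label.
#'
#' @param torso a non-empty [SurfaceMesh-class].
#' @param sagittal optional [Plane3-class] (for example the estimate from
#'   [estimateMidsagittalPlane()]); default is the centroid x-plane.
#' @return factor of length `nVertices(torso)` with the 12 levels of
#'   [segmentCodes()].
#' @export
partitionSegments <- function(torso, sagittal = NULL) {
  V <- torso@vertices
  if (nrow(V) == 0L) stop("partitionSegments: empty mesh")
  ctr <- colMeans(V)
  zr <- range(V[, 3])
  h <- diff(zr)
  zrel <- V[, 3] - zr[1]
  band <- ifelse(zrel > 2 * h / 3, "U", ifelse(zrel > h / 3, "M", "L"))
  ap <- ifelse(V[, 2] > ctr[2], "A", "P")
  if (is.null(sagittal)) {
    lr <- ifelse(V[, 1] > ctr[1], "L", "R")
  } else {
    s <- as.numeric(V %*% sagittal@normal) - sum(sagittal@point * sagittal@normal)
    lr <- ifelse(s > 0, "L", "R")
  }
  factor(paste0(ap, lr, band), levels = segmentCodes())
}

#' Peak positive and negative displacement per segment
#'
#' For each of the 12 segments, the maximum positive (pressure) and minimum
#' negative (expansion) displacement; a segment with no value of a given sign
#' scores 0 for that peak. Segments with no vertices at all are flagged.
#'
#' @param field a [DisplacementField-class].
#' @param labels per-vertex segment factor from [partitionSegments()], on the
#'   same torso.
#' @return a [SegmentPeaks-class].
#' @export
segmentPeaks <- function(field, labels) {
  v <- field@values
  if (length(v) != length(labels))
    stop("segmentPeaks: field and labels must cover the same vertices")
  codes <- segmentCodes()
  pp <- pn <- numeric(12)
  nvert <- integer(12)
  empty <- logical(12)
  for (i in seq_along(codes)) {
    x <- v[labels == codes[i]]
    nvert[i] <- length(x)
    if (length(x) == 0L) {
      empty[i] <- TRUE
      next
    }
    pos <- x[x > 0]; neg <- x[x < 0]
    pp[i] <- if (length(pos)) max(pos) else 0
    pn[i] <- if (length(neg)) min(neg) else 0
  }
  if (any(empty))
    warning("segmentPeaks: empty segments: ",
            paste(codes[empty], collapse = ", "))
  new("SegmentPeaks",
      peaks = data.frame(segment = codes, peakPositive = pp,
                         peakNegative = pn, nVertices = nvert,
                         empty = empty, stringsAsFactors = FALSE))
}
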