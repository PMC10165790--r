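#' Estimate the mid-sagittal (mirroring) plane
#'
#' Deterministic automation of the manual mirror-plane placement: the plane
#' passes through the vertex centroid and its normal is the principal axis of
#' the vertex cloud most aligned with the left-right (x) direction, re-signed
#' to +x. The dominant principal direction is taken as the longitudinal axis.
#' An explicit plane override is accepted by every caller that uses this
#' estimate.
#'
#' @param mesh a non-empty [SurfaceMesh-class].
#' @return a [Plane3-class].
#' @details Errors when the vertex covariance is rank-deficient; warns when
#'   two principal variances are nearly equal (the lateral axis is then
#'   arbitrary, as for a sphere).
#' @export
estimateMidsagittalPlane <- function(mesh) {
  V <- mesh@vertices
  if (nrow(V) < 4L) stop("estimateMidsagittalPlane: mesh too small")
  ctr <- colMeans(V)
  cv <- stats::cov(V)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] < 1e-9 * eg$values[1])
    stop("estimateMidsagittalPlane: degenerate vertex distribution (rank < 3 covariance)")
  if (min(abs(diff(eg$values))) < 1e-6 * eg$values[1])
    warning("estimateMidsagittalPlane: near-isotropic covariance; lateral axis is arbitrary")
  # exclude the dominant (longitudinal) axis; among the rest, pick the one
  # most aligned with +-x
  cand <- eg$vectors[, 2:3, drop = FALSE]
  ax <- which.max(abs(cand[1, ]))
  n <- cand[, ax]
  if (n[1] < 0) n <- -n
  plane3(ctr, n)
}

#' Point-to-point ICP registration
#'
#' Registers `source` onto `target`: area-weighted sample points on the
#' source are matched to their exact closest points on the target surface and
#' the least-squares rigid transform is solved in closed form (SVD/Kabsch) at
#' each iteration. Stops when the change in RMS residual drops below
#' `convergenceTol` or after `maxIterations`. Fully deterministic for a fixed
#' config seed.
#'
#' @param source,target non-empty [SurfaceMesh-class] objects.
#' @param cfg an [IcpConfig-class].
#' @return list with `transform` (cumulative [RigidTransform-class] mapping
#'   source onto target), `rmsResidual` (mm), `iterations`, and `converged`
#'   (`"tol"`, `"max-iterations"` or `"stalled"`; the latter flags five
#'   consecutive non-decreasing residuals and is a warning state, not an
#'   error).
#' @export
icpRegister <- function(source, target, cfg) {
  stopifnot(is(cfg, "IcpConfig"))
  if (nFaces(source) == 0L || nFaces(target) == 0L)
    stop("icpRegister: empty mesh")
  P0 <- sampleSurface(source, cfg@sampleSize, cfg@seed)
  P <- P0
  Vt <- target@vertices; Ft <- target@faces
  Rcum <- diag(3); tcum <- c(0, 0, 0)
  prevRms <- Inf
  stalled <- 0L
  status <- "max-iterations"
  iters <- 0L
  rms <- NA_real_
  for (it in seq_len(cfg@maxIterations)) {
    iters <- it
    cp <- cpp_closest_points(Vt, Ft, P)
    Q <- cp[, 1:3, drop = FALSE]
    rms <- sqrt(mean(cp[, 4]^2))
    if (is.finite(prevRms)) {
      if (abs(prevRms - rms) < cfg@convergenceTol) { status <- "tol"; break }
      if (rms >= prevRms) stalled <- stalled + 1L else stalled <- 0L
      if (stalled >= 5L) { status <- "stalled"; break }
    }
    prevRms <- rms
    # Kabsch: best rigid P -> Q
    mp <- colMeans(P); mq <- colMeans(Q)
    H <- crossprod(P - matrix(mp, nrow(P), 3, byrow = TRUE),
                   Q - matrix(mq, nrow(Q), 3, byrow = TRUE))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rk <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tk <- mq - as.numeric(Rk %*% mp)
    P <- P %*% t(Rk) + matrix(tk, nrow(P), 3, byrow = TRUE)
    Rcum <- Rk %*% Rcum
    tcum <- as.numeric(Rk %*% tcum) + tk
  }
  if (status == "stalled")
    warning("icpRegister: residual non-decreasing for 5 iterations; returning best-so-far")
  list(transform = rigidTransform(Rcum, tcum),
       rmsResidual = rms, iterations = iters, converged = status)
}

#' Trim two meshes to equal length
#'
#' Slices both meshes (capped, watertight) to the intersection of their
#' z-ranges so that they cover the same longitudinal extent.
#'
#' @param original,registeredMirror watertight [SurfaceMesh-class] objects
#'   whose z-ranges overlap by at least 10 percent of the larger range.
#' @return list with `original`, `mirror` (trimmed meshes) and
#'   `trimInterval` (zmin, zmax).
#' @export
trimToEqualLength <- function(original, registeredMirror) {
  r1 <- range(original@vertices[, 3])
  r2 <- range(registeredMirror@vertices[, 3])
  lo <- max(r1[1], r2[1]); hi <- min(r1[2], r2[2])
  bigger <- max(diff(r1), diff(r2))
  if (hi - lo < 0.10 * bigger)
    stop("trimToEqualLength: z-overlap ", signif(max(0, hi - lo), 4),
         " mm is less than 10% of the larger range (", signif(bigger, 4), " mm)")
  list(original = sliceZ(original, lo, hi, cap = TRUE),
       mirror = sliceZ(registeredMirror, lo, hi, cap = TRUE),
       trimInterval = c(lo, hi))
}

#' Volume between two watertight solids (Boolean symmetric difference)
#'
#' Voxelizes both solids on a common grid spanning the union of their
#' bounding boxes and counts cells whose center is contained in exactly one
#' solid; the result is count x pitch^3 and converges to the exact Boolean
#' symmetric-difference volume as the pitch shrinks. Occupancy uses
#' vertical-ray parity per grid column, exact for watertight meshes up to
#' the grid resolution.
#'
#' @param a,b watertight [SurfaceMesh-class] objects.
#' @param voxelPitch grid pitch in mm (> 0); default 2.
#' @param maxCells guard on the total grid size (default 2e8).
#' @return volume in mm^3.
#' @export
interSurfaceVolume <- function(a, b, voxelPitch = 2, maxCells = 2e8) {
  if (voxelPitch <= 0) stop("interSurfaceVolume: voxelPitch must be > 0")
  for (m in list(a, b)) {
    open <- openEdgeCount(m)
    if (open > 0L)
      stop("interSurfaceVolume: mesh is not watertight (", open, " open edges)")
  }
  lo <- pmin(apply(a@vertices, 2, min), apply(b@vertices, 2, min)) - voxelPitch
  hi <- pmax(apply(a@vertices, 2, max), apply(b@vertices, 2, max)) + voxelPitch
  n <- pmax(1L, as.integer(ceiling((hi - lo) / voxelPitch)))
  if (prod(as.numeric(n)) > maxCells)
    stop("interSurfaceVolume: grid of ", format(prod(as.numeric(n)), big.mark = ","),
         " cells exceeds budget; use a larger voxelPitch")
  # deterministic sub-voxel offsets keep rays off shared triangle edges
  ex <- voxelPitch * 1.04917e-6
  ey <- voxelPitch * 2.33681e-6
  occA <- cpp_voxel_occupancy(a@vertices, a@faces, lo[1], lo[2], lo[3],
                              voxelPitch, n[1], n[2], n[3], ex, ey)
  occB <- cpp_voxel_occupancy(b@vertices, b@faces, lo[1], lo[2], lo[3],
                              voxelPitch, n[1], n[2], n[3], ex, ey)
  sum(xor(occA, occB)) * voxelPitch^3
}

#' Torso / brace asymmetry index
#'
#' The full mirror-image asymmetry chain: estimate (or take) the mid-sagittal
#' plane, mirror the mesh across it, register the mirror back onto the
#' original with ICP, trim both to equal length, and report the volume
#' enclosed between the two surfaces (Boolean symmetric difference) divided
#' by the enclosed volume of the trimmed original, as a percentage. An
#' exactly mirror-symmetric solid scores ~0; the score grows with lateral
#' deviation and rib-hump-like features.
#'
#' @param mesh a watertight [SurfaceMesh-class].
#' @param cfg an [IcpConfig-class] for the mirror registration.
#' @param voxelPitch voxel pitch for the symmetric-difference volume
#'   (mm, default 2).
#' @param planeOverride optional [Plane3-class]; skips the automatic
#'   mid-sagittal estimate.
#' @return an [AsymmetryResult-class].
#' @examples
#' \donttest{
#' torso <- generateTorso(torsoParams(humpAmplitude = 12))
#' asymmetryIndex(torso, icpConfig(seed = 1))
#' }
#' @export
asymmetryIndex <- function(mesh, cfg, voxelPitch = 2, planeOverride = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("asymmetryIndex [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  open <- openEdgeCount(mesh)
  if (open > 0L)
    stop("asymmetryIndex: mesh is not watertight (", open, " open edges)")
  plane <- if (is.null(planeOverride))
    stage("plane", estimateMidsagittalPlane(mesh))
  else planeOverride
  mirrored <- stage("mirror", reflectMesh(mesh, plane))
  reg <- stage("icp", icpRegister(mirrored, mesh, cfg))
  mirrorReg <- stage("transform", applyRigid(mirrored, reg$transform))
  trimmed <- stage("trim", trimToEqualLength(mesh, mirrorReg))
  inter <- stage("volume",
                 interSurfaceVolume(trimmed$original, trimmed$mirror, voxelPitch))
  total <- stage("volume", enclosedVolume(trimmed$original))
  new("AsymmetryResult",
      asymmetryPercent = 100 * inter / total,
      interSurfaceVolume = inter, totalVolume = total,
      mirrorPlane = plane, icpTransform = reg$transform,
      icpRmsResidual = reg$rmsResidual,
      icpIterations = as.integer(reg$iterations),
      trimInterval = trimmed$trimInterval, voxelPitch = voxelPitch)
}
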