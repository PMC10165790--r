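#' Watertightness of a mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite directions (consistent winding) and so encloses a
#' well-defined solid.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return logical.
#' @seealso [openEdgeCount()]
#' @export
isWatertight <- function(mesh) {
  openEdgeCount(mesh) == 0L
}

#' Count of open (non-manifold or boundary) edges
#'
#' Edges that are not shared by exactly one pair of oppositely-directed face
#' edges.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer count; 0 for a watertight mesh.
#' @export
openEdgeCount <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0L) return(0L)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  dir <- ifelse(e[, 1] < e[, 2], 1L, -1L)
  cnt <- table(key)
  bal <- tapply(dir, key, sum)
  # need each undirected edge twice, once per direction
  sum(cnt != 2L | bal[names(cnt)] != 0L)
}

#' Reflect a mesh across a plane
#'
#' Householder reflection of every vertex; face winding is reversed so the
#' outward orientation (and hence the sign of the enclosed volume) is
#' preserved.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param plane a [Plane3-class].
#' @return the reflected [SurfaceMesh-class].
#' @export
reflectMesh <- function(mesh, plane) {
  stopifnot(is(plane, "Plane3"))
  V <- reflectPoints(mesh@vertices, plane)
  F <- mesh@faces[, c(1, 3, 2), drop = FALSE]
  new("SurfaceMesh", vertices = V, faces = F, metadata = mesh@metadata)
}

#' Reflect points across a plane
#'
#' @param points numeric matrix n x 3 or a length-3 vector.
#' @param plane a [Plane3-class].
#' @return reflected points, same shape as the input.
#' @examples
#' reflectPoints(c(3, 1, 1), plane3(c(1, 0, 0), c(1, 0, 0)))  # (-1, 1, 1)
#' @export
reflectPoints <- function(points, plane) {
  vec <- is.null(dim(points))
  P <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  n <- plane@normal
  d <- as.numeric(P %*% n) - sum(plane@point * n)
  out <- P - 2 * outer(d, n)
  if (vec) as.numeric(out) else out
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are rotated then translated; topology is unchanged, and the
#' enclosed volume is preserved.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param t a [RigidTransform-class].
#' @return transformed [SurfaceMesh-class].
#' @export
applyRigid <- function(mesh, t) {
  stopifnot(is(t, "RigidTransform"))
  V <- applyRigidPoints(mesh@vertices, t)
  new("SurfaceMesh", vertices = V, faces = mesh@faces,
      metadata = mesh@metadata)
}

#' Apply a rigid transform to points
#'
#' @param points numeric matrix n x 3 or a length-3 vector.
#' @param t a [RigidTransform-class].
#' @return transformed points, same shape as the input.
#' @export
applyRigidPoints <- function(points, t) {
  vec <- is.null(dim(points))
  P <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- P %*% t(t@rotation) +
    matrix(t@translation, nrow(P), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem signed volume; positive for outward orientation.
#'
#' @param mesh a watertight [SurfaceMesh-class].
#' @param requireOutward error on negative (inward-oriented) volume when
#'   `TRUE` (default); otherwise the signed value is returned.
#' @return volume in mm^3.
#' @export
enclosedVolume <- function(mesh, requireOutward = TRUE) {
  open <- openEdgeCount(mesh)
  if (open > 0L)
    stop("enclosedVolume: mesh is not watertight (", open, " open edges)")
  vol <- cpp_signed_volume(mesh@vertices, mesh@faces)
  if (requireOutward && vol < 0)
    stop("enclosedVolume: mesh is inward-oriented (signed volume ",
         format(vol), " mm^3); fix winding or set requireOutward = FALSE")
  vol
}

#' Total surface area of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return area in mm^2.
#' @export
surfaceArea <- function(mesh) {
  sum(cpp_face_areas(mesh@vertices, mesh@faces))
}

#' Exact closest point on a triangle mesh
#'
#' For each query point, the closest point anywhere on the triangle set
#' (vertex, edge or face interior), found through a uniform-grid spatial
#' index; distances are Euclidean and non-negative.
#'
#' @param mesh a non-empty [SurfaceMesh-class].
#' @param query length-3 vector or n x 3 matrix of query points (mm).
#' @return for a single query, a list with `point`, `distance`, `face`;
#'   for a matrix, a list with `points` (n x 3), `distances`, `faces`.
#' @export
nearestPointOnSurface <- function(mesh, query) {
  if (nFaces(mesh) == 0L) stop("nearestPointOnSurface: empty mesh")
  vec <- is.null(dim(query))
  Q <- if (vec) matrix(query, 1, 3) else as.matrix(query)
  res <- cpp_closest_points(mesh@vertices, mesh@faces, Q)
  if (vec)
    list(point = res[1, 1:3], distance = res[1, 4], face = as.integer(res[1, 5]))
  else
    list(points = res[, 1:3, drop = FALSE], distances = res[, 4],
         faces = as.integer(res[, 5]))
}

#' Generalized winding number of query points
#'
#' Approximately 1 for points inside a watertight outward-oriented surface
#' and 0 outside; robust to small mesh defects.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param query length-3 vector or n x 3 matrix.
#' @return numeric winding numbers.
#' @export
windingNumber <- function(mesh, query) {
  vec <- is.null(dim(query))
  Q <- if (vec) matrix(query, 1, 3) else as.matrix(query)
  w <- cpp_winding_number(mesh@vertices, mesh@faces, Q)
  if (vec) w[1] else w
}

#' Inside/outside/on-surface classification
#'
#' Classifies points against a watertight solid by generalized winding number
#' (|winding| > 0.5 means inside); points within `tol` of the surface are
#' reported as `"on-surface"`.
#'
#' @param mesh a watertight [SurfaceMesh-class].
#' @param query length-3 vector or n x 3 matrix.
#' @param tol on-surface distance tolerance in mm (default 1e-6).
#' @return character vector of `"inside"`, `"outside"`, `"on-surface"`.
#' @export
pointInside <- function(mesh, query, tol = 1e-6) {
  open <- openEdgeCount(mesh)
  if (open > 0L)
    stop("pointInside: mesh is not watertight (", open, " open edges)")
  vec <- is.null(dim(query))
  Q <- if (vec) matrix(query, 1, 3) else as.matrix(query)
  d <- cpp_closest_points(mesh@vertices, mesh@faces, Q)[, 4]
  w <- cpp_winding_number(mesh@vertices, mesh@faces, Q)
  out <- ifelse(d <= tol, "on-surface",
                ifelse(abs(w) > 0.5, "inside", "outside"))
  if (vec) out[1] else out
}

#' Slice a mesh to a z slab
#'
#' Clips all triangles to `zmin <= z <= zmax`. With `cap = TRUE`, planar caps
#' are added at the cut planes so a watertight input yields a watertight
#' output (cap polygons are fan-triangulated about their centroid, which is
#' exact for the star-shaped cross-sections of torso-like solids); with
#' `cap = FALSE` an open shell suitable for distance queries is returned.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param zmin,zmax slab bounds in mm, `zmin < zmax`.
#' @param cap close the cut planes (default `TRUE`).
#' @return the sliced [SurfaceMesh-class].
#' @export
sliceZ <- function(mesh, zmin, zmax, cap = TRUE) {
  if (!(zmin < zmax)) stop("sliceZ: zmin must be < zmax")
  V <- mesh@vertices; F <- mesh@faces
  zr <- range(V[, 3])
  if (zmax <= zr[1] || zmin >= zr[2])
    stop("sliceZ: slab [", zmin, ", ", zmax, "] does not intersect mesh z-range [",
         signif(zr[1], 8), ", ", signif(zr[2], 8), "]")
  snapTol <- 1e-9 * max(1, diff(zr))

  polys <- vector("list", nrow(F))
  for (i in seq_len(nrow(F))) {
    P <- V[F[i, ], , drop = FALSE]
    z <- P[, 3]
    z[abs(z - zmin) < snapTol] <- zmin
    z[abs(z - zmax) < snapTol] <- zmax
    P[, 3] <- z
    P <- clipPolyZ(P, zmin, +1)
    if (!is.null(P)) P <- clipPolyZ(P, zmax, -1)
    polys[[i]] <- P
  }
  polys <- polys[!vapply(polys, is.null, TRUE)]
  if (length(polys) == 0L) stop("sliceZ: empty result")

  # fan-triangulate clipped polygons
  triList <- lapply(polys, function(P) {
    n <- nrow(P)
    if (n < 3) return(NULL)
    do.call(rbind, lapply(2:(n - 1), function(k) rbind(P[1, ], P[k, ], P[k + 1, ])))
  })
  tri <- do.call(rbind, triList)
  nt <- nrow(tri) / 3
  Vout <- tri
  Fout <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)

  if (cap) {
    for (zcut in c(zmin, zmax)) {
      capped <- capAtPlane(Vout, Fout, zcut, snapTol)
      Vout <- capped$V; Fout <- capped$F
    }
  }
  out <- surfaceMesh(Vout, Fout, clean = TRUE, metadata = mesh@metadata)
  if (nFaces(out) == 0L) stop("sliceZ: empty result after cleaning")
  out
}

# Sutherland-Hodgman clip of one polygon against side*(z - zcut) >= 0
clipPolyZ <- function(P, zcut, side) {
  n <- nrow(P)
  keep <- side * (P[, 3] - zcut) >= 0
  if (all(keep)) return(P)
  if (!any(keep)) return(NULL)
  out <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- P[i, ]; b <- P[j, ]
    ka <- keep[i]; kb <- keep[j]
    if (ka) out <- rbind(out, a)
    if (ka != kb) {
      t <- (zcut - a[3]) / (b[3] - a[3])
      out <- rbind(out, a + t * (b - a))
    }
  }
  if (nrow(out) < 3) NULL else out
}

# Add fan caps over unmatched boundary edges lying on z == zcut.
# Cap triangles reverse the boundary edge direction, which keeps the closed
# surface consistently oriented.
capAtPlane <- function(V, F, zcut, tol) {
  onPlane <- abs(V[, 3] - zcut) < tol
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  eOn <- onPlane[e[, 1]] & onPlane[e[, 2]]
  e <- e[eOn, , drop = FALSE]
  if (nrow(e) == 0L) return(list(V = V, F = F))
  # key edges geometrically (indices may duplicate coordinates pre-merge)
  pkey <- function(idx) paste(round(V[idx, 1] / 1e-6), round(V[idx, 2] / 1e-6))
  k1 <- pkey(e[, 1]); k2 <- pkey(e[, 2])
  fwd <- paste(k1, k2); rev <- paste(k2, k1)
  unmatched <- !(fwd %in% rev)
  e <- e[unmatched, , drop = FALSE]
  k1 <- k1[unmatched]; k2 <- k2[unmatched]
  if (nrow(e) == 0L) return(list(V = V, F = F))
  # chain directed boundary edges into loops
  used <- rep(FALSE, nrow(e))
  startOf <- split(seq_len(nrow(e)), k1)
  for (s in seq_len(nrow(e))) {
    if (used[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      used[cur] <- TRUE
      loop <- c(loop, cur)
      nxtKey <- k2[cur]
      cand <- startOf[[nxtKey]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      cur <- cand[1]
    }
    if (length(loop) >= 3L) {
      pts <- V[e[loop, 1], , drop = FALSE]
      centroid <- colMeans(pts)
      ci <- nrow(V) + 1L
      V <- rbind(V, centroid)
      newF <- cbind(ci, e[loop, 2], e[loop, 1])
      F <- rbind(F, newF)
    }
  }
  list(V = V, F = F)
}

#' Area-weighted surface sampling
#'
#' Draws `n` points uniformly by area from the triangle surface; fully
#' determined by `seed`.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return n x 3 matrix of points.
#' @export
sampleSurface <- function(mesh, n, seed) {
  V <- mesh@vertices; F <- mesh@faces
  areas <- cpp_face_areas(V, F)
  withSeed(seed, {
    fi <- sample.int(nrow(F), n, replace = TRUE, prob = areas)
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    a <- V[F[fi, 1], , drop = FALSE]
    b <- V[F[fi, 2], , drop = FALSE]
    c3 <- V[F[fi, 3], , drop = FALSE]
    a + u * (b - a) + v * (c3 - a)
  })
}

# evaluate code under a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  code
}

#' Vertex normals (area-weighted)
#'
#' Average of incident face normals weighted by face area, normalised to unit
#' length. Used by the brace generator to displace the surface along local
#' normals.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return n x 3 matrix of unit normals (outward for outward-oriented meshes).
#' @export
vertexNormals <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    idx <- F[, k]
    for (d in 1:3) {
      s <- rowsum(fn[, d], idx)
      N[as.integer(rownames(s)), d] <- N[as.integer(rownames(s)), d] + s[, 1]
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}
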