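#' Axis-aligned box mesh
#'
#' @param min,max opposite corners (length-3, mm).
#' @return a watertight [SurfaceMesh-class] with 8 vertices and 12 faces.
#' @examples
#' enclosedVolume(boxMesh(c(0, 0, 0), c(1, 1, 1)))  # 1
#' @export
boxMesh <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  stopifnot(all(max > min))
  g <- expand.grid(x = c(min[1], max[1]), y = c(min[2], max[2]),
                   z = c(min[3], max[3]))
  V <- as.matrix(g)
  # vertex order: (x fastest) 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),  # z = min, outward -z
    c(5, 6, 8), c(5, 8, 7),  # z = max, outward +z
    c(1, 2, 6), c(1, 6, 5),  # y = min
    c(3, 7, 8), c(3, 8, 4),  # y = max
    c(1, 5, 7), c(1, 7, 3),  # x = min
    c(2, 4, 8), c(2, 8, 6))  # x = max
  surfaceMesh(V, F, clean = FALSE)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere; a standard near-uniform
#' sphere triangulation.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions subdivision level (0 = icosahedron; each level
#'   quadruples the face count).
#' @param center sphere center (length-3).
#' @return a watertight [SurfaceMesh-class].
#' @examples
#' s <- icosphereMesh(10, 3)
#' enclosedVolume(s) / (4 / 3 * pi * 1000)  # ~ 0.995
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    newF <- matrix(0L, 0, 3)
    midCache <- new.env(hash = TRUE)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midCache[[key]])) return(midCache[[key]])
      m <- (V[i, ] + V[j, ]) / 2
      V <<- rbind(V, m)
      midCache[[key]] <- nrow(V)
      nrow(V)
    }
    out <- vector("list", nrow(F))
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c3 <- F[f, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      out[[f]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                        c(ab, bc, ca))
    }
    F <- do.call(rbind, out)
  }
  len <- sqrt(rowSums(V^2))
  V <- V / len * radius
  V <- V + matrix(center, nrow(V), 3, byrow = TRUE)
  surfaceMesh(V, F, clean = FALSE)
}

#' Capped cylinder mesh
#'
#' @param radius cylinder radius (mm).
#' @param height cylinder height; spans z in \[0, height\].
#' @param rings number of z rings.
#' @param segments points per ring.
#' @return a watertight [SurfaceMesh-class].
#' @examples
#' v <- enclosedVolume(cylinderMesh(10, 100, segments = 256))
#' v / (pi * 100 * 100)  # ~ 1
#' @export
cylinderMesh <- function(radius = 50, height = 100, rings = 24L,
                         segments = 48L) {
  generateTorso(torsoParams(height = height, halfAxisX = radius,
                            halfAxisY = radius, taper = function(t) 1,
                            rings = max(24L, rings),
                            pointsPerRing = max(24L, segments)))
}
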