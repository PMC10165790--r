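# Independent brute-force oracles used across tests.

# Closest point on one triangle by explicit candidate enumeration:
# unconstrained plane projection (if inside), each clamped edge projection,
# and each vertex. Independent of the package's branchy closest-point code.
oracleClosestOnTriangle <- function(p, a, b, c) {
  cands <- list(a, b, c)
  edge <- function(u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    u + min(1, max(0, t)) * d
  }
  cands <- c(cands, list(edge(a, b), edge(b, c), edge(c, a)))
  e1 <- b - a; e2 <- c - a
  M <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum((p - a) * e1), sum((p - a) * e2))
  if (abs(det(M)) > 1e-300) {
    uv <- solve(M, rhs)
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cands <- c(cands, list(a + uv[1] * e1 + uv[2] * e2))
  }
  d2 <- vapply(cands, function(q) sum((p - q)^2), 0)
  cands[[which.min(d2)]]
}

# Exhaustive closest point over all triangles of a mesh.
oracleClosestOnMesh <- function(mesh, p) {
  V <- meshVertices(mesh); F <- meshFaces(mesh)
  best <- Inf; bestp <- NULL
  for (f in seq_len(nrow(F))) {
    q <- oracleClosestOnTriangle(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
    d <- sqrt(sum((p - q)^2))
    if (d < best) { best <- d; bestp <- q }
  }
  list(point = bestp, distance = best)
}

# Half-space containment oracle for a convex outward-oriented mesh.
oracleInsideConvex <- function(mesh, P, tol = 1e-9) {
  V <- meshVertices(mesh); F <- meshFaces(mesh)
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  apply(P, 1, function(p) {
    s <- rowSums((matrix(p, nrow(a), 3, byrow = TRUE) - a) * n)
    all(s <= tol)
  })
}

# Classical tie-free Spearman rank formula.
oracleSpearmanTieFree <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Independent 12-segment classification by direct coordinate comparison.
oracleSegmentLabels <- function(V, ctr, zr) {
  h <- zr[2] - zr[1]
  vapply(seq_len(nrow(V)), function(i) {
    z <- V[i, 3] - zr[1]
    band <- if (z > 2 * h / 3) "U" else if (z > h / 3) "M" else "L"
    ap <- if (V[i, 2] > ctr[2]) "A" else "P"
    lr <- if (V[i, 1] > ctr[1]) "L" else "R"
    paste0(ap, lr, band)
  }, "")
}

# small convenience: scaled copy of a mesh about its vertex centroid
scaledAboutCentroid <- function(mesh, s) {
  V <- meshVertices(mesh)
  ctr <- colMeans(V)
  V2 <- sweep(sweep(V, 2, ctr), 2, rep(s, 3), "*")
  V2 <- sweep(V2, 2, ctr, "+")
  surfaceMesh(V2, meshFaces(mesh), clean = FALSE)
}
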