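test_that("reflection is an involution and matches the analytic formula", {
  p <- plane3(c(1, 0, 0), c(1, 0, 0))
  expect_equal(reflectPoints(c(3, 1, 1), p), c(-1, 1, 1))
  m <- generateTorso(torsoParams(lateralOffset = 10, humpAmplitude = 8,
                                 rings = 24, pointsPerRing = 24))
  pl <- plane3(c(5, 2, 0), c(1, 2, 0.5))
  twice <- reflectMesh(reflectMesh(m, pl), pl)
  expect_lt(max(abs(meshVertices(twice) - meshVertices(m))), 1e-9)
  # winding reversal preserves the signed volume
  expect_equal(enclosedVolume(reflectMesh(m, pl)), enclosedVolume(m),
               tolerance = 1e-12)
  # cube centered at origin reflected about x = 0: same vertex set
  cube <- boxMesh(c(-1, -1, -1), c(1, 1, 1))
  r <- reflectMesh(cube, plane3(c(0, 0, 0), c(1, 0, 0)))
  vs <- function(x) {
    v <- meshVertices(x)
    v[order(v[, 1], v[, 2], v[, 3]), ]
  }
  expect_equal(vs(r), vs(cube))
})

test_that("rigid transforms compose, invert and preserve metric quantities", {
  t1 <- rigidTransform(axisRotation(90, "z"), c(0, 0, 0))
  expect_equal(applyRigidPoints(c(1, 0, 0), t1), c(0, 1, 0), tolerance = 1e-12)
  m <- generateTorso(torsoParams(rings = 24, pointsPerRing = 24,
                                 humpAmplitude = 5))
  t2 <- rigidTransform(axisRotation(33, "x") %*% axisRotation(-20, "y"),
                       c(12, -7, 30))
  m2 <- applyRigid(m, t2)
  expect_equal(enclosedVolume(m2), enclosedVolume(m), tolerance = 1e-9)
  back <- applyRigid(m2, invertRigid(t2))
  expect_lt(max(abs(meshVertices(back) - meshVertices(m))), 1e-9)
  # identity leaves the mesh untouched
  mid <- applyRigid(m, rigidTransform())
  expect_equal(meshVertices(mid), meshVertices(m))
  # pairwise distances preserved (sample of vertex pairs)
  set.seed(4)
  i <- sample(nVertices(m), 50); j <- sample(nVertices(m), 50)
  d0 <- sqrt(rowSums((meshVertices(m)[i, ] - meshVertices(m)[j, ])^2))
  d1 <- sqrt(rowSums((meshVertices(m2)[i, ] - meshVertices(m2)[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  # composition: (t2 o t1) applied once equals sequential application
  comp <- composeRigid(t2, t1)
  expect_equal(applyRigidPoints(c(1, 2, 3), comp),
               applyRigidPoints(applyRigidPoints(c(1, 2, 3), t1), t2),
               tolerance = 1e-12)
})

test_that("enclosed volume matches analytic solids and flags bad meshes", {
  expect_equal(enclosedVolume(boxMesh(c(0, 0, 0), c(1, 1, 1))), 1,
               tolerance = 1e-12)
  s <- icosphereMesh(10, 4)
  expect_equal(enclosedVolume(s), 4 / 3 * pi * 1000, tolerance = 0.005)
  # inverted winding: error by default, signed value on request
  cube <- boxMesh(c(0, 0, 0), c(2, 2, 2))
  inv <- surfaceMesh(meshVertices(cube), meshFaces(cube)[, c(1, 3, 2)],
                     clean = FALSE)
  expect_error(enclosedVolume(inv), "inward-oriented")
  expect_equal(enclosedVolume(inv, requireOutward = FALSE), -8,
               tolerance = 1e-12)
  # open mesh: error names the open edge count
  open <- surfaceMesh(meshVertices(cube), meshFaces(cube)[-1, , drop = FALSE],
                      clean = FALSE)
  expect_false(isWatertight(open))
  expect_error(enclosedVolume(open), "3 open edges")
})

test_that("nearest point on surface equals the brute-force triangle scan", {
  m <- icosphereMesh(10, 2)  # 320 faces
  expect_equal(nFaces(m), 320L)
  # query exactly on a vertex
  v1 <- meshVertices(m)[1, ]
  r <- nearestPointOnSurface(m, v1)
  expect_equal(r$distance, 0)
  expect_equal(r$point, v1)
  # analytic: above the center of a unit square face in z = 0
  sq <- surfaceMesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)), clean = FALSE)
  r2 <- nearestPointOnSurface(sq, c(0, 0, 5))
  expect_equal(r2$distance, 5)
  expect_equal(r2$point, c(0, 0, 0))
  # 100 random queries, inside, outside and near the surface
  set.seed(11)
  Q <- matrix(runif(300, -15, 15), ncol = 3)
  res <- nearestPointOnSurface(m, Q)
  for (i in seq_len(nrow(Q))) {
    o <- oracleClosestOnMesh(m, Q[i, ])
    expect_equal(res$distances[i], o$distance, tolerance = 1e-9)
  }
})

test_that("winding-number containment agrees with the convex oracle", {
  cube <- boxMesh(c(0, 0, 0), c(1, 1, 1))
  expect_equal(pointInside(cube, c(0.5, 0.5, 0.5)), "inside")
  expect_equal(pointInside(cube, c(5, 5, 5)), "outside")
  expect_equal(pointInside(cube, c(0.5, 0.5, 1)), "on-surface")
  m <- icosphereMesh(8, 2)
  set.seed(21)
  P <- matrix(runif(3000, -10, 10), ncol = 3)
  got <- pointInside(m, P)
  want <- oracleInsideConvex(m, P)
  # exclude points within a voxel of the surface where chordal facets differ
  d <- abs(sqrt(rowSums(P^2)) - 8)
  sel <- d > 0.2
  expect_gt(sum(sel), 800)
  expect_identical(got[sel] == "inside", unname(want[sel]))
  # non-watertight input is rejected
  open <- surfaceMesh(meshVertices(cube), meshFaces(cube)[-1, ], clean = FALSE)
  expect_error(pointInside(open, c(0.5, 0.5, 0.5)), "open edges")
})

test_that("z-slab slicing conserves volume and caps watertightly", {
  cy <- cylinderMesh(10, 100, rings = 24, segments = 48)
  v0 <- enclosedVolume(cy)
  half <- sliceZ(cy, 25, 75, cap = TRUE)
  expect_true(isWatertight(half))
  expect_equal(enclosedVolume(half), v0 / 2, tolerance = 1e-6)
  # slicing to the full range keeps the volume
  full <- sliceZ(cy, -1, 101, cap = TRUE)
  expect_equal(enclosedVolume(full), v0, tolerance = 1e-9)
  # open-shell variant is open
  shell <- sliceZ(cy, 25, 75, cap = FALSE)
  expect_false(isWatertight(shell))
  # disjoint slab errors
  expect_error(sliceZ(cy, 200, 300), "does not intersect")
  expect_error(sliceZ(cy, 50, 50), "zmin")
  # additivity on convex solids: below + slab + above = whole
  for (solid in list(cy, icosphereMesh(30, 3, center = c(0, 0, 50)))) {
    vw <- enclosedVolume(solid)
    a <- enclosedVolume(sliceZ(solid, min(meshVertices(solid)[, 3]) - 1, 40))
    b <- enclosedVolume(sliceZ(solid, 40, 61))
    c3 <- enclosedVolume(sliceZ(solid, 61, max(meshVertices(solid)[, 3]) + 1))
    expect_equal(a + b + c3, vw, tolerance = 1e-6)
  }
})
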