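test_that("mid-sagittal plane estimation finds and follows the symmetry plane", {
  sym <- generateTorso(torsoParams(rings = 32, pointsPerRing = 32))
  pl <- estimateMidsagittalPlane(sym)
  angErr <- acos(min(1, abs(sum(pl@normal * c(1, 0, 0))))) * 180 / pi
  expect_lt(angErr, 1)
  expect_lt(abs(pl@point[1]), 0.5)
  # equivariance: rotating the mesh rotates the plane
  R20 <- axisRotation(20, "z")
  rot <- applyRigid(sym, rigidTransform(R20))
  pl2 <- estimateMidsagittalPlane(rot)
  want <- as.numeric(R20 %*% pl@normal)
  expect_lt(acos(min(1, abs(sum(pl2@normal * want)))) * 180 / pi, 1)
  # near-isotropic shape: arbitrary lateral axis is flagged
  expect_warning(estimateMidsagittalPlane(icosphereMesh(10, 2)),
                 "arbitrary|isotropic")
  # rank-deficient vertex cloud (planar mesh): hard error
  flat <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)), clean = FALSE)
  expect_error(estimateMidsagittalPlane(flat), "degenerate")
})

test_that("ICP recovers injected rigid transforms and is deterministic", {
  src <- generateTorso(torsoParams(lateralOffset = 15, humpAmplitude = 12,
                                   rings = 32, pointsPerRing = 32))
  cfg <- icpConfig(seed = 5)
  # identity case
  reg0 <- icpRegister(src, src, cfg)
  expect_lt(max(abs(reg0$transform@rotation - diag(3))), 1e-5)
  expect_lt(max(abs(reg0$transform@translation)), 1e-3)
  expect_lt(reg0$rmsResidual, 1e-3)
  # known transform
  tr <- rigidTransform(axisRotation(12, "z") %*% axisRotation(-8, "x"),
                       c(15, -10, 18))
  tgt <- applyRigid(src, tr)
  reg <- icpRegister(src, tgt, cfg)
  rotErr <- BraceMorph:::rotationAngleDeg(
    crossprod(reg$transform@rotation, tr@rotation))
  expect_lt(rotErr, 0.5)
  expect_lt(sqrt(sum((reg$transform@translation - tr@translation)^2)), 0.5)
  # fixed seed: bit-identical repeat
  reg2 <- icpRegister(src, tgt, cfg)
  expect_identical(reg$transform@rotation, reg2$transform@rotation)
  expect_identical(reg$transform@translation, reg2$transform@translation)
})

test_that("trimming to equal length intersects z-ranges with an overlap guard", {
  cyl <- function(z0, z1) {
    m <- cylinderMesh(20, z1 - z0, rings = 24, segments = 24)
    applyRigid(m, rigidTransform(diag(3), c(0, 0, z0)))
  }
  tr <- trimToEqualLength(cyl(0, 100), cyl(10, 110))
  expect_equal(tr$trimInterval, c(10, 100))
  expect_equal(range(meshVertices(tr$original)[, 3]), c(10, 100))
  expect_equal(range(meshVertices(tr$mirror)[, 3]), c(10, 100))
  # identical ranges: extent unchanged
  tr2 <- trimToEqualLength(cyl(0, 100), cyl(0, 100))
  expect_equal(tr2$trimInterval, c(0, 100))
  # 1% overlap is rejected
  expect_error(trimToEqualLength(cyl(0, 100), cyl(99, 200)), "10%")
})

test_that("inter-surface volume matches analytic symmetric differences", {
  c1 <- boxMesh(c(0, 0, 0), c(100, 100, 100))
  c2 <- boxMesh(c(10, 0, 0), c(110, 100, 100))
  v <- interSurfaceVolume(c1, c2, voxelPitch = 1)
  expect_equal(v, 200000, tolerance = 0.02)
  # symmetry in the arguments (same grid)
  expect_identical(v, interSurfaceVolume(c2, c1, voxelPitch = 1))
  # nested spheres: analytic shell
  s1 <- icosphereMesh(50, 4); s2 <- icosphereMesh(40, 4)
  shell <- 4 / 3 * pi * (50^3 - 40^3)
  expect_equal(interSurfaceVolume(s1, s2, voxelPitch = 1), shell,
               tolerance = 0.02)
  # identical solids: exactly zero on a shared grid
  expect_identical(interSurfaceVolume(s1, s1, voxelPitch = 2), 0)
  # halving the pitch moves the estimate by less than the voxel-shell bound
  v2 <- interSurfaceVolume(s1, s2, voxelPitch = 2)
  v1 <- interSurfaceVolume(s1, s2, voxelPitch = 1)
  bound <- (surfaceArea(s1) + surfaceArea(s2)) * 2
  expect_lt(abs(v2 - v1), bound)
  # non-watertight input rejected
  open <- surfaceMesh(meshVertices(c1), meshFaces(c1)[-1, ], clean = FALSE)
  expect_error(interSurfaceVolume(open, c1, 2), "watertight")
  # grid budget guard
  expect_error(interSurfaceVolume(s1, s2, voxelPitch = 0.01), "budget")
})

test_that("asymmetry index is ~0 for symmetric phantoms and scales with a bump", {
  cfg <- icpConfig(seed = 1)
  sym <- generateTorso(torsoParams())
  a0 <- asymmetryIndex(sym, cfg, voxelPitch = 2)
  expect_lte(asymmetryPercent(a0), 0.5)
  expect_equal(asymmetryPercent(a0),
               100 * a0@interSurfaceVolume / a0@totalVolume)

  # single lateral bump of analytic volume v = A * 2*pi*sigma^2: the mirror
  # carries it to the other side, so the symmetric difference is ~2v
  A <- 8; sig <- 50
  bump <- generateTorso(torsoParams(humpAmplitude = A, humpWidth = sig))
  ab <- asymmetryIndex(bump, cfg, voxelPitch = 1)
  expected <- 100 * 2 * (A * 2 * pi * sig^2) / ab@totalVolume
  expect_equal(asymmetryPercent(ab), expected, tolerance = 0.15)

  # rigid invariance
  moved <- applyRigid(bump, rigidTransform(
    axisRotation(25, "z") %*% axisRotation(10, "x"), c(30, -20, 15)))
  am <- asymmetryIndex(moved, cfg, voxelPitch = 2)
  ab2 <- asymmetryIndex(bump, cfg, voxelPitch = 2)
  expect_lt(abs(asymmetryPercent(am) - asymmetryPercent(ab2)), 0.2)

  # non-watertight input rejected with the failing stage identifiable
  open <- surfaceMesh(meshVertices(sym), meshFaces(sym)[-1, ], clean = FALSE)
  expect_error(asymmetryIndex(open, cfg), "watertight")
})

test_that("asymmetry grows monotonically with rib-hump amplitude", {
  cfg <- icpConfig(seed = 1)
  amps <- c(0, 5, 10, 15, 20)
  vals <- vapply(amps, function(a) {
    m <- generateTorso(torsoParams(humpAmplitude = a,
                                   rings = 32, pointsPerRing = 32))
    asymmetryPercent(asymmetryIndex(m, cfg, voxelPitch = 2))
  }, 0)
  expect_true(all(diff(vals) > 0))
})
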