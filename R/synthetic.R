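#' Parameters of the synthetic torso phantom
#'
#' The phantom is a watertight generalized cylinder: elliptical cross
#' sections swept along z with a smooth taper, whose centerline can be
#' laterally offset (simulating the coronal convexity of a scoliotic curve)
#' and whose surface can carry an azimuthally Gaussian bump (simulating a rib
#' hump). With `lateralOffset = 0` and `humpAmplitude = 0` the phantom is
#' exactly mirror-symmetric about the x = 0 plane by construction.
#'
#' @param height torso height in mm.
#' @param halfAxisX,halfAxisY base cross-section half-axes in mm
#'   (x = left-right, y = antero-posterior).
#' @param taper smooth scalar function of normalized z in \[0, 1\] scaling
#'   the cross section (default a mild waist).
#' @param lateralOffset amplitude of the centerline x-offset in mm
#'   (signed: + is toward patient left).
#' @param apexZ normalized z of the lateral-offset apex (0, 1).
#' @param humpAmplitude radial amplitude of the rib-hump bump in mm.
#' @param humpZ normalized z of the hump center.
#' @param humpAzimuthDeg azimuth of the hump center in degrees
#'   (0 = +x = patient left, 90 = +y = anterior; 225 = posterior right).
#' @param humpWidth Gaussian width (sigma) of the hump in mm.
#' @param rings number of cross-section rings (>= 24).
#' @param pointsPerRing points per ring (>= 24, even so the ring point set is
#'   exactly closed under x-mirroring).
#' @param seed integer; accepted for interface uniformity (the phantom build
#'   is deterministic in the parameters).
#' @return a validated parameter list of class `TorsoParams`.
#' @seealso [generateTorso()]
#' @export
torsoParams <- function(height = 500, halfAxisX = 140, halfAxisY = 100,
                        taper = function(t) 1 - 0.15 * sin(pi * t)^2,
                        lateralOffset = 0, apexZ = 0.5,
                        humpAmplitude = 0, humpZ = 0.65,
                        humpAzimuthDeg = 225, humpWidth = 60,
                        rings = 48L, pointsPerRing = 48L, seed = 1L) {
  p <- list(height = height, halfAxisX = halfAxisX, halfAxisY = halfAxisY,
            taper = taper, lateralOffset = lateralOffset, apexZ = apexZ,
            humpAmplitude = humpAmplitude, humpZ = humpZ,
            humpAzimuthDeg = humpAzimuthDeg, humpWidth = humpWidth,
            rings = as.integer(rings),
            pointsPerRing = as.integer(pointsPerRing),
            seed = as.integer(seed))
  if (p$height <= 0 || p$halfAxisX <= 0 || p$halfAxisY <= 0)
    stop("torsoParams: height and half-axes must be positive")
  if (p$rings < 24L || p$pointsPerRing < 24L)
    stop("torsoParams: resolution must be at least 24 x 24")
  if (p$pointsPerRing %% 2L != 0L)
    stop("torsoParams: pointsPerRing must be even")
  if (p$apexZ <= 0 || p$apexZ >= 1)
    stop("torsoParams: apexZ must be in (0, 1)")
  if (p$humpWidth <= 0) stop("torsoParams: humpWidth must be positive")
  class(p) <- "TorsoParams"
  p
}

#' Generate a watertight torso phantom
#'
#' Builds the generalized-cylinder phantom described by [torsoParams()]:
#' elliptical rings swept along z, centerline offset
#' `lateralOffset * sin(pi * s)` (with `s` rescaled so the apex falls at
#' `apexZ`), an azimuthally Gaussian radial hump, and planar end caps.
#' Ring trigonometry is explicitly symmetrized so that a phantom with zero
#' asymmetry parameters equals its own x = 0 reflection to the last bit.
#' Deterministic for fixed parameters.
#'
#' @param params a `TorsoParams` list from [torsoParams()].
#' @return a watertight, outward-oriented [SurfaceMesh-class]; the parameters
#'   are stored in the mesh metadata.
#' @export
generateTorso <- function(params) {
  if (!inherits(params, "TorsoParams")) stop("generateTorso: invalid params")
  p <- params
  R <- p$rings; P <- p$pointsPerRing
  j <- 0:(P - 1)
  cth <- cos(2 * pi * j / P)
  sth <- sin(2 * pi * j / P)
  # enforce exact closure of the ring point set under x-mirroring:
  # mirror pairs j <-> (P/2 - j) mod P get bitwise-opposite cos, equal sin
  k <- (P / 2 - j) %% P
  canon <- which(j < k)
  cth[k[canon] + 1] <- -cth[canon]
  sth[k[canon] + 1] <- sth[canon]
  cth[j == k] <- 0

  tgrid <- seq(0, 1, length.out = R)
  scl <- vapply(tgrid, p$taper, 0)
  if (any(scl <= 0)) stop("generateTorso: taper must stay positive")
  # lateral centerline offset with apex at apexZ
  s <- ifelse(tgrid <= p$apexZ, tgrid / (2 * p$apexZ),
              0.5 + (tgrid - p$apexZ) / (2 * (1 - p$apexZ)))
  cx <- p$lateralOffset * sin(pi * s)

  nv <- R * P
  V <- matrix(0, nv + 2L, 3)
  humpAz <- p$humpAzimuthDeg * pi / 180
  theta <- 2 * pi * j / P
  for (i in seq_len(R)) {
    t <- tgrid[i]
    z <- t * p$height
    x <- cx[i] + p$halfAxisX * scl[i] * cth
    y <- p$halfAxisY * scl[i] * sth
    if (p$humpAmplitude != 0) {
      rloc <- sqrt((x - cx[i])^2 + y^2)
      dAz <- atan2(sin(theta - humpAz), cos(theta - humpAz))
      darc <- dAz * rloc
      dz <- z - p$humpZ * p$height
      g <- p$humpAmplitude * exp(-(dz^2 + darc^2) / (2 * p$humpWidth^2))
      x <- x + g * cth
      y <- y + g * sth
    }
    idx <- (i - 1L) * P + seq_len(P)
    V[idx, 1] <- x; V[idx, 2] <- y; V[idx, 3] <- z
  }
  bottomC <- nv + 1L; topC <- nv + 2L
  V[bottomC, ] <- c(cx[1], 0, 0)
  V[topC, ] <- c(cx[R], 0, p$height)

  # side quads
  Fs <- vector("list", R - 1L)
  for (i in seq_len(R - 1L)) {
    a <- (i - 1L) * P + j + 1L
    b <- (i - 1L) * P + ((j + 1L) %% P) + 1L
    a2 <- a + P; b2 <- b + P
    Fs[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  Fside <- do.call(rbind, Fs)
  a <- j + 1L
  b <- ((j + 1L) %% P) + 1L
  Fbottom <- cbind(bottomC, b, a)
  at <- (R - 1L) * P + j + 1L
  bt <- (R - 1L) * P + ((j + 1L) %% P) + 1L
  Ftop <- cbind(topC, at, bt)
  F <- rbind(Fside, Fbottom, Ftop)

  if (cpp_signed_volume(V, matrix(as.integer(F), ncol = 3)) < 0)
    F <- F[, c(1, 3, 2)]
  surfaceMesh(V, F, clean = TRUE, metadata = list(params = p))
}

#' Specify a brace pad or relief zone
#'
#' A Gaussian surface deformation targeted at one of the 12 segments:
#' positive depth moves the surface inward (a pressure pad), negative depth
#' moves it outward (a relief / expansion zone).
#'
#' @param segment one of [segmentCodes()].
#' @param depth deformation depth in mm (signed).
#' @param width Gaussian footprint sigma in mm (default 45).
#' @return a `PadSpec` list.
#' @seealso [generateBrace()]
#' @export
padSpec <- function(segment, depth, width = 45) {
  if (!segment %in% segmentCodes())
    stop("padSpec: unknown segment '", segment, "'")
  if (width <= 0) stop("padSpec: width must be positive")
  structure(list(segment = segment, depth = depth, width = width),
            class = "PadSpec")
}

# representative center of a segment on a torso: z at the band center,
# azimuth at the quadrant bisector (L: x>0, A: y>0)
segmentCenter <- function(torso, segment) {
  zr <- range(torso@vertices[, 3])
  h <- diff(zr)
  bands <- c(U = 5 / 6, M = 0.5, L = 1 / 6)
  zc <- zr[1] + h * bands[[substr(segment, 3, 3)]]
  az <- switch(paste0(substr(segment, 1, 1), substr(segment, 2, 2)),
               AL = 45, AR = 135, PR = 225, PL = 315)
  list(z = zc, azimuthDeg = az)
}

#' Derive a brace model from a torso by pad/relief deformation
#'
#' Displaces the torso surface along its inward vertex normals by the summed
#' Gaussian pad profiles, emulating the virtual reshaping of a scan into a
#' brace model: positive pad depth pushes the brace surface inside the torso
#' (a pressure zone), negative depth pulls it outside (an expansion zone).
#' Topology is preserved, so a watertight torso yields a watertight brace;
#' deformations strong enough to fold the surface are rejected.
#'
#' @param torso a watertight [SurfaceMesh-class].
#' @param pads list of [padSpec()] objects (possibly empty).
#' @return the brace [SurfaceMesh-class].
#' @export
generateBrace <- function(torso, pads = list()) {
  open <- openEdgeCount(torso)
  if (open > 0L)
    stop("generateBrace: torso is not watertight (", open, " open edges)")
  if (inherits(pads, "PadSpec")) pads <- list(pads)
  V <- torso@vertices
  bb <- apply(V[, 1:2, drop = FALSE], 2, range)
  minHalf <- min(diff(bb[, 1]), diff(bb[, 2])) / 2
  N <- vertexNormals(torso)
  ctr <- colMeans(V)
  disp <- numeric(nrow(V))
  for (pad in pads) {
    if (!inherits(pad, "PadSpec")) stop("generateBrace: pads must be PadSpec")
    if (abs(pad$depth) >= minHalf / 2)
      stop("generateBrace: |depth| of ", pad$depth,
           " mm exceeds half the smallest cross-section half-axis")
    cen <- segmentCenter(torso, pad$segment)
    az <- cen$azimuthDeg * pi / 180
    thv <- atan2(V[, 2] - ctr[2], V[, 1] - ctr[1])
    rloc <- sqrt((V[, 1] - ctr[1])^2 + (V[, 2] - ctr[2])^2)
    dAz <- atan2(sin(thv - az), cos(thv - az))
    d2 <- (V[, 3] - cen$z)^2 + (dAz * rloc)^2
    disp <- disp + pad$depth * exp(-d2 / (2 * pad$width^2))
  }
  Vb <- V - N * disp
  brace <- new("SurfaceMesh", vertices = Vb, faces = torso@faces,
               metadata = list(pads = pads))
  # reject folded (self-intersecting) deformations: face normals must not flip
  if (length(pads) > 0) {
    if (any(faceNormalDots(torso, brace) <= 0))
      stop("generateBrace: pad depth causes local self-intersection (folded faces)")
  }
  brace
}

# dot products of corresponding face normals of two same-topology meshes
faceNormalDots <- function(a, b) {
  fn <- function(m) {
    V <- m@vertices; F <- m@faces
    e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  }
  rowSums(fn(a) * fn(b))
}

#' Cohort simulation model
#'
#' Describes a synthetic study cohort: group sizes, pre-brace Cobb-angle
#' distributions (defaults follow the published study population: Lenke 1
#' AP 38.4 +- 14.8 deg, Lenke 5 AP 30.5 +- 5.8 deg, truncated at the
#' 20-degree inclusion threshold), and the planted effect structure mapping
#' a named segment-peak feature to in-brace correction with Gaussian noise.
#'
#' The default planted effects mirror the correlation structure flagged in
#' the study population: IBC depends negatively on the peak expansion
#' (negative displacement) in ARM for Lenke 1 and in PLM for Lenke 5, with
#' coefficient 2 %/mm; the noise SDs are calibrated so the population
#' Spearman correlations are about -0.72 and -0.85 respectively.
#'
#' @param nLenke1,nLenke5 patients per group (>= 3; defaults 11 and 14).
#' @param preCaAP named list of `c(mean, sd)` per group.
#' @param preCaLat named list of `c(mean, sd)` per group.
#' @param effects named list per group: `intercept`, `feature` (a column of
#'   [segmentFeatureNames()]), `coef` (%/mm), `noiseSD` (%).
#' @param ibcLat named list of `c(mean, sd)` per group for the lateral IBC
#'   (no planted effect).
#' @param reliefDepth `c(mean, sd)` of the planted relief-pad depth (mm,
#'   negative).
#' @param padDepth `c(mean, sd)` of pressure-pad depths (mm, positive).
#' @param nNuisancePads random small adjustment pads per patient.
#' @param resolution `c(rings, pointsPerRing)` of the phantom meshes.
#' @param seed integer master seed.
#' @return a validated list of class `CohortModel`.
#' @export
cohortModel <- function(nLenke1 = 11L, nLenke5 = 14L,
                        preCaAP = list(`1` = c(38.4, 14.8),
                                       `5` = c(30.5, 5.8)),
                        preCaLat = list(`1` = c(21.2, 15.0),
                                        `5` = c(48.3, 11.9)),
                        effects = list(
                          `1` = list(intercept = 28, feature = "peakNegative_ARM",
                                     coef = 2.0, noiseSD = 3.3),
                          `5` = list(intercept = 32, feature = "peakNegative_PLM",
                                     coef = 2.0, noiseSD = 2.0)),
                        ibcLat = list(`1` = c(5.1, 15.0),
                                      `5` = c(13.7, 14.4)),
                        reliefDepth = c(-6, 2),
                        padDepth = c(6, 1.5),
                        nNuisancePads = 2L,
                        resolution = c(24L, 24L),
                        seed = 1L) {
  m <- list(nLenke1 = as.integer(nLenke1), nLenke5 = as.integer(nLenke5),
            preCaAP = preCaAP, preCaLat = preCaLat, effects = effects,
            ibcLat = ibcLat, reliefDepth = reliefDepth, padDepth = padDepth,
            nNuisancePads = as.integer(nNuisancePads),
            resolution = as.integer(resolution), seed = as.integer(seed))
  if (m$nLenke1 < 3L || m$nLenke5 < 3L)
    stop("cohortModel: need at least 3 patients per group")
  for (g in c("1", "5")) {
    if (m$effects[[g]]$noiseSD < 0) stop("cohortModel: noiseSD must be >= 0")
    if (!m$effects[[g]]$feature %in% segmentFeatureNames())
      stop("cohortModel: unknown effect feature ", m$effects[[g]]$feature)
  }
  class(m) <- "CohortModel"
  m
}

rtruncnorm1 <- function(mean, sd, lower, upper = Inf) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Simulate a synthetic study cohort
#'
#' For each patient: draws a pre-brace Cobb angle from the group distribution
#' (truncated at the 20-degree inclusion threshold), builds a torso phantom
#' whose lateral offset and rib hump scale with the Cobb angle (Lenke 1
#' thoracic right-convex, Lenke 5 lumbar left-convex), derives a brace with
#' the group's planted relief pad (drawn depth), pressure pads and random
#' nuisance pads, measures the segment peaks through the real displacement
#' pipeline, and generates IBC as the planted linear effect on the named
#' feature plus Gaussian noise, back-computing the in-brace Cobb angle.
#' Fully reproducible from the model seed.
#'
#' @param model a [cohortModel()].
#' @param computeAsymmetry also run the asymmetry-index chain per patient
#'   (slower; default `FALSE`, columns are then `NA`).
#' @param outDir optional directory: writes per-patient torso/brace PLY
#'   files, a `manifest.csv` and a `ground_truth.json`.
#' @param voxelPitch pitch for the optional asymmetry computation (mm).
#' @return data.frame of patient records (one row per patient) with Cobb
#'   angles, IBC percentages, asymmetry indices and the 24 segment-peak
#'   features; the planted ground truth is attached as attribute
#'   `groundTruth`.
#' @export
generateCohort <- function(model, computeAsymmetry = FALSE, outDir = NULL,
                           voxelPitch = 2) {
  stopifnot(inherits(model, "CohortModel"))
  withSeed(model$seed, {
    rows <- list()
    gt <- list()
    pid <- 0L
    for (g in c(1, 5)) {
      n <- if (g == 1) model$nLenke1 else model$nLenke5
      eff <- model$effects[[as.character(g)]]
      capDist <- model$preCaAP[[as.character(g)]]
      latDist <- model$preCaLat[[as.character(g)]]
      ibcLatDist <- model$ibcLat[[as.character(g)]]
      for (i in seq_len(n)) {
        pid <- pid + 1L
        preAP <- rtruncnorm1(capDist[1], capDist[2], 20)
        preLat <- rtruncnorm1(latDist[1], latDist[2], 5)
        convexSign <- if (g == 1) -1 else 1  # Lenke1 right (-x), Lenke5 left (+x)
        apex <- if (g == 1) 0.65 else 0.35
        humpAz <- if (g == 1) 225 else 315   # posterior, convex side
        tp <- torsoParams(
          lateralOffset = convexSign * 0.45 * preAP,
          apexZ = apex,
          humpAmplitude = (if (g == 1) 0.25 else 0.15) * preAP,
          humpZ = apex, humpAzimuthDeg = humpAz,
          rings = model$resolution[1], pointsPerRing = model$resolution[2])
        torso <- generateTorso(tp)

        reliefSeg <- sub("peakNegative_", "", eff$feature)
        pressureSegs <- if (g == 1) c("PRU", "ALU") else c("ARM", "PLL")
        rec <- NULL
        for (attempt in 1:10) {
          reliefD <- rtruncnorm1(model$reliefDepth[1], model$reliefDepth[2],
                                 -11, -1.5)
          pads <- list(padSpec(reliefSeg, reliefD))
          presD <- numeric(length(pressureSegs))
          for (k in seq_along(pressureSegs)) {
            presD[k] <- rtruncnorm1(model$padDepth[1], model$padDepth[2], 2, 10)
            pads[[length(pads) + 1L]] <- padSpec(pressureSegs[k], presD[k])
          }
          nuis <- character(0); nuisD <- numeric(0)
          if (model$nNuisancePads > 0) {
            nuis <- sample(setdiff(segmentCodes(), c(reliefSeg, pressureSegs)),
                           model$nNuisancePads)
            nuisD <- stats::rnorm(model$nNuisancePads, 0, 1.5)
            for (k in seq_along(nuis))
              pads[[length(pads) + 1L]] <- padSpec(nuis[k], nuisD[k], width = 35)
          }
          brace <- tryCatch(generateBrace(torso, pads), error = function(e) NULL)
          if (!is.null(brace)) {
            rec <- list(brace = brace, reliefD = reliefD, presD = presD,
                        nuis = nuis, nuisD = nuisD)
            break
          }
        }
        if (is.null(rec))
          stop("generateCohort: infeasible geometry after 10 retries (patient ",
               pid, ")")

        field <- signedDisplacementField(torso, rec$brace)
        labels <- partitionSegments(torso)
        pk <- peaksTable(segmentPeaks(field, labels))
        feats <- c(stats::setNames(pk$peakPositive,
                                   paste0("peakPositive_", pk$segment)),
                   stats::setNames(pk$peakNegative,
                                   paste0("peakNegative_", pk$segment)))

        ibcAP <- eff$intercept + eff$coef * feats[[eff$feature]] +
          stats::rnorm(1, 0, eff$noiseSD)
        ibcAP <- min(ibcAP, 95)
        inAP <- preAP * (1 - ibcAP / 100)
        ibcLat <- stats::rnorm(1, ibcLatDist[1], ibcLatDist[2])
        ibcLat <- min(ibcLat, 95)
        inLat <- preLat * (1 - ibcLat / 100)

        asymT <- asymB <- NA_real_
        if (computeAsymmetry) {
          cfgA <- icpConfig(seed = model$seed + pid)
          asymT <- asymmetryPercent(asymmetryIndex(torso, cfgA, voxelPitch))
          asymB <- asymmetryPercent(asymmetryIndex(rec$brace, cfgA, voxelPitch))
        }

        id <- sprintf("P%03d", pid)
        rows[[pid]] <- c(list(patientId = id, lenkeType = g,
                              preCaAP = preAP, inBraceCaAP = inAP,
                              preCaLat = preLat, inBraceCaLat = inLat,
                              ibcAP = ibcAP, ibcLat = ibcLat,
                              asymmetryTorso = asymT, asymmetryBrace = asymB),
                         as.list(feats))
        gt[[pid]] <- list(patientId = id, lenkeType = g,
                          reliefSegment = reliefSeg, reliefDepth = rec$reliefD,
                          pressureSegments = pressureSegs,
                          pressureDepths = rec$presD,
                          nuisanceSegments = rec$nuis,
                          nuisanceDepths = rec$nuisD,
                          effect = eff)
        if (!is.null(outDir)) {
          dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
          writeMesh(torso, file.path(outDir, paste0(id, "_torso.ply")))
          writeMesh(rec$brace, file.path(outDir, paste0(id, "_brace.ply")))
        }
      }
    }
    records <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(records) <- NULL
    attr(records, "groundTruth") <- gt
    if (!is.null(outDir)) {
      manifest <- data.frame(
        patient_id = records$patientId,
        torso_path = paste0(records$patientId, "_torso.ply"),
        brace_path = paste0(records$patientId, "_brace.ply"),
        lenke_type = records$lenkeType,
        pre_ca_ap = records$preCaAP, inbrace_ca_ap = records$inBraceCaAP,
        pre_ca_lat = records$preCaLat, inbrace_ca_lat = records$inBraceCaLat)
      utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                       row.names = FALSE)
      jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    records
  })
}
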