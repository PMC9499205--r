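# Ground-truthed synthetic ramus cases: a parametric hemimandible phantom
# (condylar head, coronoid process, mandibular notch, gonial angle) built as
# a smooth implicit solid so that every cephalometric landmark is a unique,
# brute-force-verifiable extremum of the extracted mesh.

#' Shape parameters of the synthetic ramus phantom
#'
#' All lengths in mm, in the canonical right-side frame (x anterior,
#' y lateral, z superior). The phantom is the union of a super-elliptic ramal
#' blade (with a Gaussian notch depression in its upper border and a slight
#' anteroposterior tilt so extremal landmarks are unique), a condylar head
#' ellipsoid on a cylindrical neck, a tapered coronoid process, and a gonial
#' bulge at the posterior-inferior angle.
#'
#' @param bladeHalfX,bladeHalfY,bladeHalfZ half-extents of the ramal blade.
#' @param bladeCenterZ vertical centre of the blade.
#' @param bladeTilt vertical tilt of the blade centre per mm of x.
#' @param notchDepth,notchWidth,notchX depth (mm), Gaussian width (mm) and
#'   anteroposterior position of the mandibular-notch depression.
#' @param condyleCenter,condyleRadii centre and semi-axes of the condylar head.
#' @param neckA,neckB,neckRadius condylar neck capsule endpoints and radius.
#' @param coronoidA,coronoidB,coronoidR0,coronoidR1 tapered coronoid capsule.
#' @param gonionCenter,gonionRadius gonial bulge sphere.
#' @param variability relative scale of the per-case random shape jitter.
#' @param meshSpacing grid spacing (mm) for isosurface extraction.
#' @return A named list of shape parameters.
#' @export
ramusShapeParams <- function(bladeHalfX = 14, bladeHalfY = 3.5, bladeHalfZ = 18,
                             bladeCenterZ = -12, bladeTilt = 0.08,
                             notchDepth = 4, notchWidth = 4, notchX = 0,
                             condyleCenter = c(-13, 0, 16),
                             condyleRadii = c(6.5, 5.5, 7),
                             neckA = c(-10, 0, 2), neckB = c(-13, 0, 13),
                             neckRadius = 4,
                             coronoidA = c(9, 0, 2), coronoidB = c(11.5, 0, 15),
                             coronoidR0 = 4, coronoidR1 = 1.6,
                             gonionCenter = c(-13, 0, -27.5), gonionRadius = 5,
                             variability = 0.04, meshSpacing = 0.9) {
  p <- as.list(environment())
  lens <- c(p$bladeHalfX, p$bladeHalfY, p$bladeHalfZ, p$notchDepth, p$notchWidth,
            p$condyleRadii, p$neckRadius, p$coronoidR0, p$coronoidR1,
            p$gonionRadius, p$meshSpacing)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("degenerate shape parameters: all dimensions must be positive and finite")
  if (p$variability < 0 || p$variability > 0.2)
    stop("variability must lie in [0, 0.2]")
  p
}

# implicit inside-function (> 0 inside) evaluated at an n x 3 point matrix
ramusField <- function(pts, p) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  # the notch depression shapes only the upper border of the blade
  hzTop <- p$bladeHalfZ - p$notchDepth * exp(-((x - p$notchX) / p$notchWidth)^2)
  cz <- p$bladeCenterZ + p$bladeTilt * x
  hz <- ifelse(z > cz, hzTop, p$bladeHalfZ)
  blade <- 1 - (y / p$bladeHalfY)^2 - ((z - cz) / hz)^2 - (x / p$bladeHalfX)^8
  cc <- p$condyleCenter; cr <- p$condyleRadii
  cond <- 1 - ((x - cc[1]) / cr[1])^2 - ((y - cc[2]) / cr[2])^2 -
    ((z - cc[3]) / cr[3])^2
  capsule <- function(a, b, r0, r1) {
    ab <- b - a
    tt <- pmin(pmax(((x - a[1]) * ab[1] + (y - a[2]) * ab[2] +
                       (z - a[3]) * ab[3]) / sum(ab^2), 0), 1)
    d2 <- (x - a[1] - tt * ab[1])^2 + (y - a[2] - tt * ab[2])^2 +
      (z - a[3] - tt * ab[3])^2
    r <- r0 + tt * (r1 - r0)
    1 - d2 / r^2
  }
  neck <- capsule(p$neckA, p$neckB, p$neckRadius, p$neckRadius)
  corp <- capsule(p$coronoidA, p$coronoidB, p$coronoidR0, p$coronoidR1)
  gc <- p$gonionCenter
  gon <- 1 - ((x - gc[1])^2 + (y - gc[2])^2 + (z - gc[3])^2) / p$gonionRadius^2
  pmax(blade, cond, neck, corp, gon)
}

jitterParams <- function(p, seed) {
  if (p$variability == 0) return(p)
  withSeed(deriveSeed(seed, 101L), {
    jit <- function(v) {
      u <- pmin(pmax(rnorm(length(v), 0, p$variability), -2 * p$variability),
                2 * p$variability)
      v * (1 + u)
    }
    for (nm in c("bladeHalfX", "bladeHalfZ", "notchDepth", "condyleRadii",
                 "coronoidR0", "gonionRadius"))
      p[[nm]] <- jit(p[[nm]])
    p
  })
}

#' Generate a ground-truthed synthetic ramus case
#'
#' Builds the phantom mesh by marching-tetrahedra extraction of the implicit
#' solid, computes every cephalometric landmark from the mesh (extremal-point
#' definitions; never sampled), constructs the anatomical cutting planes and
#' the region labelling from those landmarks, and voxelizes a CBCT-like
#' preoperative volume (default 0.30 mm isotropic spacing). Regenerating with
#' the same parameters and seed is bit-identical.
#'
#' @param shapeParams from \code{\link{ramusShapeParams}}.
#' @param side "R" or "L" (left cases are mirrored across y = 0).
#' @param seed integer seed controlling the bounded per-case shape jitter.
#' @param volumeSpacing spacing of the preoperative volume, mm (default 0.30).
#' @param makeVolume set FALSE to skip volume generation.
#' @param caseId case identifier.
#' @return A \linkS4class{SyntheticCase} (postoperative slots empty; see
#'   \code{\link{buildPostop}}).
#' @export
generateRamus <- function(shapeParams = ramusShapeParams(), side = c("R", "L"),
                          seed = 1L, volumeSpacing = 0.30, makeVolume = TRUE,
                          caseId = sprintf("case%04d", seed)) {
  side <- match.arg(side)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single integer")
  seed <- as.integer(seed)
  p <- jitterParams(shapeParams, seed)

  # implicit -> watertight mesh
  lo <- c(-p$bladeHalfX - p$gonionRadius - 3, -p$condyleRadii[2] - 2,
          p$bladeCenterZ - p$bladeHalfZ - p$gonionRadius - 3)
  hi <- c(p$bladeHalfX + 4, p$condyleRadii[2] + 2,
          p$condyleCenter[3] + p$condyleRadii[3] + 2)
  dims <- as.integer(ceiling((hi - lo) / p$meshSpacing)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * p$meshSpacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * p$meshSpacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * p$meshSpacing
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  vals <- ramusField(pts, p)
  iso <- cpp_march_tets(vals, dims, 0)
  V <- sweep(iso$vertices * p$meshSpacing, 2, lo, "+")
  mesh <- surfaceMesh(V, iso$faces)
  if (side == "L") mesh <- mirrorMesh(mesh)

  lms <- phantomLandmarks(mesh, p, side)
  lms <- locateDerivedLandmarks(mesh, lms, side = side)
  planes <- buildPlanes(lms, side = side)
  labeling <- partitionRamus(mesh, planes)
  vol <- if (makeVolume) voxelizeMesh(mesh, spacing = volumeSpacing,
                                      seed = deriveSeed(seed, 7L)) else NULL
  new("SyntheticCase", caseId = caseId, side = side, preopMesh = mesh,
      preopVolume = vol, postopMesh = NULL, postopVolume = NULL,
      landmarks = lms, planes = planes, labeling = labeling,
      trueDisplacement = rigidIdentity(), resorption = NULL,
      shapeParams = p, seed = seed)
}

# manual-equivalent landmarks computed from the mesh: C-point (most caudal
# point of the mandibular-notch arc), Go (most caudal + posterior point of
# the gonial angle), and the auxiliary Frankfurt landmarks Or/Po placed on
# cranial reference geometry attached to the case (the phantom has no skull).
# anteroposterior search window of the mandibular-notch arc
notchWindow <- function(p) {
  c(p$notchX - 0.9 * p$notchWidth - 2, p$notchX + 0.9 * p$notchWidth + 2)
}

phantomLandmarks <- function(mesh, p, side) {
  V <- mesh@vertices
  cp <- notchArcCPoint(V, window = notchWindow(p), halfWidth = 0.5)
  dGo <- unitv(c(-1, 0, -1))
  go <- V[which.max(V %*% dGo), ]
  zF <- max(V[, 3]) # Frankfurt at the level of the condylar apex
  aux <- rbind(c(45, 30, zF), c(45, -30, zF), c(-35, 30, zF), c(-35, -30, zF))
  new("LandmarkSet",
      name = c("C-point", "Go", "Or", "Or", "Po", "Po"),
      side = c(side, side, "L", "R", "L", "R"),
      coords = rbind(cp, go, aux),
      provenance = c("manual", "manual", rep("auxiliary", 4)))
}

# The notch arc: vertices that are the highest within their anteroposterior
# neighbourhood (|dx| <= halfWidth) inside the notch window; the C-point is
# the arc vertex with minimal z (first index on ties).
notchArcCPoint <- function(V, window, halfWidth = 0.5) {
  x <- V[, 1]; z <- V[, 3]
  cand <- which(x >= window[1] & x <= window[2])
  if (!length(cand)) stop("empty notch window; shape parameters degenerate")
  near <- which(x >= window[1] - halfWidth & x <= window[2] + halfWidth)
  ord <- near[order(x[near])]
  xs <- x[ord]; zs <- z[ord]
  onArc <- vapply(cand, function(v) {
    lo <- findInterval(x[v] - halfWidth, xs) + 1L
    hi <- findInterval(x[v] + halfWidth, xs)
    z[v] >= max(zs[lo:hi])
  }, logical(1))
  arc <- cand[onArc]
  arcV <- V[arc, , drop = FALSE]
  as.numeric(arcV[which.min(arcV[, 3]), ])
}

# ---------------------------------------------------------------------------
# Resorption / remodelling
# ---------------------------------------------------------------------------

#' Specify a resorption (inward remodelling) field
#'
#' @param targetRegion "condyle", "coronoid", a subregion label ("R01".."R20")
#'   or "reference_structure".
#' @param magnitude maximum inward surface displacement, mm.
#' @param falloff compact-support smoothness scale, mm.
#' @param affectedFraction fraction of the target region affected (0-1].
#' @export
resorptionSpec <- function(targetRegion = "condyle", magnitude = 1.0,
                           falloff = 4, affectedFraction = 1.0) {
  new("ResorptionSpec", targetRegion = targetRegion,
      magnitude = as.numeric(magnitude), falloff = as.numeric(falloff),
      affectedFraction = as.numeric(affectedFraction))
}

#' Apply parametric resorption to the preoperative mesh
#'
#' Displaces the affected vertices inward along their outward normals by a
#' compactly supported radial weight: full magnitude on the affected core of
#' the target region, smoothly decaying to exactly zero at \code{falloff} mm
#' from it. Volume never increases; the mesh topology (and watertightness)
#' is preserved; \code{magnitude = 0} returns the mesh unchanged.
#'
#' @param case a \linkS4class{SyntheticCase} (its labelling resolves the
#'   target region; "reference_structure" resolves through
#'   \code{\link{buildReferenceStructure}} on the ground-truth landmarks).
#' @param spec a \linkS4class{ResorptionSpec}.
#' @param seed reserved for stochastic remodelling textures; the default
#'   field is deterministic.
#' @return The remodelled \linkS4class{SurfaceMesh}.
#' @export
applyRemodelling <- function(case, spec, seed = 1L) {
  validObject(spec)
  mesh <- case@preopMesh
  if (spec@magnitude == 0) return(mesh)
  if (!isWatertight(mesh)) stop("preoperative mesh is not watertight")
  targetFaces <- resolveRegionFaces(case, spec@targetRegion)
  # affected core: the affectedFraction of target faces closest to the
  # area-weighted region centre
  fc <- faceCentroids(mesh)[targetFaces, , drop = FALSE]
  fa <- faceAreas(mesh)[targetFaces]
  ctr <- colSums(fc * fa) / sum(fa)
  dctr <- rowNorms(sweep(fc, 2, ctr))
  keep <- dctr <= quantile(dctr, probs = min(spec@affectedFraction, 1))
  if (!any(keep)) keep[which.min(dctr)] <- TRUE
  core <- submesh(mesh, targetFaces[keep])
  d <- cpp_closest_point(mesh@vertices, core@vertices, core@faces)$distance
  rho <- pmin(d / spec@falloff, 1)
  w <- (1 - rho^2)^2
  n <- vertexNormals(mesh)
  Vnew <- mesh@vertices - spec@magnitude * w * n
  surfaceMesh(Vnew, mesh@faces, mesh@faceLabels)
}

resolveRegionFaces <- function(case, targetRegion) {
  if (targetRegion == "reference_structure") {
    ref <- buildReferenceStructure(case@preopMesh, case@landmarks,
                                   side = case@side, planes = case@planes,
                                   makeVoxelMask = FALSE)
    return(ref@faces)
  }
  lab <- case@labeling@labels
  if (!targetRegion %in% lab)
    stop("unknown target region '", targetRegion, "'; expected one of: ",
         paste(unique(c(case@labeling@levels, "reference_structure")),
               collapse = ", "))
  which(lab == targetRegion)
}

#' Build the postoperative state of a synthetic case
#'
#' Applies resorption (optional) followed by the known rigid displacement,
#' stores the ground truth on the case, and voxelizes the postoperative
#' volume on its own grid.
#'
#' @param case a \linkS4class{SyntheticCase}.
#' @param displacement a \linkS4class{RigidTransform} (preop -> postop).
#' @param resorption optional \linkS4class{ResorptionSpec}.
#' @param volumeSpacing spacing of the postoperative volume (mm); defaults to
#'   the preoperative spacing (0.30 if no preop volume was generated).
#' @param noiseSd additive Gaussian intensity noise (HU-like).
#' @param seed integer seed (noise).
#' @export
buildPostop <- function(case, displacement = rigidIdentity(),
                        resorption = NULL, volumeSpacing = NULL,
                        noiseSd = 0, seed = case@seed) {
  m <- if (is.null(resorption)) case@preopMesh
       else applyRemodelling(case, resorption, seed = seed)
  m <- applyTransform(m, displacement)
  sp <- volumeSpacing %||%
    (if (!is.null(case@preopVolume)) case@preopVolume@spacing[1] else 0.30)
  vol <- if (!is.null(case@preopVolume))
    voxelizeMesh(m, spacing = sp, noiseSd = noiseSd,
                 seed = deriveSeed(seed, 11L)) else NULL
  case@postopMesh <- m
  case@postopVolume <- vol
  case@trueDisplacement <- displacement
  case@resorption <- resorption
  case
}

# ---------------------------------------------------------------------------
# Observer simulation
# ---------------------------------------------------------------------------

#' Simulate an observer's landmark and ROI selection variability
#'
#' Each landmark is displaced tangentially (on the visible bone surface) by
#' an isotropic two-component Gaussian whose root-mean-square total
#' displacement equals \code{perturbationScale}; ramal landmarks are then
#' re-projected onto the mesh surface. The reference-structure boundary
#' offsets are drawn from the same scale and jitter the ROI selection.
#'
#' @param case a \linkS4class{SyntheticCase}.
#' @param perturbationScale RMS landmark displacement, mm (>= 0).
#' @param seed integer seed; identical seeds reproduce the perturbation.
#' @return list with elements \code{landmarks} (perturbed
#'   \linkS4class{LandmarkSet}) and \code{roiOffsets} (named numeric(4), mm).
#' @export
simulateObserver <- function(case, perturbationScale, seed = 1L) {
  if (perturbationScale < 0) stop("perturbationScale must be >= 0")
  lms <- case@landmarks
  if (perturbationScale == 0)
    return(list(landmarks = lms,
                roiOffsets = c(cPlane = 0, posterior = 0, anterior = 0,
                               inferior = 0)))
  mesh <- case@preopMesh
  vn <- vertexNormals(mesh)
  # only the manual inputs (and the auxiliary Frankfurt points) carry
  # observer error; the derived landmarks are recomputed from the mesh
  keep <- lms@provenance != "derived"
  base <- new("LandmarkSet", name = lms@name[keep], side = lms@side[keep],
              coords = lms@coords[keep, , drop = FALSE],
              provenance = lms@provenance[keep])
  withSeed(seed, {
    pert <- perturbLandmarkSet(mesh, base, perturbationScale, vn)
    roi <- rnorm(4, 0, perturbationScale)
    full <- locateDerivedLandmarks(mesh, pert, side = case@side)
    list(landmarks = full,
         roiOffsets = c(cPlane = roi[1], posterior = roi[2],
                        anterior = roi[3], inferior = roi[4]))
  })
}

# tangential (on-surface) Gaussian displacement of a landmark set; uses the
# current RNG stream
perturbLandmarkSet <- function(mesh, lms, scale, vn = vertexNormals(mesh)) {
  fr <- buildFrankfurt(lms)
  co <- lms@coords
  for (i in seq_len(nrow(co))) {
    if (lms@provenance[i] == "auxiliary") {
      nrm <- fr@normal
    } else {
      cp <- cpp_closest_point(matrix(co[i, ], 1, 3), mesh@vertices, mesh@faces)
      nrm <- vn[mesh@faces[cp$face[1], 1], ]
    }
    e1 <- unitv(pracmaFreeOrtho(nrm))
    e2 <- cross3(nrm, e1)
    g <- rnorm(2, 0, scale / sqrt(2))
    pnew <- co[i, ] + g[1] * e1 + g[2] * e2
    if (lms@provenance[i] != "auxiliary") {
      cp2 <- cpp_closest_point(matrix(pnew, 1, 3), mesh@vertices, mesh@faces)
      pnew <- cp2$closest[1, ]
    }
    co[i, ] <- pnew
  }
  new("LandmarkSet", name = lms@name, side = lms@side, coords = co,
      provenance = lms@provenance)
}

# any unit vector orthogonal to n
pracmaFreeOrtho <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  cross3(n, a)
}

# ---------------------------------------------------------------------------
# Case bundles on disk
# ---------------------------------------------------------------------------

#' Write / read a synthetic case bundle
#'
#' Meshes as binary STL, volumes as NIfTI (.nii.gz), landmarks as CSV and
#' the ground truth (4 x 4 row-major transform, resorption spec, seed) as a
#' JSON sidecar.
#'
#' @param case a \linkS4class{SyntheticCase}.
#' @param dir output directory (created if needed).
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMesh(case@preopMesh, file.path(dir, "preop.stl"))
  if (!is.null(case@preopVolume)) writeVolume(case@preopVolume,
                                              file.path(dir, "preop.nii.gz"))
  if (!is.null(case@postopMesh)) writeMesh(case@postopMesh,
                                           file.path(dir, "postop.stl"))
  if (!is.null(case@postopVolume)) writeVolume(case@postopVolume,
                                               file.path(dir, "postop.nii.gz"))
  writeLandmarks(case@landmarks, file.path(dir, "landmarks.csv"))
  truth <- list(case_id = case@caseId, side = case@side, seed = case@seed,
                transform_rowmajor = as.numeric(t(transformMatrix(case@trueDisplacement))))
  if (!is.null(case@resorption))
    truth$resorption <- list(target_region = case@resorption@targetRegion,
                             magnitude = case@resorption@magnitude,
                             falloff = case@resorption@falloff,
                             affected_fraction = case@resorption@affectedFraction)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCase
#' @export
readCase <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  mesh <- readMesh(file.path(dir, "preop.stl"))
  lms <- readLandmarks(file.path(dir, "landmarks.csv"))
  planes <- buildPlanes(lms, side = truth$side)
  labeling <- partitionRamus(mesh, planes)
  vol <- if (file.exists(file.path(dir, "preop.nii.gz")))
    readVolume(file.path(dir, "preop.nii.gz")) else NULL
  pm <- if (file.exists(file.path(dir, "postop.stl")))
    readMesh(file.path(dir, "postop.stl")) else NULL
  pv <- if (file.exists(file.path(dir, "postop.nii.gz")))
    readVolume(file.path(dir, "postop.nii.gz")) else NULL
  rs <- NULL
  if (!is.null(truth$resorption))
    rs <- resorptionSpec(truth$resorption$target_region,
                         truth$resorption$magnitude, truth$resorption$falloff,
                         truth$resorption$affected_fraction)
  new("SyntheticCase", caseId = truth$case_id, side = truth$side,
      preopMesh = mesh, preopVolume = vol, postopMesh = pm, postopVolume = pv,
      landmarks = lms, planes = planes, labeling = labeling,
      trueDisplacement = transformFromMatrix(
        matrix(truth$transform_rowmajor, 4, 4, byrow = TRUE)),
      resorption = rs, shapeParams = list(), seed = as.integer(truth$seed))
}
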