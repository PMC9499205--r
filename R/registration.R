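# The two masked rigid registration engines, run per side: iterative closest
# point on the reference-structure surface, and normalised mutual information
# on voxel intensities inside the reference-structure ROI.

#' Build the stable ramal reference structure
#'
#' Selects the coronoid process plus the ramal band between the mandibular
#' notch and the posterior border of the ramus: all faces below the C-plane
#' within the anteroposterior span of the ramus down to \code{bandDepth} of
#' the craniocaudal extent, plus the coronoid component, never the condyle.
#' Optionally derives the matching voxel mask (voxels within
#' \code{voxelBand} mm of the selected surface) on the grid of \code{volume}.
#'
#' @param mesh the preoperative ramus \linkS4class{SurfaceMesh}.
#' @param landmarks complete \linkS4class{LandmarkSet} for the side.
#' @param side "R" or "L".
#' @param planes optional precomputed \linkS4class{PlaneSet}.
#' @param roiOffsets named numeric(4) boundary jitter (mm): cPlane,
#'   posterior, anterior, inferior (observer variability of the selection).
#' @param bandDepth fraction of the C-plane-to-inferior extent included in
#'   the ramal band (default 0.4: the upper two of five craniocaudal rows).
#' @param volume \linkS4class{VoxelVolume} providing the ROI grid.
#' @param voxelBand half-thickness of the voxel ROI around the surface, mm.
#' @param makeVoxelMask set FALSE to skip the voxel mask.
#' @param observer observer id recorded on the structure.
#' @return A \linkS4class{ReferenceStructure}.
#' @export
buildReferenceStructure <- function(mesh, landmarks, side = c("R", "L"),
                                    planes = NULL,
                                    roiOffsets = c(cPlane = 0, posterior = 0,
                                                   anterior = 0, inferior = 0),
                                    bandDepth = 0.4, volume = NULL,
                                    voxelBand = 1.0, makeVoxelMask = !is.null(volume),
                                    observer = "obs1") {
  side <- match.arg(side)
  requireLandmarks(landmarks, c("C-point", "Con", "Cor", "Go", "RP"), side)
  if (is.null(planes)) planes <- buildPlanes(landmarks, side = side)
  fc <- faceCentroids(mesh)
  sdC <- planeDistance(fc, planes@cPlane)
  above <- which(sdC > 0)
  split <- condyleCoronoidSplit(mesh, fc, above, planes@anterior, sdC = sdC)
  coronoidFaces <- split$coronoid
  u <- planeDistance(fc, planes@posteriorRamus)
  D <- sum((planes@anteriorRamus@point - planes@posteriorRamus@point) *
             planes@posteriorRamus@normal)
  H <- -sum((planes@inferiorRamus@point - planes@cPlane@point) *
              planes@cPlane@normal)
  band <- which(sdC <= roiOffsets[["cPlane"]] &
                  -sdC <= bandDepth * H + roiOffsets[["inferior"]] &
                  u >= roiOffsets[["posterior"]] &
                  u <= D + roiOffsets[["anterior"]])
  sel <- sort(unique(c(coronoidFaces, band)))
  if (!length(sel)) stop("empty reference-structure selection")
  vm <- NULL
  if (makeVoxelMask) {
    if (is.null(volume)) stop("a volume is required to build the voxel mask")
    vm <- voxelMaskFromFaces(mesh, sel, volume, voxelBand)
  }
  new("ReferenceStructure", side = side, faces = as.integer(sel),
      voxelMask = vm, observer = observer)
}

# voxels of `volume` whose centre lies within `band` mm of the face subset
voxelMaskFromFaces <- function(mesh, faceIdx, volume, band) {
  sub <- submesh(mesh, faceIdx)
  d <- dim(volume@data)
  ext <- apply(sub@vertices, 2, range)
  loIdx <- pmax(floor((ext[1, ] - band - volume@origin) / volume@spacing) + 1, 1)
  hiIdx <- pmin(ceiling((ext[2, ] + band - volume@origin) / volume@spacing) + 1, d)
  idx <- as.matrix(expand.grid(i = loIdx[1]:hiIdx[1], j = loIdx[2]:hiIdx[2],
                               k = loIdx[3]:hiIdx[3]))
  w <- voxelToWorld(volume, idx)
  dist <- cpp_closest_point(w, sub@vertices, sub@faces)$distance
  m <- array(FALSE, d)
  m[idx[dist <= band, , drop = FALSE]] <- TRUE
  binaryMask(m, volume@spacing, volume@origin)
}

# ---------------------------------------------------------------------------
# ICP
# ---------------------------------------------------------------------------

#' ICP parameters
#' @param tol convergence tolerance on the change of the mean residual, mm.
#' @param maxIterations iteration cap.
#' @param maxPoints moving-vertex subsample size.
#' @param captureDistance moving vertices farther than this (mm, after the
#'   initial transform) from the fixed reference surface are not used.
#' @param trimFraction fraction of worst correspondences discarded per
#'   iteration (0 = none).
#' @export
icpParams <- function(tol = 1e-6, maxIterations = 200L, maxPoints = 1500L,
                      captureDistance = 2, trimFraction = 0) {
  list(tol = tol, maxIterations = as.integer(maxIterations),
       maxPoints = as.integer(maxPoints), captureDistance = captureDistance,
       trimFraction = trimFraction)
}

#' Surface-based rigid registration (iterative closest point)
#'
#' Aligns the moving (postoperative) mesh to the fixed (preoperative) mesh
#' using only the reference structure: moving vertices that start near the
#' fixed reference surface are matched to their closest points on that
#' surface (point-to-triangle), a closed-form rigid update is fitted, and
#' the loop repeats until the mean residual change falls below \code{tol}.
#' Deterministic given its inputs.
#'
#' @param fixedMesh,movingMesh \linkS4class{SurfaceMesh} objects.
#' @param reference \linkS4class{ReferenceStructure} on the fixed mesh.
#' @param init initial \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{prealign}}).
#' @param params see \code{\link{icpParams}}.
#' @return A \linkS4class{RegistrationResult}; the transform maps the moving
#'   mesh into the fixed frame.
#' @export
icpRegister <- function(fixedMesh, movingMesh, reference,
                        init = rigidIdentity(), params = icpParams()) {
  if (length(reference@faces) < 2)
    stop("reference structure has too few faces for surface registration")
  refMesh <- submesh(fixedMesh, reference@faces)
  M <- movingMesh@vertices
  M0 <- applyTransform(M, init)
  # a moving vertex belongs to the reference region if its closest point on
  # the full fixed surface lies on a reference face (and is within capture
  # range); this keeps near-boundary off-region vertices from biasing the fit
  cp0 <- cpp_closest_point(M0, fixedMesh@vertices, fixedMesh@faces)
  usable <- which(cp0$distance <= params$captureDistance &
                    cp0$face %in% reference@faces)
  if (length(usable) < 10)
    stop("fewer than 10 moving vertices near the reference surface; ",
         "check the initial alignment")
  if (length(usable) > params$maxPoints)
    usable <- usable[round(seq(1, length(usable), length.out = params$maxPoints))]
  P <- M[usable, , drop = FALSE]
  Tcur <- init
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  res <- NA_real_
  while (iter < params$maxIterations) {
    iter <- iter + 1L
    Pt <- applyTransform(P, Tcur)
    cp <- cpp_closest_point(Pt, refMesh@vertices, refMesh@faces)
    tgt <- cp$closest
    src <- P
    if (params$trimFraction > 0) {
      keep <- order(cp$distance)[seq_len(ceiling((1 - params$trimFraction) *
                                                   length(cp$distance)))]
      src <- P[keep, , drop = FALSE]; tgt <- tgt[keep, , drop = FALSE]
    }
    Tcur <- kabsch(tgt, src)
    res <- mean(cpp_closest_point(applyTransform(src, Tcur), refMesh@vertices,
                                  refMesh@faces)$distance)
    if (is.finite(prev) && abs(prev - res) < params$tol) {
      converged <- TRUE
      break
    }
    prev <- res
  }
  new("RegistrationResult", transform = rigidTransform(Tcur@rotation, Tcur@translation),
      converged = converged, finalMetric = res, iterations = iter,
      method = "surface",
      diagnostics = list(nPoints = nrow(P), trimFraction = params$trimFraction))
}

# ---------------------------------------------------------------------------
# NMI voxel registration
# ---------------------------------------------------------------------------

#' Voxel-engine parameters
#' @param nBins joint-histogram size per axis.
#' @param levels multi-resolution downsampling factors, coarse to fine.
#' @param initialStep,minStep regular-step gradient-ascent step lengths (mm
#'   at the rotation lever arm), per finest level.
#' @param maxIterations iteration cap per level.
#' @param minRoiVoxels insufficient-information threshold on ROI size.
#' @param minEntropyBits insufficient-information threshold on the joint
#'   intensity entropy (bits) of the initial ROI histogram.
#' @param minMovingEntropyBits companion threshold on the moving-image
#'   marginal entropy under the ROI (the statistic that collapses when the
#'   reference structure has remodelled away); either entropy below its bar
#'   raises the failure.
#' @param rotationLever parameter scaling between rotation (radians) and
#'   translation (mm), mm.
#' @export
miParams <- function(nBins = 32L, levels = c(4L, 2L, 1L), initialStep = 2,
                     minStep = 0.01, maxIterations = 200L,
                     minRoiVoxels = 500L, minEntropyBits = 0.5,
                     minMovingEntropyBits = 0.5, rotationLever = 30) {
  list(nBins = as.integer(nBins), levels = as.integer(levels),
       initialStep = initialStep, minStep = minStep,
       maxIterations = as.integer(maxIterations),
       minRoiVoxels = as.integer(minRoiVoxels),
       minEntropyBits = minEntropyBits,
       minMovingEntropyBits = minMovingEntropyBits,
       rotationLever = rotationLever)
}

shannonBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

insufficientInformation <- function(msg, diagnostics = list()) {
  stop(structure(class = c("insufficientInformation", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

#' Voxel-based rigid registration (normalised mutual information)
#'
#' Maximises the normalised mutual information (H(F) + H(M)) / H(F, M) of
#' the joint 32 x 32 intensity histogram, computed with partial-volume
#' (trilinear-weight) binning over the fixed-image voxels inside the ROI
#' mask against the moving image, over the 6 rigid degrees of freedom, by a
#' deterministic regular-step gradient ascent within a 3-level
#' multi-resolution pyramid. An ROI below the minimum voxel count, or whose
#' intensity entropy (fixed, or moving under the initial transform) is below
#' the threshold, raises an explicit "insufficientInformation" condition:
#' there is not enough mutual image information to control the 3D transform.
#'
#' @param fixedVolume,movingVolume \linkS4class{VoxelVolume} objects
#'   (preoperative = fixed).
#' @param roiMask \linkS4class{BinaryMask} on the fixed grid.
#' @param init initial \linkS4class{RigidTransform} (moving -> fixed frame).
#' @param params see \code{\link{miParams}}.
#' @return A \linkS4class{RegistrationResult}; the transform maps the moving
#'   volume into the fixed frame.
#' @export
miRegister <- function(fixedVolume, movingVolume, roiMask,
                       init = rigidIdentity(), params = miParams()) {
  if (!all(dim(roiMask@data) == dim(fixedVolume@data)))
    stop("ROI mask is not on the fixed-volume grid")
  roiIdx <- which(roiMask@data)
  if (length(roiIdx) < params$minRoiVoxels)
    insufficientInformation(sprintf(
      "ROI has %d voxels, below the minimum of %d",
      length(roiIdx), params$minRoiVoxels))
  d <- dim(fixedVolume@data)
  ijk <- arrayInd(roiIdx, d)
  fpts <- voxelToWorld(fixedVolume, ijk)
  fint <- fixedVolume@data[roiIdx]
  nb <- params$nBins
  frng <- range(fint)
  if (diff(frng) <= 0)
    insufficientInformation("ROI intensity is constant (zero entropy)")
  fbin <- pmin(pmax(floor((fint - frng[1]) / diff(frng) * nb), 0), nb - 1)
  hf <- shannonBits(tabulate(fbin + 1L, nb) / length(fbin))
  Minv <- invertTransform(init) # fixed frame -> moving frame
  mrng <- range(movingVolume@data)
  if (diff(mrng) <= 0)
    insufficientInformation("moving volume intensity is constant")
  mBinW <- diff(mrng) / nb
  sampleH <- function(Tfm, vol, stride) {
    sel <- seq(1, nrow(fpts), by = stride)
    mp <- applyTransform(fpts[sel, , drop = FALSE], Tfm)
    mpIdx <- sweep(sweep(mp, 2, vol@origin, "-"), 2, vol@spacing, "/")
    H <- cpp_pv_hist(mpIdx, as.integer(fbin[sel]), as.numeric(vol@data),
                     as.integer(dim(vol@data)), nb, mrng[1], mBinW)
    H
  }
  Hinit <- sampleH(Minv, movingVolume, 1L)
  if (sum(Hinit) < params$minRoiVoxels / 2)
    insufficientInformation("ROI falls mostly outside the moving volume under the initial transform")
  hmInit <- shannonBits(colSums(Hinit) / sum(Hinit))
  hJoint <- shannonBits(as.numeric(Hinit) / sum(Hinit))
  # a well-aligned two-level ROI legitimately sits at ~1 bit of joint
  # entropy; what collapses when the reference structure has resorbed away is
  # the moving-image marginal under the ROI. Either entropy falling below its
  # bar means there is not enough mutual image information.
  if (hJoint < params$minEntropyBits || hmInit < params$minMovingEntropyBits)
    insufficientInformation(sprintf(
      "joint intensity entropy %.2f bits / moving-image entropy %.2f bits under the ROI: not enough mutual image information to control the transform",
      hJoint, hmInit))

  ctr <- colMeans(fpts)
  L <- params$rotationLever
  # parameter vector p: rotation (rad * L) about ctr, then translation (mm),
  # describing the fixed->moving map
  p2t <- function(p) rigidFromEuler(p[1:3] / L * 180 / pi, p[4:6], center = ctr)
  nmiOf <- function(H) {
    s <- sum(H)
    if (s <= 0) return(-Inf)
    P <- H / s
    hF <- shannonBits(rowSums(P)); hM <- shannonBits(colSums(P))
    hJ <- shannonBits(as.numeric(P))
    if (hJ <= 0) return(-Inf)
    (hF + hM) / hJ
  }
  # initial p from init (rotation about ctr)
  Rm <- Minv@rotation
  angY <- asin(-Rm[3, 1])
  angZ <- atan2(Rm[2, 1], Rm[1, 1])
  angX <- atan2(Rm[3, 2], Rm[3, 3])
  tpart <- applyTransform(ctr, Minv) - ctr
  p <- c(c(angX, angY, angZ) * L, tpart)
  totalIter <- 0L
  converged <- TRUE
  for (li in seq_along(params$levels)) {
    lev <- params$levels[li]
    vol <- downsampleVolume(movingVolume, lev)
    stride <- max(lev, 1L)
    f <- function(pp) nmiOf(sampleH(p2t(pp), vol, stride))
    step <- params$initialStep * lev
    minStep <- params$minStep * lev
    cur <- f(p)
    it <- 0L
    while (step > minStep && it < params$maxIterations) {
      it <- it + 1L
      g <- numeric(6)
      h <- step / 4
      for (q in 1:6) {
        e <- numeric(6); e[q] <- h
        g[q] <- (f(p + e) - f(p - e)) / (2 * h)
      }
      gn <- vnorm(g)
      if (gn < 1e-12) { step <- step / 2; next }
      cand <- p + step * g / gn
      cf <- f(cand)
      if (cf > cur) {
        p <- cand; cur <- cf
      } else {
        step <- step / 2
      }
    }
    if (it >= params$maxIterations && li == length(params$levels))
      converged <- FALSE
    totalIter <- totalIter + it
  }
  final <- nmiOf(sampleH(p2t(p), movingVolume, 1L))
  new("RegistrationResult", transform = invertTransform(p2t(p)),
      converged = converged, finalMetric = -final, iterations = totalIter,
      method = "voxel",
      diagnostics = list(nRoiVoxels = length(roiIdx), fixedEntropyBits = hf,
                         movingEntropyBits = hmInit, nmi = final))
}

#' Compare two rigid transforms
#'
#' Rotation discrepancy (degrees) and translation discrepancy measured as
#' the displacement difference at a reference point.
#' @param t1,t2 \linkS4class{RigidTransform} objects.
#' @param at reference point (mm) at which the translation difference is
#'   evaluated.
#' @export
transformDiscrepancy <- function(t1, t2, at = c(0, 0, 0)) {
  dT <- composeTransforms(invertTransform(t2), t1)
  c(rotationDeg = rotationAngle(dT) * 180 / pi,
    translationMm = vnorm(applyTransform(at, t1) - applyTransform(at, t2)))
}

#' Target registration error over a point set
#'
#' Mean distance between points mapped by an estimated transform and by the
#' ground-truth one.
#' @param estimated,truth \linkS4class{RigidTransform} objects.
#' @param points n x 3 matrix of evaluation points (e.g. reference vertices).
#' @export
targetRegistrationError <- function(estimated, truth, points) {
  mean(rowNorms(applyTransform(points, estimated) -
                  applyTransform(points, truth)))
}
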