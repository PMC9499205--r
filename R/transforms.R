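# Rigid 6-DOF transforms: construction, composition, inversion, application.

#' Create a rigid transform
#'
#' @param rotation 3 x 3 orthonormal rotation matrix with det = +1.
#' @param translation numeric(3) translation in mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Identity rigid transform
#' @export
rigidIdentity <- function() rigidTransform()

#' Rigid transform from Euler angles
#'
#' Intrinsic rotations about the fixed x, y, z axes (applied in that order),
#' optionally about a centre point.
#'
#' @param anglesDeg numeric(3) rotation angles in degrees.
#' @param translation numeric(3) translation in mm.
#' @param center optional numeric(3) rotation centre (mm).
#' @export
rigidFromEuler <- function(anglesDeg = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  a <- anglesDeg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  t <- as.numeric(translation) + as.numeric(center) - R %*% as.numeric(center)
  rigidTransform(R, t)
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(t2, t1)} is the transform "apply t1, then t2".
#' @param t2,t1 \linkS4class{RigidTransform} objects.
#' @export
composeTransforms <- function(t2, t1) {
  rigidTransform(t2@rotation %*% t1@rotation,
                 as.numeric(t2@rotation %*% t1@translation) + t2@translation)
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' Rotation angle of a rigid transform (radians)
#' @param transform a \linkS4class{RigidTransform}.
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@rotation))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

#' 4 x 4 homogeneous matrix of a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @export
transformMatrix <- function(transform) {
  M <- diag(4)
  M[1:3, 1:3] <- transform@rotation
  M[1:3, 4] <- transform@translation
  M
}

#' Rigid transform from a 4 x 4 homogeneous matrix
#'
#' Rejects matrices whose upper-left block is not a proper rotation
#' (non-orthonormal beyond tolerance, or det != +1).
#' @param M 4 x 4 numeric matrix.
#' @export
transformFromMatrix <- function(M) {
  if (!all(dim(M) == c(4, 4))) stop("expected a 4 x 4 matrix")
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("matrix is not a proper rigid transform (non-orthonormal or det != +1)")
  # re-orthonormalise residual float error so validity holds exactly
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigidTransform(R, M[1:3, 4])
}

#' Apply a rigid transform
#'
#' Generic over point matrices, meshes, landmark sets and voxel volumes.
#' Volumes are resampled onto their own grid by trilinear interpolation
#' (values outside the source grid become \code{background}).
#'
#' @param x object to transform.
#' @param transform a \linkS4class{RigidTransform}.
#' @param ... further arguments (\code{background} for volumes).
#' @export
setGeneric("applyTransform", function(x, transform, ...)
  standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform, ...) {
  stopifnot(ncol(x) == 3)
  x %*% t(transform@rotation) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "numeric", function(x, transform, ...) {
  as.numeric(transform@rotation %*% x) + transform@translation
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "SurfaceMesh", function(x, transform, ...) {
  new("SurfaceMesh", vertices = applyTransform(x@vertices, transform),
      faces = x@faces, faceLabels = x@faceLabels)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "LandmarkSet", function(x, transform, ...) {
  new("LandmarkSet", name = x@name, side = x@side,
      coords = applyTransform(x@coords, transform), provenance = x@provenance)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "VoxelVolume", function(x, transform, background = 0, ...) {
  d <- dim(x@data)
  inv <- invertTransform(transform)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  world <- sweep(sweep(idx - 1, 2, x@spacing, "*"), 2, x@origin, "+")
  src <- applyTransform(world, inv)
  srcIdx <- sweep(sweep(src, 2, x@origin, "-"), 2, x@spacing, "/")
  vals <- cpp_trilinear(srcIdx, as.numeric(x@data), as.integer(d), background)
  new("VoxelVolume", data = array(vals, d), spacing = x@spacing, origin = x@origin)
})

#' Closed-form least-squares rigid alignment of paired points
#'
#' Solves the orthogonal Procrustes problem for the rigid transform that maps
#' \code{moving} onto \code{fixed} in the least-squares sense, via SVD of the
#' cross-covariance (Kabsch), with the determinant correction that excludes
#' reflections.
#'
#' @param fixed,moving n x 3 matrices of paired points (n >= 3, non-collinear).
#' @return A \linkS4class{RigidTransform} with attribute \code{rmse}
#'   (root-mean-square residual, mm).
#' @export
kabsch <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (nrow(fixed) != nrow(moving)) stop("point sets must be paired")
  if (nrow(fixed) < 3) stop("at least 3 point pairs are required")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  F0 <- sweep(fixed, 2, cf); M0 <- sweep(moving, 2, cm)
  # collinearity check: second singular value of the centred cloud
  svF <- svd(M0)$d
  if (svF[2] < 1e-9 * max(svF[1], 1))
    stop("point configuration is collinear; rigid fit is degenerate")
  H <- crossprod(M0, F0)
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  tvec <- cf - as.numeric(R %*% cm)
  out <- rigidTransform(R, tvec)
  res <- applyTransform(moving, out) - fixed
  attr(out, "rmse") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Landmark-based pre-alignment
#'
#' Rigidly aligns the moving landmark set onto the fixed one (paired by
#' landmark name and side) in closed form; the manual pre-alignment step that
#' initialises both registration engines.
#'
#' @param fixedLandmarks,movingLandmarks \linkS4class{LandmarkSet} objects
#'   sharing at least 3 non-collinear (name, side) pairs.
#' @return A \linkS4class{RigidTransform} with attribute \code{rmse}.
#' @export
prealign <- function(fixedLandmarks, movingLandmarks) {
  kf <- paste(fixedLandmarks@name, fixedLandmarks@side)
  km <- paste(movingLandmarks@name, movingLandmarks@side)
  common <- intersect(kf, km)
  if (length(common) < 3)
    stop("prealign needs at least 3 shared landmark pairs, got ", length(common))
  kabsch(fixedLandmarks@coords[match(common, kf), , drop = FALSE],
         movingLandmarks@coords[match(common, km), , drop = FALSE])
}

#' Draw a random rigid transform
#'
#' Uniform rotation angles up to \code{maxRotDeg} about each axis and a
#' translation uniform in the ball of radius \code{maxTranslation}.
#'
#' @param maxTranslation maximum translation norm, mm.
#' @param maxRotDeg maximum per-axis rotation, degrees.
#' @param center rotation centre (mm).
#' @param seed integer seed.
#' @export
randomRigidTransform <- function(maxTranslation = 5, maxRotDeg = 10,
                                 center = c(0, 0, 0), seed = 1L) {
  withSeed(seed, {
    ang <- runif(3, -maxRotDeg, maxRotDeg)
    dir <- rnorm(3); dir <- dir / vnorm(dir)
    r <- maxTranslation * runif(1)^(1 / 3)
    rigidFromEuler(ang, dir * r, center = center)
  })
}
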