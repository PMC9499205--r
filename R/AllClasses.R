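#' @useDynLib ramus3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames setValidity show
#' @importFrom stats rnorm runif sd qf pt var quantile cor aov anova lm t.test
#'   p.adjust aggregate
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools file_ext
#' @importFrom grDevices colorRamp rgb
NULL

# ---------------------------------------------------------------------------
# VoxelVolume / BinaryMask
# ---------------------------------------------------------------------------

#' VoxelVolume: a 3D scalar grid with physical geometry
#'
#' Carrier of CBCT-like intensities (HU-like, uncalibrated) on a regular,
#' axis-aligned, right-handed grid. World coordinates of voxel (i,j,k)
#' (1-based) are \code{origin + (c(i,j,k) - 1) * spacing}.
#'
#' @slot data 3D numeric (or logical for masks) array.
#' @slot spacing numeric(3), mm per axis, all positive.
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 2L)) return("grid dimensions must be >= 2 per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' BinaryMask: boolean occupancy on the grid of its source volume
#' @export
setClass("BinaryMask", contains = "VoxelVolume")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  TRUE
})

# ---------------------------------------------------------------------------
# SurfaceMesh
# ---------------------------------------------------------------------------

#' SurfaceMesh: triangulated bone surface in mm
#'
#' @slot vertices n x 3 numeric matrix (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices; consistent
#'   counter-clockwise orientation seen from outside where watertight.
#' @slot faceLabels optional character vector (length m) of region labels.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", faceLabels = "character"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) > 0) {
    rng <- range(object@faces)
    if (rng[1] < 1L || rng[2] > nrow(object@vertices))
      return("face indices out of range")
  }
  if (length(object@faceLabels) > 0 &&
      length(object@faceLabels) != nrow(object@faces))
    return("faceLabels length must equal number of faces")
  TRUE
})

# ---------------------------------------------------------------------------
# RigidTransform
# ---------------------------------------------------------------------------

#' RigidTransform: proper rigid motion (rotation + translation)
#'
#' Maps points by \code{x -> R x + t}. The rotation must be orthonormal with
#' determinant +1 (no reflection, no scaling).
#' @slot rotation 3 x 3 orthonormal matrix, det = +1.
#' @slot translation numeric(3), mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal within 1e-8")
  if (det(R) < 0) return("rotation has negative determinant (reflection)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be 3 finite values (mm)")
  TRUE
})

# ---------------------------------------------------------------------------
# Landmarks, planes, regions
# ---------------------------------------------------------------------------

#' LandmarkSet: named cephalometric points in mm
#'
#' Landmark names follow the standard 3D cephalometric set: Or and Po (the
#' Frankfurt plane points, on cranial reference geometry), C-point (most
#' caudal point of the mandibular notch), Con, Cor, Go, RP and RI on the
#' ramus, each with side R or L.
#' @slot name character vector of landmark names.
#' @slot side character vector, "R" or "L".
#' @slot coords n x 3 numeric matrix (mm).
#' @slot provenance character vector: "manual", "derived" or "auxiliary".
#' @export
setClass("LandmarkSet",
  representation(name = "character", side = "character",
                 coords = "matrix", provenance = "character"))

setValidity("LandmarkSet", function(object) {
  n <- length(object@name)
  if (length(object@side) != n || nrow(object@coords) != n ||
      length(object@provenance) != n) return("field lengths differ")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (n > 0 && any(!is.finite(object@coords))) return("non-finite coordinates")
  if (n > 0 && !all(object@side %in% c("R", "L")))
    return("side must be 'R' or 'L'")
  TRUE
})

#' Plane3: an oriented plane (point + unit normal)
#' @export
setClass("Plane3", representation(point = "numeric", normal = "numeric"))

setValidity("Plane3", function(object) {
  if (length(object@point) != 3L || length(object@normal) != 3L)
    return("point and normal must be length 3")
  if (abs(vnorm(object@normal) - 1) > 1e-9) return("normal must be unit length")
  TRUE
})

#' PlaneSet: the anatomical cutting planes of one ramus
#'
#' Holds the Frankfurt plane, the C-plane (through C-point, parallel to
#' Frankfurt), the ramus plane (through Con, Cor, Go), the posterior,
#' anterior and inferior ramus planes, and the equally spaced intermediate
#' planes used to partition the ramal part, together with the oriented
#' anatomical axes derived from them.
#' @export
setClass("PlaneSet",
  representation(frankfurt = "Plane3", cPlane = "Plane3", ramusPlane = "Plane3",
                 posteriorRamus = "Plane3", anteriorRamus = "Plane3",
                 inferiorRamus = "Plane3", intermediatesAP = "list",
                 intermediatesCI = "list", side = "character",
                 anterior = "numeric", superior = "numeric",
                 nApBands = "integer", nCiBands = "integer"))

#' RegionLabeling: per-face anatomical region labels
#'
#' Labels over {condyle, coronoid, R01..R20}; the condyle and coronoid lie
#' above the C-plane, the twenty subregions tile the ramal part below it.
#' @export
setClass("RegionLabeling",
  representation(labels = "character", levels = "character",
                 separator = "Plane3", planes = "PlaneSet"))

# ---------------------------------------------------------------------------
# Registration
# ---------------------------------------------------------------------------

#' ReferenceStructure: the stable ramal region driving registration
#'
#' The coronoid process plus the ramal band between the mandibular notch and
#' the posterior border, excluding the condyle: the surface-mask form (face
#' subset of the preoperative mesh) drives the ICP engine, the voxel-mask
#' form drives the mutual-information engine.
#' @export
setClass("ReferenceStructure",
  representation(side = "character", faces = "integer",
                 voxelMask = "ANY", observer = "character"))

#' RegistrationResult: output of either rigid registration engine
#' @slot transform estimated rigid transform mapping the postoperative
#'   (moving) frame into the preoperative (fixed) frame.
#' @slot converged logical convergence flag.
#' @slot finalMetric mean closest-point residual (mm) for ICP; negative
#'   normalised mutual information for the voxel engine.
#' @slot iterations iteration count.
#' @slot method "surface" or "voxel".
#' @slot diagnostics list of engine-specific diagnostics.
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", converged = "logical",
                 finalMetric = "numeric", iterations = "integer",
                 method = "character", diagnostics = "list"))

# ---------------------------------------------------------------------------
# Synthetic cases
# ---------------------------------------------------------------------------

#' ResorptionSpec: parametric inward remodelling of a region
#'
#' @slot targetRegion region label ("condyle", "coronoid", "R01".."R20") or
#'   "reference_structure".
#' @slot magnitude maximum inward surface displacement, mm (>= 0).
#' @slot falloff smoothness scale of the compactly supported radial falloff, mm.
#' @slot affectedFraction fraction (0-1) of the target region affected.
#' @export
setClass("ResorptionSpec",
  representation(targetRegion = "character", magnitude = "numeric",
                 falloff = "numeric", affectedFraction = "numeric"))

setValidity("ResorptionSpec", function(object) {
  if (object@magnitude < 0) return("magnitude must be >= 0")
  if (object@falloff <= 0) return("falloff must be > 0")
  if (object@affectedFraction < 0 || object@affectedFraction > 1)
    return("affectedFraction must be in [0, 1]")
  TRUE
})

setClassUnion("OptionalMesh", c("SurfaceMesh", "NULL"))
setClassUnion("OptionalVolume", c("VoxelVolume", "NULL"))
setClassUnion("OptionalResorption", c("ResorptionSpec", "NULL"))

#' SyntheticCase: one ground-truthed pre/post ramus case
#'
#' A parametric hemimandible-ramus phantom: preoperative mesh and CBCT-like
#' volume, the full Table-style landmark set computed from the mesh, the
#' ground-truth rigid displacement, the resorption specification, and (once
#' built) the postoperative mesh/volume.
#' @export
setClass("SyntheticCase",
  representation(caseId = "character", side = "character",
                 preopMesh = "SurfaceMesh", preopVolume = "OptionalVolume",
                 postopMesh = "OptionalMesh", postopVolume = "OptionalVolume",
                 landmarks = "LandmarkSet", planes = "PlaneSet",
                 labeling = "RegionLabeling",
                 trueDisplacement = "RigidTransform",
                 resorption = "OptionalResorption",
                 shapeParams = "list", seed = "integer"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n", class(object),
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (length(object@faceLabels))
                sprintf(", %d region labels", length(unique(object@faceLabels)))
              else ""))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation [%s] mm\n",
              ang, paste(format(object@translation, digits = 4), collapse = ", ")))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks (%s)\n", length(object@name),
              paste(unique(object@name), collapse = ", ")))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%s): converged = %s, metric = %.6g, %d iterations\n",
              object@method, object@converged, object@finalMetric,
              object@iterations))
})

setMethod("show", "SyntheticCase", function(object) {
  cat(sprintf("SyntheticCase %s (side %s): %d-face preop mesh, seed %d%s\n",
              object@caseId, object@side, nrow(object@preopMesh@faces),
              object@seed,
              if (!is.null(object@postopMesh)) ", postop built" else ""))
})
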