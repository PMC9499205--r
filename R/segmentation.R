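# Bone segmentation and surface reconstruction: threshold region growing from
# a seed, cavity filling, isosurface extraction with smoothing + decimation.

#' Threshold region-growing bone segmentation
#'
#' The mask is the 26-connected component of supra-threshold voxels that
#' contains the seed point. The default lower threshold of 226 is the
#' standard predefined CT-bone threshold (HU-like; CBCT grey values are not
#' HU-calibrated, only separability matters).
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param seedPoint numeric(3) world coordinates (mm) of a voxel inside bone.
#' @param lowerThreshold lower intensity threshold, default 226.
#' @return A \linkS4class{BinaryMask}.
#' @export
segmentBone <- function(volume, seedPoint, lowerThreshold = 226) {
  d <- dim(volume@data)
  idx <- round(worldToVoxel(volume, matrix(seedPoint, 1, 3)))
  if (any(idx < 1) || any(idx > d))
    stop("seed point lies outside the volume grid")
  if (volume@data[idx[1], idx[2], idx[3]] < lowerThreshold)
    stop(sprintf("seed error: intensity %.1f at the seed is below the threshold %.1f",
                 volume@data[idx[1], idx[2], idx[3]], lowerThreshold))
  supra <- volume@data >= lowerThreshold
  lab <- cpp_label_components(as.logical(supra), as.integer(d), 26L)
  seedLab <- lab[(idx[3] - 1) * d[1] * d[2] + (idx[2] - 1) * d[1] + idx[1]]
  binaryMask(array(lab == seedLab, d), volume@spacing, volume@origin)
}

#' Fill interior cavities of a mask
#'
#' Background components (6-connectivity) not connected to the grid boundary
#' are interior cavities and are set to foreground; the exterior is untouched.
#' Idempotent.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @export
fillMask <- function(mask) {
  d <- dim(mask@data)
  if (!any(mask@data)) stop("fillMask: mask is empty")
  bg <- cpp_label_components(as.logical(!mask@data), as.integer(d), 6L)
  bgArr <- array(bg, d)
  boundaryLabs <- unique(c(bgArr[c(1, d[1]), , ], bgArr[, c(1, d[2]), ],
                           bgArr[, , c(1, d[3])]))
  boundaryLabs <- setdiff(boundaryLabs, 0L)
  cavity <- bgArr != 0L & !(bgArr %in% boundaryLabs)
  binaryMask(mask@data | cavity, mask@spacing, mask@origin)
}

#' Keep only the largest connected component of a mask
#'
#' Batch replacement for interactive noise removal: discards all but the
#' largest 26-connected foreground component.
#' @param mask a \linkS4class{BinaryMask}.
#' @export
largestComponent <- function(mask) {
  d <- dim(mask@data)
  lab <- cpp_label_components(as.logical(mask@data), as.integer(d), 26L)
  if (attr(lab, "ncomp") <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  binaryMask(array(lab == which.max(counts), d), mask@spacing, mask@origin)
}

#' Reconstruct a smoothed, decimated bone surface from a mask
#'
#' Extracts a watertight isosurface of the mask (marching tetrahedra at the
#' 0.5 occupancy level), applies volume-bias-compensated Laplacian smoothing
#' and finally bounded edge-collapse decimation. The defaults mirror a
#' standard clinical reconstruction configuration: 10 smoothing iterations at
#' factor 0.2, decimation tolerance 0.0375 mm with a 10 degree edge angle and
#' 3 decimation passes.
#'
#' @param mask a nonempty, single-component \linkS4class{BinaryMask}.
#' @param smoothIterations,smoothFactor smoothing parameters
#'   (\code{\link{smoothMesh}}).
#' @param decimTolerance,edgeAngle,decimIterations decimation parameters
#'   (\code{\link{decimateMesh}}); \code{decimIterations = 0} skips decimation.
#' @return A watertight \linkS4class{SurfaceMesh} in world coordinates (mm).
#' @export
reconstructSurface <- function(mask, smoothIterations = 10, smoothFactor = 0.2,
                               decimTolerance = 0.0375, edgeAngle = 10,
                               decimIterations = 3) {
  d <- dim(mask@data)
  if (!any(mask@data)) stop("reconstructSurface: mask is empty")
  lab <- cpp_label_components(as.logical(mask@data), as.integer(d), 26L)
  if (attr(lab, "ncomp") > 1L)
    stop("mask has ", attr(lab, "ncomp"),
         " connected components; segment and reconstruct each component separately")
  # pad by one empty layer so the isosurface is closed at the grid boundary
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask@data)
  iso <- cpp_march_tets(as.numeric(padded), as.integer(d + 2L), 0.5)
  # grid index (0-based, padded) -> world mm
  V <- sweep(sweep(iso$vertices - 1, 2, mask@spacing, "*"), 2, mask@origin, "+")
  mesh <- surfaceMesh(V, iso$faces)
  mesh <- smoothMesh(mesh, smoothIterations, smoothFactor)
  if (decimIterations > 0)
    mesh <- decimateMesh(mesh, decimTolerance, edgeAngle, decimIterations)
  mesh
}
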