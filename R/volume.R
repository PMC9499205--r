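# VoxelVolume construction, coordinate helpers, voxelization of meshes.

#' Construct a voxel volume
#'
#' @param data 3D numeric array of intensities (HU-like).
#' @param spacing numeric(3) or scalar, mm per axis.
#' @param origin numeric(3), world position of the first voxel centre (mm).
#' @export
voxelVolume <- function(data, spacing = 0.30, origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a binary mask on the grid of a volume
#' @param data 3D logical array.
#' @param spacing,origin grid geometry, as for \code{\link{voxelVolume}}.
#' @export
binaryMask <- function(data, spacing = 0.30, origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname voxelVolume
#' @param volume a \linkS4class{VoxelVolume}.
#' @export
voxelData <- function(volume) volume@data

#' @rdname voxelVolume
#' @export
voxelSpacing <- function(volume) volume@spacing

#' @rdname voxelVolume
#' @export
voxelOrigin <- function(volume) volume@origin

# world coordinates of voxel centres for 1-based index matrix
voxelToWorld <- function(volume, idx) {
  sweep(sweep(idx - 1, 2, volume@spacing, "*"), 2, volume@origin, "+")
}

worldToVoxel <- function(volume, world) {
  sweep(sweep(world, 2, volume@origin, "-"), 2, volume@spacing, "/") + 1
}

allVoxelCenters <- function(volume) {
  d <- dim(volume@data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  voxelToWorld(volume, idx)
}

#' Voxelize a closed mesh into a CBCT-like intensity volume
#'
#' Voxels whose centre lies inside the mesh receive the bone-level intensity,
#' all others the background level; optional additive Gaussian noise. The
#' two-level intensity model reflects that CBCT grey values are not
#' HU-calibrated: only threshold separability of bone from background is
#' modelled. The default spacing is 0.30 mm isotropic and the default bone
#' level (800) sits well above the standard 226 bone threshold.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param spacing voxel spacing in mm (scalar = isotropic), default 0.30.
#' @param boneIntensity,backgroundIntensity two-level intensity model.
#' @param noiseSd standard deviation of additive Gaussian noise (0 = none).
#' @param seed integer seed for the noise.
#' @param margin padding around the mesh bounding box, mm.
#' @return A \linkS4class{VoxelVolume}.
#' @export
voxelizeMesh <- function(mesh, spacing = 0.30, boneIntensity = 800,
                         backgroundIntensity = 0, noiseSd = 0, seed = 1L,
                         margin = 2) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  ext <- apply(mesh@vertices, 2, range)
  if (any(spacing > (ext[2, ] - ext[1, ])))
    stop("voxel spacing exceeds the smallest extent of the mesh")
  origin <- ext[1, ] - margin
  dims <- as.integer(ceiling((ext[2, ] - ext[1, ] + 2 * margin) / spacing)) + 1L
  occ <- cpp_voxelize(mesh@vertices, mesh@faces, dims, origin, spacing)
  vals <- ifelse(occ, boneIntensity, backgroundIntensity)
  if (noiseSd > 0)
    vals <- vals + withSeed(seed, rnorm(length(vals), 0, noiseSd))
  voxelVolume(array(vals, dims), spacing, origin)
}

#' Occupancy mask of a mesh on a given grid
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param volume a \linkS4class{VoxelVolume} providing the grid.
#' @export
meshOccupancy <- function(mesh, volume) {
  d <- dim(volume@data)
  occ <- cpp_voxelize(mesh@vertices, mesh@faces, as.integer(d),
                      volume@origin, volume@spacing)
  binaryMask(array(occ, d), volume@spacing, volume@origin)
}

#' Mean-pool a volume by an integer factor (multi-resolution pyramid level)
#' @param volume a \linkS4class{VoxelVolume}.
#' @param factor integer downsampling factor per axis.
#' @export
downsampleVolume <- function(volume, factor) {
  if (factor == 1) return(volume)
  d <- dim(volume@data)
  nd <- d %/% factor
  if (any(nd < 2)) stop("volume too small to downsample by ", factor)
  a <- volume@data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                   seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  pooled <- apply(a, c(2, 4, 6), mean)
  voxelVolume(pooled, volume@spacing * factor,
              volume@origin + (factor - 1) / 2 * volume@spacing)
}
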