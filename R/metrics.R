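# Per-region surface-distance and volumetric discrepancy between the
# registered pre- and postoperative rami; colour-coded distance-map export.

#' Per-vertex surface distances between two aligned meshes
#'
#' For every source (preoperative) vertex, the distance to the closest point
#' on any target triangle (point-to-surface, not point-to-vertex), signed by
#' the target face normal: positive where the source lies outside the target
#' surface.
#'
#' @param sourceMesh,targetMesh \linkS4class{SurfaceMesh} objects in a
#'   common frame (post-registration).
#' @return list with numeric vectors \code{signed} and \code{absolute} (mm)
#'   and the index vector \code{face} of the closest target triangles.
#' @export
surfaceDistances <- function(sourceMesh, targetMesh) {
  if (nrow(sourceMesh@faces) == 0 || nrow(targetMesh@faces) == 0)
    stop("empty mesh")
  cp <- cpp_closest_point(sourceMesh@vertices, targetMesh@vertices,
                          targetMesh@faces)
  n <- faceNormals(targetMesh)[cp$face, , drop = FALSE]
  sgn <- sign(rowSums((sourceMesh@vertices - cp$closest) * n))
  sgn[sgn == 0] <- 1
  list(signed = sgn * cp$distance, absolute = cp$distance, face = cp$face)
}

#' Per-region accuracy: area-weighted mean absolute surface distance
#'
#' The accuracy measure for a registration method: the area-weighted mean of
#' the absolute surface distances over each region's faces (a face's
#' distance is the mean of its three vertex distances). Regions with no
#' faces are flagged missing (NA), never reported as zero.
#'
#' @param labeling a \linkS4class{RegionLabeling} of the source mesh.
#' @param distances output of \code{\link{surfaceDistances}} on that mesh.
#' @param mesh the labelled source \linkS4class{SurfaceMesh}.
#' @return named numeric vector, mm per region (plus \code{whole}).
#' @export
regionAccuracy <- function(labeling, distances, mesh) {
  absd <- distances$absolute
  F <- mesh@faces
  faceDist <- (absd[F[, 1]] + absd[F[, 2]] + absd[F[, 3]]) / 3
  areas <- faceAreas(mesh)
  out <- vapply(labeling@levels, function(lb) {
    i <- which(labeling@labels == lb)
    if (!length(i)) return(NA_real_)
    sum(faceDist[i] * areas[i]) / sum(areas[i])
  }, numeric(1))
  c(out, whole = sum(faceDist * areas) / sum(areas))
}

#' Exact per-region volumes by plane-clipped capped solids
#'
#' Each region's solid is the watertight mesh clipped by its bounding
#' half-spaces (interior planes only: outermost bands are open outward), with
#' cut sections capped exactly; volumes by the divergence theorem.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param labeling a \linkS4class{RegionLabeling} (carries the plane set).
#' @return named numeric vector, mm^3 per region.
#' @export
regionVolumes <- function(mesh, labeling) {
  if (!isWatertight(mesh)) stop("regionVolumes requires a watertight mesh")
  pl <- labeling@planes
  cpt <- pl@cPlane@point; sup <- pl@cPlane@normal
  np <- pl@posteriorRamus@normal
  nAp <- pl@nApBands; nCi <- pl@nCiBands
  out <- numeric(0)
  # condyle / coronoid: above the C-plane, split at the separator
  above <- clipMeshClosed(mesh, plane3(cpt, sup))
  sep <- labeling@separator
  out[["condyle"]] <- meshVolume(clipMeshClosed(above,
                                                plane3(sep@point, -sep@normal)))
  out[["coronoid"]] <- meshVolume(clipMeshClosed(above, sep))
  # subregion cells: clip the ramal part once per shared boundary plane
  # (outermost bands are open outward)
  below <- clipMeshClosed(mesh, plane3(cpt, -sup))
  for (ap in seq_len(nAp)) {
    col <- below
    if (ap > 1L) {
      b <- pl@intermediatesAP[[ap - 1L]]
      col <- clipMeshClosed(col, plane3(b@point, np))
    }
    if (ap < nAp) {
      b <- pl@intermediatesAP[[ap]]
      col <- clipMeshClosed(col, plane3(b@point, -np))
    }
    for (ci in seq_len(nCi)) {
      lb <- sprintf("R%02d", (ci - 1L) * nAp + ap)
      if (!lb %in% labeling@levels) next
      cell <- col
      if (ci > 1L) {
        b <- pl@intermediatesCI[[ci - 1L]]
        cell <- clipMeshClosed(cell, plane3(b@point, -sup))
      }
      if (ci < nCi) {
        b <- pl@intermediatesCI[[ci]]
        cell <- clipMeshClosed(cell, plane3(b@point, sup))
      }
      out[[lb]] <- meshVolume(cell)
    }
  }
  out[labeling@levels]
}

#' Signed percent volume change
#'
#' \code{(post - pre) / pre * 100}; reported signed, the absolute value is
#' used in the reliability summaries.
#' @param pre,post volumes (mm^3), scalars or equal-length vectors.
#' @export
percentVolumeChange <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be equal length")
  ifelse(pre > 0, (post - pre) / pre * 100, NA_real_)
}

#' Export a colour-coded surface-distance map
#'
#' Writes the mesh as ASCII PLY with the per-vertex signed distance as a
#' "quality" scalar and a symmetric blue-white-red diverging colour scale
#' about zero, clamped at \code{clamp} mm.
#'
#' @param mesh the source \linkS4class{SurfaceMesh}.
#' @param distances per-vertex signed distances (mm), e.g.
#'   \code{surfaceDistances(...)$signed}.
#' @param path output .ply path.
#' @param clamp symmetric colour-scale limit, mm.
#' @export
exportDistanceMap <- function(mesh, distances, path, clamp = 2) {
  if (length(distances) != nrow(mesh@vertices))
    stop("one distance per vertex required")
  x <- pmin(pmax(distances / clamp, -1), 1)
  ramp <- colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  cols <- ramp((x + 1) / 2)
  writePLY(mesh, path, quality = distances,
           colors = matrix(as.integer(round(cols)), ncol = 3))
  invisible(path)
}

#' Read back the scalar field of an exported distance map
#' @param path a .ply written by \code{\link{exportDistanceMap}}.
#' @export
readDistanceMap <- function(path) {
  m <- readPLY(path)
  list(mesh = m, distances = attr(m, "quality"))
}
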