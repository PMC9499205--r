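# File I/O: NIfTI volumes (via RNifti), STL and PLY meshes, landmark CSV,
# transform JSON sidecars, on-disk case bundles.

#' Read and write voxel volumes (NIfTI-1)
#'
#' Volumes are stored as NIfTI (.nii / .nii.gz) with the voxel spacing in the
#' header; masks as an integer datatype with values {0, 1} (recognised as
#' masks on read). The qform carries the origin. Round-tripping reproduces
#' grid, spacing and origin to float precision and mask values exactly.
#'
#' @param path file path ending in .nii or .nii.gz.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  sp <- hdr$pixdim[2:4]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  arr <- array(as.numeric(img), dim(img)[1:3])
  intTypes <- c(2L, 4L, 8L, 256L, 512L, 768L)
  if (hdr$datatype %in% intTypes && all(arr %in% c(0, 1)))
    return(binaryMask(array(arr > 0.5, dim(arr)), sp, origin))
  voxelVolume(arr, sp, origin)
}

#' @rdname readVolume
#' @param volume a \linkS4class{VoxelVolume} or \linkS4class{BinaryMask}.
#' @export
writeVolume <- function(volume, path) {
  isMask <- is(volume, "BinaryMask")
  arr <- if (isMask) array(as.integer(volume@data), dim(volume@data)) else volume@data
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, volume@spacing)
  m <- diag(4)
  m[1, 1] <- volume@spacing[1]; m[2, 2] <- volume@spacing[2]
  m[3, 3] <- volume@spacing[3]
  m[1:3, 4] <- volume@origin
  img <- RNifti::`qform<-`(img, structure(m, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# STL
# ---------------------------------------------------------------------------

#' Read and write triangle meshes (STL, PLY)
#'
#' STL is supported in binary and ASCII form; PLY in ASCII form with optional
#' per-vertex scalar ("quality") and colour properties and per-face integer
#' labels. STL stores a triangle soup, so \code{readMesh} welds coincident
#' vertices back together on read; triangle count round-trips exactly.
#'
#' @param path file path; format chosen by extension (.stl / .ply).
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = readSTL(path),
         ply = readPLY(path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname readMesh
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param binary for STL, write the 80-byte-header binary form (default) or
#'   ASCII.
#' @export
writeMesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = writeSTL(mesh, path, binary = binary),
         ply = writePLY(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

writeSTL <- function(mesh, path, binary = TRUE) {
  co <- faceCorners(mesh)
  n <- faceNormals(mesh)
  nf <- nrow(mesh@faces)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 little-endian floats + uint16 attribute per 50-byte record
    block <- rbind(t(n), t(co$a), t(co$b), t(co$c)) # 12 x nf
    fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    rec <- matrix(as.raw(0), 50, nf)
    rec[1:48, ] <- matrix(fl, 48, nf)
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- function(v) paste(formatC(v, format = "e", digits = 9), collapse = " ")
    writeLines("solid ramus3d", con)
    for (i in seq_len(nf)) {
      writeLines(c(paste("facet normal", fmt(n[i, ])), " outer loop",
                   paste("  vertex", fmt(co$a[i, ])),
                   paste("  vertex", fmt(co$b[i, ])),
                   paste("  vertex", fmt(co$c[i, ])),
                   " endloop", "endfacet"), con)
    }
    writeLines("endsolid ramus3d", con)
  }
}

readSTL <- function(path) {
  con <- file(path, "rb")
  head5 <- readBin(con, "raw", 5)
  close(con)
  if (rawToChar(head5) == "solid" && isAsciiSTL(path)) readSTLascii(path)
  else readSTLbinary(path)
}

isAsciiSTL <- function(path) {
  # binary STL may begin with "solid" too; check for "facet" in the first chunk
  txt <- suppressWarnings(readLines(path, n = 3))
  any(grepl("facet|endsolid", txt))
}

readSTLbinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- matrix(readBin(con, "raw", nf * 50), 50, nf)
  vals <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                  n = nf * 12, size = 4, endian = "little")
  vals <- matrix(vals, 12, nf) # normal + 3 vertices per column
  tri <- matrix(0, nf * 3, 3)
  for (v in 1:3)
    tri[seq(v, by = 3, length.out = nf), ] <- t(vals[(3 * v + 1):(3 * v + 3), ,
                                                     drop = FALSE])
  weldTriangleSoup(tri)
}

readSTLascii <- function(path) {
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums)) stop("malformed STL: non-numeric vertex coordinates")
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  weldTriangleSoup(nums)
}

weldTriangleSoup <- function(tri) {
  key <- apply(tri, 1, function(v) paste(formatC(v, format = "g", digits = 15),
                                         collapse = "_"))
  uid <- match(key, unique(key))
  Vu <- tri[!duplicated(key), , drop = FALSE]
  surfaceMesh(Vu, matrix(uid, ncol = 3, byrow = TRUE))
}

# ---------------------------------------------------------------------------
# PLY (ASCII)
# ---------------------------------------------------------------------------

writePLY <- function(mesh, path, quality = NULL, colors = NULL) {
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  hasLab <- length(mesh@faceLabels) > 0
  hdr <- c("ply", "format ascii 1.0", "comment ramus3d")
  if (hasLab) hdr <- c(hdr, paste("comment region_levels",
                                  paste(sort(unique(mesh@faceLabels)), collapse = " ")))
  hdr <- c(hdr, sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (!is.null(quality)) hdr <- c(hdr, "property double quality")
  if (!is.null(colors)) hdr <- c(hdr, "property uchar red",
                                 "property uchar green", "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (hasLab) hdr <- c(hdr, "property int region")
  hdr <- c(hdr, "end_header")
  vtxt <- formatVertexRows(mesh@vertices, quality, colors)
  labInt <- if (hasLab) match(mesh@faceLabels, sort(unique(mesh@faceLabels))) - 1L
  ftxt <- paste(3, mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L, mesh@faces[, 3] - 1L)
  if (hasLab) ftxt <- paste(ftxt, labInt)
  writeLines(c(hdr, vtxt, ftxt), path)
}

formatVertexRows <- function(vmat, quality, colors) {
  txt <- sprintf("%.17g %.17g %.17g", vmat[, 1], vmat[, 2], vmat[, 3])
  if (!is.null(quality)) txt <- sprintf("%s %.17g", txt, quality)
  if (!is.null(colors))
    txt <- sprintf("%s %d %d %d", txt, colors[, 1], colors[, 2], colors[, 3])
  txt
}

readPLY <- function(path) {
  txt <- readLines(path)
  endh <- match("end_header", txt)
  if (is.na(endh)) stop("malformed PLY: missing end_header")
  hdr <- txt[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vprops <- character(0)
  inVert <- FALSE
  for (l in hdr) {
    if (startsWith(l, "element")) inVert <- startsWith(l, "element vertex")
    else if (inVert && startsWith(l, "property"))
      vprops <- c(vprops, sub(".* ", "", l))
  }
  vlines <- txt[(endh + 1):(endh + nv)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  flines <- strsplit(trimws(txt[(endh + nv + 1):(endh + nv + nf)]), "\\s+")
  fdat <- t(vapply(flines, function(x) as.numeric(x), numeric(length(flines[[1]]))))
  F <- matrix(as.integer(fdat[, 2:4]) + 1L, ncol = 3)
  labels <- character(0)
  if (ncol(fdat) >= 5) {
    lev <- grep("^comment region_levels", hdr, value = TRUE)
    if (length(lev)) {
      levels <- strsplit(sub("comment region_levels ", "", lev), " ")[[1]]
      labels <- levels[as.integer(fdat[, 5]) + 1L]
    }
  }
  m <- surfaceMesh(vdat[, c("x", "y", "z"), drop = FALSE], F, labels)
  if ("quality" %in% colnames(vdat))
    attr(m, "quality") <- as.numeric(vdat[, "quality"])
  m
}

# ---------------------------------------------------------------------------
# Landmarks (CSV) and transforms (JSON)
# ---------------------------------------------------------------------------

#' Read and write landmark sets (CSV)
#'
#' Columns: name, side, x_mm, y_mm, z_mm and optionally provenance. A missing
#' or non-numeric coordinate is a format error naming the offending field.
#' @param path CSV file path.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file does not exist: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "side", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed landmark CSV: missing column(s) ",
                         paste(miss, collapse = ", "))
  co <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(co))) {
    bad <- which(!is.finite(co), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed landmark CSV: missing/non-numeric %s for landmark '%s'",
                 c("x_mm", "y_mm", "z_mm")[bad[2]], df$name[bad[1]]))
  }
  new("LandmarkSet", name = df$name, side = df$side, coords = unname(co),
      provenance = df$provenance %||% rep("manual", nrow(df)))
}

#' @rdname readLandmarks
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @export
writeLandmarks <- function(landmarks, path) {
  df <- data.frame(name = landmarks@name, side = landmarks@side,
                   x_mm = landmarks@coords[, 1], y_mm = landmarks@coords[, 2],
                   z_mm = landmarks@coords[, 3],
                   provenance = landmarks@provenance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Transform JSON sidecar
#'
#' 4 x 4 row-major homogeneous matrix plus convergence metadata.
#' @param result a \linkS4class{RegistrationResult} (or
#'   \linkS4class{RigidTransform}).
#' @param path JSON path.
#' @export
writeTransform <- function(result, path) {
  tr <- if (is(result, "RegistrationResult")) result@transform else result
  obj <- list(matrix_rowmajor = as.numeric(t(transformMatrix(tr))))
  if (is(result, "RegistrationResult"))
    obj <- c(obj, list(converged = result@converged,
                       final_metric = result@finalMetric,
                       iterations = result@iterations, method = result@method))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transformFromMatrix(matrix(obj$matrix_rowmajor, 4, 4, byrow = TRUE))
}
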