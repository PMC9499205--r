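# Anatomical model: the cephalometric landmark set, the cutting planes
# derived from it, and the partition of the ramus into the condyle, the
# coronoid process and twenty subregions.

#' Look up a landmark by name (and side)
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param name landmark name, e.g. "C-point".
#' @param side "R" or "L"; may be omitted when the name is unique.
#' @export
getLandmark <- function(landmarks, name, side = NULL) {
  hit <- landmarks@name == name
  if (!is.null(side)) hit <- hit & landmarks@side == side
  i <- which(hit)
  if (length(i) == 0)
    stop("missing landmark: ", name, if (!is.null(side)) paste0(" (", side, ")"))
  as.numeric(landmarks@coords[i[1], ])
}

hasLandmark <- function(landmarks, name, side = NULL) {
  if (is.null(side)) name %in% landmarks@name
  else any(landmarks@name == name & landmarks@side == side)
}

requireLandmarks <- function(landmarks, names, side) {
  missing <- names[!vapply(names, function(n) hasLandmark(landmarks, n, side),
                           logical(1))]
  if (length(missing))
    stop("missing landmark(s) for side ", side, ": ",
         paste(missing, collapse = ", "))
}

# Frankfurt plane: least-squares fit through the four Or/Po points, normal
# oriented superior (the mandible, represented by C-point, lies below it)
buildFrankfurt <- function(landmarks) {
  side0 <- landmarks@side[landmarks@name == "C-point"][1]
  for (nm in c("Or", "Po"))
    if (sum(landmarks@name == nm) < 2)
      stop("missing landmark: bilateral ", nm, " required for the Frankfurt plane")
  P <- landmarks@coords[landmarks@name %in% c("Or", "Po"), , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  n <- sv$v[, 3]
  cp <- landmarks@coords[landmarks@name == "C-point", , drop = FALSE][1, ]
  if (sum((cp - ctr) * n) > 0) n <- -n # superior = away from the mandible
  plane3(ctr, n)
}

# in-plane anterior direction: from mean Po (posterior) to mean Or (anterior)
anteriorAxis <- function(landmarks, frankfurt) {
  orM <- colMeans(landmarks@coords[landmarks@name == "Or", , drop = FALSE])
  poM <- colMeans(landmarks@coords[landmarks@name == "Po", , drop = FALSE])
  v <- orM - poM
  unitv(v - sum(v * frankfurt@normal) * frankfurt@normal)
}

#' Intersection of a mesh with a plane
#'
#' Returns the points where mesh edges cross the plane (the polyline sampling
#' of the intersection curve).
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param plane a \linkS4class{Plane3}.
#' @export
meshPlaneIntersection <- function(mesh, plane) {
  d <- planeDistance(mesh@vertices, plane)
  eps <- 1e-9 * (max(abs(mesh@vertices)) + 1)
  onPlane <- abs(d) <= eps # vertices lying exactly on the plane
  F <- mesh@faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- e[e[, 1] < e[, 2], , drop = FALSE] # each undirected edge once
  da <- d[e[, 1]]; db <- d[e[, 2]]
  crossE <- (da > eps & db < -eps) | (da < -eps & db > eps)
  pts <- mesh@vertices[onPlane, , drop = FALSE]
  if (any(crossE)) {
    e <- e[crossE, , drop = FALSE]
    tt <- d[e[, 1]] / (d[e[, 1]] - d[e[, 2]])
    pts <- rbind(pts, mesh@vertices[e[, 1], , drop = FALSE] +
                   tt * (mesh@vertices[e[, 2], , drop = FALSE] -
                           mesh@vertices[e[, 1], , drop = FALSE]))
  }
  if (nrow(pts) == 0) stop("plane does not intersect the mesh")
  pts
}

#' Locate the derived ramal landmarks
#'
#' From the manual inputs (C-point, Go and the Frankfurt landmarks Or/Po),
#' computes the derived extremal landmarks in sequence: Con and Cor as the
#' most posterior / most anterior points of the mesh section by the C-plane;
#' RP as the most posterior point of the section by the ramus plane
#' (through Con, Cor, Go); and RI as the most inferior point of the section
#' by the first vertical intermediate plane (parallel to the posterior ramus
#' plane). All are returned with provenance "derived".
#'
#' @param mesh the ramus \linkS4class{SurfaceMesh}.
#' @param partialLandmarks \linkS4class{LandmarkSet} holding at least
#'   C-point, Go, Or (R/L) and Po (R/L).
#' @param side "R" or "L".
#' @param nApIntermediates number of intermediate vertical planes (the first
#'   locates RI).
#' @export
locateDerivedLandmarks <- function(mesh, partialLandmarks, side = c("R", "L"),
                                   nApIntermediates = 3) {
  side <- match.arg(side)
  requireLandmarks(partialLandmarks, c("C-point", "Go"), side)
  fr <- buildFrankfurt(partialLandmarks)
  ant <- anteriorAxis(partialLandmarks, fr)
  cp <- getLandmark(partialLandmarks, "C-point", side)
  cpl <- plane3(cp, fr@normal)
  sec <- meshPlaneIntersection(mesh, cpl)
  con <- sec[which.min(sec %*% ant), ]
  cor <- sec[which.max(sec %*% ant), ]
  go <- getLandmark(partialLandmarks, "Go", side)
  nr <- cross3(cor - con, go - con)
  if (vnorm(nr) < 1e-9) stop("degenerate ramus plane: Con, Cor, Go are collinear")
  rpl <- plane3(con, nr)
  sec2 <- meshPlaneIntersection(mesh, rpl)
  # "on the ramus": the ramal part below the C-plane (condyle and coronoid
  # protrude beyond it and are excluded)
  sec2 <- sec2[planeDistance(sec2, cpl) <= 0, , drop = FALSE]
  if (nrow(sec2) == 0) stop("ramus plane does not intersect the ramal part")
  rp <- sec2[which.min(sec2 %*% ant), ]
  # posterior ramus plane and the first vertical intermediate
  np <- unitv(cross3(unitv(nr), con - rp))
  if (sum(np * ant) < 0) np <- -np
  D <- sum((cor - rp) * np)
  v1 <- plane3(rp + np * (D / (nApIntermediates + 1)), np)
  sec3 <- meshPlaneIntersection(mesh, v1)
  sec3 <- sec3[planeDistance(sec3, cpl) <= 0, , drop = FALSE]
  if (nrow(sec3) == 0) stop("first vertical plane does not intersect the ramal part")
  ri <- sec3[which.max(sec3 %*% (-fr@normal)), ]
  keep <- !(partialLandmarks@name %in% c("Con", "Cor", "RP", "RI") &
              partialLandmarks@side == side)
  new("LandmarkSet",
      name = c(partialLandmarks@name[keep], "Con", "Cor", "RP", "RI"),
      side = c(partialLandmarks@side[keep], rep(side, 4)),
      coords = rbind(partialLandmarks@coords[keep, , drop = FALSE],
                     con, cor, rp, ri),
      provenance = c(partialLandmarks@provenance[keep], rep("derived", 4)))
}

#' Build the anatomical cutting-plane set
#'
#' Constructs, for one side: the Frankfurt plane (least-squares through the
#' four Or/Po points); the C-plane through C-point parallel to Frankfurt; the
#' ramus plane through Con, Cor and Go; the posterior ramus plane through RP
#' and Con perpendicular to the ramus plane; the anterior ramus plane through
#' Cor parallel to it; the inferior ramus plane through RI parallel to the
#' C-plane; and the equally spaced intermediate planes. The cutting planes
#' consume the five ramal landmarks Con, Cor, Go, RP and RI.
#'
#' With the default grid there are 3 vertical intermediates (4
#' anteroposterior bands) and 4 horizontal intermediates (5 craniocaudal
#' bands), giving the canonical 20 ramal subregions; \code{grid = "literal"}
#' instead uses 6 horizontal intermediates (7 bands, 28 cells, empty cells
#' dropped).
#'
#' @param landmarks complete per-side \linkS4class{LandmarkSet}.
#' @param side "R" or "L".
#' @param nApIntermediates intermediate vertical planes (default 3).
#' @param nCiIntermediates intermediate horizontal planes; default 4
#'   ("default" grid) or 6 ("literal").
#' @param grid "default" (4 x 5 = 20 cells) or "literal" (4 x 7).
#' @return A \linkS4class{PlaneSet}.
#' @export
buildPlanes <- function(landmarks, side = c("R", "L"), nApIntermediates = 3,
                        nCiIntermediates = NULL, grid = c("default", "literal")) {
  side <- match.arg(side)
  grid <- match.arg(grid)
  if (is.null(nCiIntermediates))
    nCiIntermediates <- if (grid == "literal") 6L else 4L
  requireLandmarks(landmarks, c("C-point", "Con", "Cor", "Go", "RP", "RI"), side)
  fr <- buildFrankfurt(landmarks)
  ant <- anteriorAxis(landmarks, fr)
  sup <- fr@normal
  cp <- getLandmark(landmarks, "C-point", side)
  con <- getLandmark(landmarks, "Con", side)
  cor <- getLandmark(landmarks, "Cor", side)
  go <- getLandmark(landmarks, "Go", side)
  rp <- getLandmark(landmarks, "RP", side)
  ri <- getLandmark(landmarks, "RI", side)
  cpl <- plane3(cp, sup)
  nr <- cross3(cor - con, go - con)
  if (vnorm(nr) < 1e-9) stop("degenerate ramus plane: Con, Cor, Go are collinear")
  rpl <- plane3(con, nr)
  np <- unitv(cross3(rpl@normal, con - rp))
  if (sum(np * ant) < 0) np <- -np
  post <- plane3(rp, np)
  antp <- plane3(cor, np)
  infp <- plane3(ri, sup)
  D <- sum((cor - rp) * np)
  if (D <= 0) stop("anterior ramus plane is not anterior to the posterior one")
  H <- -sum((ri - cp) * sup)
  if (H <= 0) stop("inferior ramus plane is not inferior to the C-plane")
  iAP <- lapply(seq_len(nApIntermediates), function(i)
    plane3(rp + np * (i * D / (nApIntermediates + 1)), np))
  iCI <- lapply(seq_len(nCiIntermediates), function(i)
    plane3(cp - sup * (i * H / (nCiIntermediates + 1)), sup))
  ps <- new("PlaneSet", frankfurt = fr, cPlane = cpl, ramusPlane = rpl,
            posteriorRamus = post, anteriorRamus = antp, inferiorRamus = infp,
            intermediatesAP = iAP, intermediatesCI = iCI, side = side,
            anterior = ant, superior = sup,
            nApBands = as.integer(nApIntermediates + 1),
            nCiBands = as.integer(nCiIntermediates + 1))
  # record which ramal landmarks the construction consumed
  attr(ps, "ramalLandmarks") <- c("Con", "Cor", "Go", "RP", "RI")
  ps
}

#' Partition the ramus into condyle, coronoid process and subregions
#'
#' Faces above the C-plane must form exactly two connected components: the
#' posterior one is the condyle, the anterior one the coronoid process.
#' Faces below are assigned to the anteroposterior x craniocaudal grid cell
#' containing their centroid (outermost bands are open outward, so every
#' face receives a label). Under the default grid the twenty subregions must
#' all be nonempty.
#'
#' @param mesh a watertight ramus \linkS4class{SurfaceMesh}.
#' @param planes a \linkS4class{PlaneSet}.
#' @return A \linkS4class{RegionLabeling}.
#' @export
partitionRamus <- function(mesh, planes) {
  fc <- faceCentroids(mesh)
  sdC <- planeDistance(fc, planes@cPlane)
  above <- which(sdC > 0)
  if (length(above) < 2) stop("no faces above the C-plane; not a ramus?")
  split <- condyleCoronoidSplit(mesh, fc, above, planes@anterior, sdC = sdC)
  labels <- character(nrow(fc))
  labels[split$condyle] <- "condyle"
  labels[split$coronoid] <- "coronoid"
  below <- c(which(sdC <= 0), split$extras)
  nAp <- planes@nApBands; nCi <- planes@nCiBands
  u <- planeDistance(fc[below, , drop = FALSE], planes@posteriorRamus)
  D <- sum((planes@anteriorRamus@point - planes@posteriorRamus@point) *
             planes@posteriorRamus@normal)
  apBand <- pmin(pmax(floor(u / D * nAp) + 1, 1), nAp)
  v <- -sdC[below]
  H <- -sum((planes@inferiorRamus@point - planes@cPlane@point) *
              planes@cPlane@normal)
  ciBand <- pmin(pmax(floor(v / H * nCi) + 1, 1), nCi)
  labels[below] <- sprintf("R%02d", (ciBand - 1) * nAp + apBand)
  expected <- sprintf("R%02d", seq_len(nAp * nCi))
  present <- intersect(expected, labels)
  if (nAp * nCi == 20L && length(present) < 20L)
    stop("partition-configuration error: empty subregion cell(s) ",
         paste(setdiff(expected, present), collapse = ", "))
  sep <- plane3(planes@cPlane@point, planes@anterior)
  new("RegionLabeling", labels = labels,
      levels = c("condyle", "coronoid", present),
      separator = sep, planes = planes)
}

# Split the faces above the C-plane into condyle (posterior) and coronoid
# (anterior). The two processes meet the plane exactly at the notch saddle,
# so a hair's-width sliver can connect them (or tiny islands can graze the
# plane): components are found on a core band a little above the plane,
# where the separation is unambiguous, and grown back down to the plane
# through face adjacency. A genuine failure to find two processes is an
# anatomy error.
condyleCoronoidSplit <- function(mesh, fc, above, anterior, cPlane = NULL,
                                 sdC = NULL) {
  areasAll <- faceAreas(mesh)
  if (is.null(sdC)) sdC <- planeDistance(fc, cPlane)
  delta <- max(0.75, 2 * sqrt(stats::median(areasAll)))
  core <- above[sdC[above] > delta]
  if (length(core) < 2)
    stop("expected exactly 2 components above the C-plane (condyle, coronoid), got 0")
  comp <- faceComponents(mesh, core)
  compArea <- vapply(seq_len(max(comp)), function(k)
    sum(areasAll[core[comp == k]]), numeric(1))
  big <- which(compArea >= 0.01 * sum(compArea))
  if (length(big) != 2)
    stop("expected exactly 2 components above the C-plane (condyle, coronoid), got ",
         length(big))
  apPos <- vapply(big, function(k)
    mean(fc[core[comp == k], , drop = FALSE] %*% anterior), numeric(1))
  lab <- integer(nrow(mesh@faces)) # 0 unassigned, 1 condyle, 2 coronoid
  lab[core[comp == big[which.min(apPos)]]] <- 1L
  lab[core[comp == big[which.max(apPos)]]] <- 2L
  # grow the two labels down through the band between the plane and the core
  band <- setdiff(above, core)
  if (length(band)) {
    adj <- faceAdjacencyPairs(mesh, above)
    repeat {
      grow <- which(lab[adj[, 1]] == 0L & lab[adj[, 2]] != 0L)
      if (!length(grow)) break
      lab[adj[grow, 1]] <- lab[adj[grow, 2]]
      grow2 <- which(lab[adj[, 2]] == 0L & lab[adj[, 1]] != 0L)
      lab[adj[grow2, 2]] <- lab[adj[grow2, 1]]
      if (!length(grow) && !length(grow2)) break
    }
  }
  list(condyle = above[lab[above] == 1L],
       coronoid = above[lab[above] == 2L],
       extras = above[lab[above] == 0L])
}

# unordered adjacent face pairs (shared edge) within a face subset
faceAdjacencyPairs <- function(mesh, faceSubset) {
  F <- mesh@faces[faceSubset, , drop = FALSE]
  nv <- nrow(mesh@vertices)
  ek <- meshEdgeKeys(F)
  key <- ek$lo + ek$hi * (nv + 1)
  fid <- rep(faceSubset, 3)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  same <- which(key[-1] == key[-length(key)])
  cbind(fid[same], fid[same + 1])
}

#' @rdname partitionRamus
#' @param labeling a \linkS4class{RegionLabeling}.
#' @param label a region label.
#' @export
regionFaces <- function(labeling, label) which(labeling@labels == label)

#' @rdname partitionRamus
#' @export
regionLevels <- function(labeling) labeling@levels

# half-space list bounding one region's solid (outermost bands open outward)
regionHalfspaces <- function(labeling, label) {
  pl <- labeling@planes
  cpt <- pl@cPlane@point; sup <- pl@cPlane@normal
  if (label == "condyle")
    return(list(plane3(cpt, sup),
                plane3(labeling@separator@point, -labeling@separator@normal)))
  if (label == "coronoid")
    return(list(plane3(cpt, sup), labeling@separator))
  i <- as.integer(sub("^R", "", label))
  nAp <- pl@nApBands
  apBand <- (i - 1L) %% nAp + 1L
  ciBand <- (i - 1L) %/% nAp + 1L
  hs <- list(plane3(cpt, -sup)) # below the C-plane
  np <- pl@posteriorRamus@normal
  if (apBand > 1L) {
    b <- pl@intermediatesAP[[apBand - 1L]]
    hs <- c(hs, list(plane3(b@point, np)))
  }
  if (apBand < nAp) {
    b <- pl@intermediatesAP[[apBand]]
    hs <- c(hs, list(plane3(b@point, -np)))
  }
  if (ciBand > 1L) {
    b <- pl@intermediatesCI[[ciBand - 1L]]
    hs <- c(hs, list(plane3(b@point, -sup)))
  }
  if (ciBand < pl@nCiBands) {
    b <- pl@intermediatesCI[[ciBand]]
    hs <- c(hs, list(plane3(b@point, sup)))
  }
  hs
}

#' Write a region table (JSON)
#'
#' Exports the labelling as a JSON table mapping each region label to its
#' face indices and exact capped volume (mm^3).
#'
#' @param labeling a \linkS4class{RegionLabeling}.
#' @param mesh the labelled watertight \linkS4class{SurfaceMesh}.
#' @param path output .json path.
#' @export
writeRegionTable <- function(labeling, mesh, path) {
  vols <- regionVolumes(mesh, labeling)
  tab <- lapply(labeling@levels, function(lb)
    list(faces = regionFaces(labeling, lb), volume_mm3 = vols[[lb]]))
  names(tab) <- labeling@levels
  jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
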