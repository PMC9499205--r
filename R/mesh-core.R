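# Core triangle-mesh operations: measures, topology, smoothing, decimation,
# plane clipping with exact capped volumes.

#' Construct a surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param faceLabels optional character vector of per-face region labels.
#' @export
surfaceMesh <- function(vertices, faces, faceLabels = character(0)) {
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices), faces = faces,
      faceLabels = faceLabels)
}

#' @rdname surfaceMesh
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
vertices <- function(mesh) mesh@vertices

#' @rdname surfaceMesh
#' @export
faces <- function(mesh) mesh@faces

#' @rdname surfaceMesh
#' @export
faceLabels <- function(mesh) mesh@faceLabels

faceCorners <- function(mesh) {
  F <- mesh@faces
  list(a = mesh@vertices[F[, 1], , drop = FALSE],
       b = mesh@vertices[F[, 2], , drop = FALSE],
       c = mesh@vertices[F[, 3], , drop = FALSE])
}

#' Per-face unnormalised normals, areas, centroids and vertex normals
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
faceNormals <- function(mesh) {
  co <- faceCorners(mesh)
  n <- rowCross(co$b - co$a, co$c - co$a)
  n / pmax(rowNorms(n), 1e-300)
}

#' @rdname faceNormals
#' @export
faceAreas <- function(mesh) {
  co <- faceCorners(mesh)
  rowNorms(rowCross(co$b - co$a, co$c - co$a)) / 2
}

#' @rdname faceNormals
#' @export
faceCentroids <- function(mesh) {
  co <- faceCorners(mesh)
  (co$a + co$b + co$c) / 3
}

#' @rdname faceNormals
#' @export
vertexNormals <- function(mesh) {
  co <- faceCorners(mesh)
  fn <- rowCross(co$b - co$a, co$c - co$a) # area-weighted
  idx <- as.vector(mesh@faces)
  acc <- rowsum(fn[rep(seq_len(nrow(fn)), 3), , drop = FALSE], idx)
  out <- matrix(0, nrow(mesh@vertices), 3)
  out[as.integer(rownames(acc)), ] <- acc
  out / pmax(rowNorms(out), 1e-300)
}

#' Enclosed volume and total area of a mesh
#'
#' Volume by the divergence theorem (signed-tetrahedron sum); positive for a
#' closed, outward-oriented surface.
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
meshVolume <- function(mesh) {
  co <- faceCorners(mesh)
  sum(rowSums(co$a * rowCross(co$b, co$c))) / 6
}

#' @rdname meshVolume
#' @export
meshArea <- function(mesh) sum(faceAreas(mesh))

meshEdgeKeys <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  list(lo = pmin(e[, 1], e[, 2]), hi = pmax(e[, 1], e[, 2]), raw = e)
}

#' Is the mesh watertight?
#'
#' Closed and 2-manifold with consistent orientation: every undirected edge
#' is used by exactly two faces, once in each direction.
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
isWatertight <- function(mesh) {
  if (nrow(mesh@faces) == 0) return(FALSE)
  ek <- meshEdgeKeys(mesh@faces)
  nv <- nrow(mesh@vertices)
  und <- ek$lo + ek$hi * (nv + 1)
  dir <- ek$raw[, 1] + ek$raw[, 2] * (nv + 1)
  tu <- table(und)
  if (any(tu != 2L)) return(FALSE)
  !any(duplicated(dir)) # each direction exactly once => consistent orientation
}

# face adjacency components over a subset of faces (shared-edge connectivity)
faceComponents <- function(mesh, faceSubset = seq_len(nrow(mesh@faces))) {
  F <- mesh@faces[faceSubset, , drop = FALSE]
  m <- nrow(F)
  if (m == 0) return(integer(0))
  ek <- meshEdgeKeys(F)
  nv <- nrow(mesh@vertices)
  key <- ek$lo + ek$hi * (nv + 1)
  fid <- rep(seq_len(m), 3)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  same <- which(key[-1] == key[-length(key)])
  # union-find
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (s in same) {
    ra <- find(fid[s]); rb <- find(fid[s + 1])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Extract a submesh from a face subset
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param faceIdx integer vector of face indices to keep.
#' @export
submesh <- function(mesh, faceIdx) {
  F <- mesh@faces[faceIdx, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  surfaceMesh(mesh@vertices[used, , drop = FALSE],
              matrix(remap[F], ncol = 3),
              if (length(mesh@faceLabels)) mesh@faceLabels[faceIdx] else character(0))
}

#' Mirror a mesh across the plane y = 0
#'
#' Face winding is flipped so orientation stays consistent.
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
mirrorMesh <- function(mesh) {
  V <- mesh@vertices
  V[, 2] <- -V[, 2]
  surfaceMesh(V, mesh@faces[, c(1, 3, 2), drop = FALSE], mesh@faceLabels)
}

# ---------------------------------------------------------------------------
# Smoothing
# ---------------------------------------------------------------------------

#' Volume-bias-compensated Laplacian smoothing (Taubin lambda/mu)
#'
#' Each iteration applies one inflation-compensated pair: a Laplacian step of
#' weight \code{factor} followed by one of weight \code{-1.03 * factor}, which
#' damps surface noise while keeping shrinkage of the enclosed volume small.
#' \code{iterations = 0} or \code{factor = 0} returns the input unchanged.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param iterations number of lambda/mu smoothing passes.
#' @param factor smoothing factor in (0, 1).
#' @export
smoothMesh <- function(mesh, iterations = 10, factor = 0.2) {
  if (iterations == 0 || factor == 0) return(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  # undirected unique edges, both directions for averaging
  und <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  und <- und[!duplicated(und[, 1] + und[, 2] * (nrow(V) + 1)), , drop = FALSE]
  src <- c(und[, 1], und[, 2]); dst <- c(und[, 2], und[, 1])
  deg <- tabulate(dst, nbins = nrow(V))
  lapStep <- function(V, w) {
    s <- rowsum(V[src, , drop = FALSE], dst, reorder = FALSE)
    out <- matrix(0, nrow(V), 3)
    out[as.integer(rownames(s)), ] <- s
    V + w * (out / pmax(deg, 1) - V)
  }
  for (i in seq_len(iterations)) {
    V <- lapStep(V, factor)
    V <- lapStep(V, -1.03 * factor)
  }
  surfaceMesh(V, F, mesh@faceLabels)
}

# ---------------------------------------------------------------------------
# Decimation (edge collapse with deviation bound)
# ---------------------------------------------------------------------------

#' Decimate a mesh by bounded edge collapse
#'
#' Collapses short edges whose removal keeps the removed vertex within
#' \code{tolerance} of the decimated surface and preserves the closed
#' 2-manifold structure (link condition, no face flips beyond
#' \code{edgeAngle}). Kept vertices are a subset of the input vertices, so
#' the decimated surface never departs from the original one by more than
#' \code{tolerance} at its vertices.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param tolerance maximum allowed deviation introduced per collapse, mm.
#' @param edgeAngle maximum allowed rotation of an incident face normal,
#'   degrees.
#' @param iterations number of passes over the candidate edges.
#' @export
decimateMesh <- function(mesh, tolerance = 0.0375, edgeAngle = 10, iterations = 3) {
  V <- mesh@vertices
  F <- mesh@faces
  cosTol <- cos(edgeAngle * pi / 180)
  alive <- rep(TRUE, nrow(F))
  # vertex -> incident faces
  vf <- vector("list", nrow(V))
  for (c0 in 1:3) {
    sp <- split(seq_len(nrow(F)), F[, c0])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      vf[[i]] <- c(vf[[i]], sp[[nm]])
    }
  }
  # removed original vertices tracked per surviving face so the cumulative
  # (not just per-collapse) deviation stays bounded by the tolerance: every
  # face modification re-checks and re-assigns the vertices it carried
  fbag <- vector("list", nrow(F))
  removed <- rep(FALSE, nrow(V))
  triNormal <- function(f) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c <- V[F[f, 3], ]
    n <- cross3(b - a, c - a)
    l <- vnorm(n)
    if (l < 1e-300) return(c(0, 0, 0))
    n / l
  }
  localQuery <- function(ptIdx, faceIdx, Fmat) {
    faces <- Fmat[faceIdx, , drop = FALSE]
    used <- unique(as.vector(faces))
    remap <- integer(nrow(V)); remap[used] <- seq_along(used)
    r <- cpp_closest_point(V[ptIdx, , drop = FALSE],
                           V[used, , drop = FALSE],
                           matrix(remap[faces], ncol = 3))
    list(dist = r$distance, face = faceIdx[r$face])
  }
  for (pass in seq_len(iterations)) {
    Fa <- F[alive, , drop = FALSE]
    e <- rbind(Fa[, c(1, 2)], Fa[, c(2, 3)], Fa[, c(3, 1)])
    und <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    und <- und[!duplicated(und[, 1] + und[, 2] * (nrow(V) + 1)), , drop = FALSE]
    len <- rowNorms(V[und[, 1], , drop = FALSE] - V[und[, 2], , drop = FALSE])
    cand <- und[order(len), , drop = FALSE]
    collapsed <- 0L
    for (q in seq_len(nrow(cand))) {
      u <- cand[q, 1]; v <- cand[q, 2]
      if (removed[u] || removed[v]) next
      fu <- vf[[u]][alive[vf[[u]]]]; fv <- vf[[v]][alive[vf[[v]]]]
      shared <- intersect(fu, fv)
      if (length(shared) != 2) next # non-manifold or boundary: skip
      # link condition: vertex links intersect exactly in the 2 opposite verts
      ringU <- setdiff(unique(as.vector(F[fu, , drop = FALSE])), c(u, v))
      ringV <- setdiff(unique(as.vector(F[fv, , drop = FALSE])), c(u, v))
      opp <- setdiff(unique(as.vector(F[shared, , drop = FALSE])), c(u, v))
      if (!setequal(intersect(ringU, ringV), opp)) next
      # candidate new faces: v's faces with v -> u, minus the shared two
      newf <- setdiff(fv, shared)
      ok <- TRUE
      oldn <- lapply(newf, triNormal)
      Fnew <- F
      for (f in newf) Fnew[f, ][Fnew[f, ] == v] <- u
      for (i in seq_along(newf)) {
        f <- newf[i]
        a <- V[Fnew[f, 1], ]; b <- V[Fnew[f, 2], ]; c <- V[Fnew[f, 3], ]
        n <- cross3(b - a, c - a); l <- vnorm(n)
        if (l < 1e-12) { ok <- FALSE; break }
        if (sum((n / l) * oldn[[i]]) < cosTol) { ok <- FALSE; break }
      }
      if (!ok) next
      # cumulative deviation bound: the collapsing vertex AND every removed
      # vertex carried by a face that this collapse deletes or modifies must
      # remain within tolerance of the updated local surface
      tracked <- unique(c(v, unlist(fbag[c(shared, newf)])))
      localFaces <- unique(c(setdiff(fu, shared), newf))
      lq <- localQuery(tracked, localFaces, Fnew)
      if (!all(is.finite(lq$dist)) || max(lq$dist) > tolerance) next
      # commit and re-assign the tracked vertices to their new nearest faces
      F <- Fnew
      alive[shared] <- FALSE
      removed[v] <- TRUE
      for (f in c(shared, newf)) fbag[[f]] <- integer(0)
      for (i in seq_along(tracked))
        fbag[[lq$face[i]]] <- c(fbag[[lq$face[i]]], tracked[i])
      vf[[u]] <- unique(c(vf[[u]], newf))
      collapsed <- collapsed + 1L
    }
    if (collapsed == 0L) break
  }
  keepF <- F[alive, , drop = FALSE]
  m2 <- surfaceMesh(V, keepF,
                    if (length(mesh@faceLabels)) mesh@faceLabels[alive] else character(0))
  dropUnusedVertices(m2)
}

dropUnusedVertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh@faces)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  surfaceMesh(mesh@vertices[used, , drop = FALSE],
              matrix(remap[mesh@faces], ncol = 3), mesh@faceLabels)
}

# ---------------------------------------------------------------------------
# Planes and clipped volumes
# ---------------------------------------------------------------------------

#' Construct an oriented plane
#' @param point numeric(3) point on the plane (mm).
#' @param normal numeric(3) normal (normalised internally).
#' @export
plane3 <- function(point, normal) {
  new("Plane3", point = as.numeric(point), normal = unitv(as.numeric(normal)))
}

#' Signed distance from points to a plane
#' @param points n x 3 matrix or numeric(3).
#' @param plane a \linkS4class{Plane3}.
#' @export
planeDistance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  as.numeric((points - matrix(plane@point, nrow(points), 3, byrow = TRUE)) %*%
               plane@normal)
}

#' Clip a watertight mesh by a half-space, capping the cut
#'
#' Keeps the part of the solid on the non-negative side of the plane. Faces
#' are split at the plane, the cut boundary is chained into closed loops and
#' each loop is triangulated (ear clipping) into cap faces with outward
#' orientation, so the result is again a closed solid. Successive calls
#' implement clipping by a convex cell.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param plane a \linkS4class{Plane3} (keep side: signed distance >= 0).
#' @return a closed \linkS4class{SurfaceMesh} (possibly empty).
#' @export
clipMeshClosed <- function(mesh, plane) {
  V <- mesh@vertices
  F <- mesh@faces
  eps <- 1e-9 * (max(abs(V)) + 1)
  d <- planeDistance(V, plane)
  s <- ifelse(d > eps, 1L, ifelse(d < -eps, -1L, 0L))
  if (!any(s[F] < 0)) return(mesh)
  if (!any(s[F] > 0))
    return(surfaceMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  fs <- matrix(s[F], ncol = 3)
  keepAll <- rowSums(fs >= 0) == 3L & rowSums(fs > 0) > 0L
  dropAll <- rowSums(fs <= 0) == 3L
  mixed <- which(!keepAll & !dropAll)
  # shared crossing vertices, one per cut edge
  newV <- list(); edgeId <- new.env(hash = TRUE)
  nv0 <- nrow(V)
  crossingVertex <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- edgeId[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    newV[[length(newV) + 1L]] <<- V[i, ] + t * (V[j, ] - V[i, ])
    id <- nv0 + length(newV)
    edgeId[[key]] <- id
    id
  }
  outFaces <- list()
  boundary <- list() # oriented edges (from, to) on the cut plane
  for (f in mixed) {
    vs <- F[f, ]
    poly <- integer(0)
    onPlane <- logical(0)
    for (q in 1:3) {
      i <- vs[q]; j <- vs[if (q == 3) 1 else q + 1]
      if (s[i] >= 0) { poly <- c(poly, i); onPlane <- c(onPlane, s[i] == 0L) }
      if (s[i] * s[j] < 0) {
        poly <- c(poly, crossingVertex(i, j))
        onPlane <- c(onPlane, TRUE)
      }
    }
    np <- length(poly)
    if (np < 3) next
    for (q in 2:(np - 1)) # fan
      outFaces[[length(outFaces) + 1L]] <- poly[c(1, q, q + 1)]
    for (q in seq_len(np)) {
      r <- if (q == np) 1L else q + 1L
      if (onPlane[q] && onPlane[r])
        boundary[[length(boundary) + 1L]] <- c(poly[q], poly[r])
    }
  }
  # wholesale-kept faces can contribute boundary edges where both endpoints
  # lie exactly on the plane; interior duplicates (used in both directions)
  # cancel below
  kf <- which(keepAll)
  kfs <- fs[kf, , drop = FALSE]
  cand <- kf[rowSums(kfs == 0L) >= 2L]
  for (f in cand) {
    vs <- F[f, ]
    for (q in 1:3) {
      i <- vs[q]; j <- vs[if (q == 3) 1 else q + 1]
      if (s[i] == 0L && s[j] == 0L)
        boundary[[length(boundary) + 1L]] <- c(i, j)
    }
  }
  Vall <- rbind(V, if (length(newV)) do.call(rbind, newV))
  Fkeep <- F[kf, , drop = FALSE]
  Fnew <- if (length(outFaces)) do.call(rbind, outFaces) else matrix(0L, 0, 3)
  capF <- matrix(0L, 0, 3)
  if (length(boundary)) {
    B <- do.call(rbind, boundary)
    # cancel oppositely-directed duplicates (interior plane-lying edges)
    fwd <- paste0(B[, 1], "_", B[, 2])
    rev_ <- paste0(B[, 2], "_", B[, 1])
    B <- B[!(fwd %in% rev_), , drop = FALSE]
    B <- B[!duplicated(paste0(B[, 1], "_", B[, 2])), , drop = FALSE]
    if (nrow(B) >= 3) {
      caps <- triangulateLoops(B, Vall)
      if (length(caps$faces)) {
        capF <- caps$faces
        if (length(caps$extra)) Vall <- rbind(Vall, do.call(rbind, caps$extra))
      }
    }
  }
  Fall <- rbind(Fkeep, Fnew, capF)
  storage.mode(Fall) <- "integer"
  # drop degenerate faces
  ok <- Fall[, 1] != Fall[, 2] & Fall[, 2] != Fall[, 3] & Fall[, 1] != Fall[, 3]
  dropUnusedVertices(surfaceMesh(Vall, Fall[ok, , drop = FALSE]))
}

# Chain oriented boundary edges into closed loops and cap each with a
# centroid fan. The fan uses the loop's own orientation reversed, so the cap
# faces outward (away from the kept half-space) and every boundary edge is
# used exactly once: the capped solid is combinatorially closed and its
# signed-tetrahedron volume is exact even for non-convex section loops
# (overlapping fan triangles cancel in signed area).
triangulateLoops <- function(B, V) {
  nxt <- integer(0)
  nxt[as.character(B[, 1])] <- B[, 2]
  used <- logical(max(B) + 1L)
  faces <- list(); extra <- list()
  nv <- nrow(V)
  for (q in seq_len(nrow(B))) {
    start <- B[q, 1]
    if (used[start]) next
    loop <- integer(0)
    cur <- start
    ok <- TRUE
    repeat {
      loop <- c(loop, cur)
      used[cur] <- TRUE
      nx <- nxt[as.character(cur)]
      if (is.na(nx)) { ok <- FALSE; break } # open chain: skip defensively
      cur <- nx
      if (cur == start) break
      if (length(loop) > nrow(B)) { ok <- FALSE; break }
    }
    if (!ok || length(loop) < 3) next
    ctr <- colMeans(V[loop, , drop = FALSE])
    nv <- nv + 1L
    extra[[length(extra) + 1L]] <- ctr
    m <- length(loop)
    # reversed orientation: cap normal points out of the kept solid
    faces[[length(faces) + 1L]] <-
      cbind(rep(nv, m), loop[c(seq_len(m)[-1], 1L)], loop)
  }
  list(faces = if (length(faces)) do.call(rbind, faces) else matrix(0L, 0, 3),
       extra = extra)
}

#' Volume of a watertight mesh clipped by half-spaces
#'
#' Clips the solid by each plane in turn (\code{\link{clipMeshClosed}}), so
#' cut sections are capped and closed at every step, then evaluates the
#' signed-tetrahedron volume of the resulting solid.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param planes list of \linkS4class{Plane3} half-spaces (keep side:
#'   signed distance >= 0).
#' @return volume in mm^3.
#' @export
clippedVolume <- function(mesh, planes) {
  if (length(planes) == 0) return(meshVolume(mesh))
  out <- mesh
  for (pl in planes) {
    out <- clipMeshClosed(out, pl)
    if (nrow(out@faces) == 0) return(0)
  }
  meshVolume(out)
}

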