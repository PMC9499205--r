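# Shared fixtures (built in code) and independent brute-force oracles.

# unit cube mesh (12 triangles, outward-oriented, watertight)
makeCube <- function(scale = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * scale
  v <- sweep(v, 2, origin, "+")
  f <- matrix(c(1,3,2, 2,3,4, 5,6,7, 6,8,7, 1,2,5, 2,6,5,
                3,7,4, 4,7,8, 1,5,3, 3,5,7, 2,4,6, 4,8,6),
              ncol = 3, byrow = TRUE)
  surfaceMesh(v, f)
}

# watertight sphere mesh from the signed-distance field
makeSphereMesh <- function(r = 10, spacing = 0.5, pad = 1.5) {
  g <- seq(-r - pad, r + pad, by = spacing)
  n <- length(g)
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n))
    arr[, , k] <- outer(g, g, function(x, y) r - sqrt(x^2 + y^2 + g[k]^2))
  iso <- ramus3d:::cpp_march_tets(as.numeric(arr), c(n, n, n), 0)
  surfaceMesh(sweep(iso$vertices * spacing, 2, g[1], "+"), iso$faces)
}

# small shared ramus case (no volume), cached across tests
.fixtureEnv <- new.env()
sharedCase <- function(seed = 7, side = "R") {
  key <- paste0("case", seed, side)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateRamus(side = side, seed = seed,
                                        makeVolume = FALSE)
  .fixtureEnv[[key]]
}

sharedCaseWithVolume <- function(seed = 3, spacing = 0.6) {
  key <- paste0("vcase", seed, spacing)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateRamus(seed = seed, volumeSpacing = spacing)
  .fixtureEnv[[key]]
}

# ---------------------------------------------------------------------------
# independent oracles (plain R, no package internals)
# ---------------------------------------------------------------------------

# exact point-to-triangle distance by projection onto the plane and the
# three edges (independent of the C++ implementation)
brutePointTriDist <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  cand <- c()
  if (nn > 1e-300) {
    n <- n / nn
    q <- p - sum((p - a) * n) * n
    # barycentric test for the projection
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) cand <- c(cand, sqrt(sum((p - q)^2)))
  }
  segDist <- function(p, s, e) {
    d <- e - s
    t <- max(0, min(1, sum((p - s) * d) / sum(d * d)))
    sqrt(sum((p - s - t * d)^2))
  }
  min(c(cand, segDist(p, a, b), segDist(p, b, c), segDist(p, c, a)))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# minimum distance from each point to any triangle of a mesh, by full loop
bruteClosestDistances <- function(pts, mesh) {
  V <- vertices(mesh); F <- faces(mesh)
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(F)), function(t)
      brutePointTriDist(p, V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ]),
      numeric(1)))
  }, numeric(1))
}

# signed-tetrahedron volume, independent accumulation order
bruteMeshVolume <- function(mesh) {
  V <- vertices(mesh); F <- faces(mesh)
  tot <- 0
  for (t in seq_len(nrow(F))) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; c <- V[F[t, 3], ]
    tot <- tot + (a[1] * (b[2] * c[3] - b[3] * c[2]) -
                    a[2] * (b[1] * c[3] - b[3] * c[1]) +
                    a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
  }
  tot
}

# 3D flood fill by breadth-first search (independent of the C++ version)
bruteFloodFill <- function(mask, seedIdx, connectivity = 26) {
  d <- dim(mask)
  out <- array(FALSE, d)
  if (!mask[seedIdx[1], seedIdx[2], seedIdx[3]]) return(out)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  queue <- matrix(seedIdx, 1, 3)
  out[seedIdx[1], seedIdx[2], seedIdx[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (q in seq_len(nrow(nb))) {
      p <- cur + nb[q, ]
      if (any(p < 1) || any(p > d)) next
      if (mask[p[1], p[2], p[3]] && !out[p[1], p[2], p[3]]) {
        out[p[1], p[2], p[3]] <- TRUE
        queue <- rbind(queue, p)
      }
    }
  }
  out
}

# ICC(1,1) through R's ANOVA machinery (independent of the package formula)
oracleIcc <- function(x, y) {
  df <- data.frame(subject = factor(rep(seq_along(x), 2)), value = c(x, y))
  av <- anova(lm(value ~ subject, data = df))
  msb <- av["subject", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# notch-arc C-point by exhaustive double loop over vertices
oracleCPoint <- function(mesh, window, halfWidth = 0.5) {
  V <- vertices(mesh)
  x <- V[, 1]; z <- V[, 3]
  near <- which(x >= window[1] - halfWidth & x <= window[2] + halfWidth)
  cand <- which(x >= window[1] & x <= window[2])
  onArc <- vapply(cand, function(v)
    !any(abs(x[near] - x[v]) <= halfWidth & z[near] > z[v]), logical(1))
  arc <- cand[onArc]
  as.numeric(V[arc[which.min(z[arc])], ])
}
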