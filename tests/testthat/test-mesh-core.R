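test_that("mesh measures match analytic values on the unit cube", {
  cube <- makeCube()
  expect_true(isWatertight(cube))
  expect_equal(meshVolume(cube), 1)
  expect_equal(meshArea(cube), 6)
  expect_equal(meshVolume(mirrorMesh(cube)), 1) # winding flip keeps volume +
  expect_true(isWatertight(mirrorMesh(cube)))
})

test_that("clipped capped volumes are exact on the cube", {
  cube <- makeCube()
  mid <- plane3(c(0.5, 0.5, 0.5), c(0, 0, 1))
  expect_equal(clippedVolume(cube, list(mid)), 0.5)
  expect_equal(clippedVolume(cube, list(plane3(c(0.5, 0.5, 0.5), c(0, 0, -1)))),
               0.5)
  slab <- list(plane3(c(0, 0, 0.25), c(0, 0, 1)),
               plane3(c(0, 0, 0.75), c(0, 0, -1)))
  expect_equal(clippedVolume(cube, slab), 0.5)
  # oblique cut: half-space through the centre with a skew normal still
  # bisects the cube by symmetry
  obl <- plane3(c(0.5, 0.5, 0.5), ramus3d:::unitv(c(1, 1, 1)))
  expect_equal(clippedVolume(cube, list(obl)), 0.5, tolerance = 1e-12)
  # degenerate: cutting plane coincides with a cube facet
  expect_equal(clippedVolume(cube, list(plane3(c(0, 0, 0), c(0, 0, 1)))), 1)
  expect_equal(clippedVolume(cube, list(plane3(c(0, 0, 0), c(0, 0, -1)))), 0)
})

test_that("parallel plane cells of a sphere match closed-form spherical caps", {
  r <- 10
  sphere <- makeSphereMesh(r, spacing = 0.25)
  capV <- function(h) pi * h^2 * (3 * r - h) / 3
  analytic <- c(capV(5), capV(10) - capV(5), capV(15) - capV(10),
                capV(20) - capV(15))
  zcuts <- c(-5, 0, 5)
  got <- c(clippedVolume(sphere, list(plane3(c(0, 0, -5), c(0, 0, -1)))),
           clippedVolume(sphere, list(plane3(c(0, 0, -5), c(0, 0, 1)),
                                      plane3(c(0, 0, 0), c(0, 0, -1)))),
           clippedVolume(sphere, list(plane3(c(0, 0, 0), c(0, 0, 1)),
                                      plane3(c(0, 0, 5), c(0, 0, -1)))),
           clippedVolume(sphere, list(plane3(c(0, 0, 5), c(0, 0, 1)))))
  expect_lt(max(abs(got - analytic) / analytic), 0.005)
  expect_equal(sum(got), meshVolume(sphere), tolerance = 1e-9)
})

test_that("zero smoothing is the identity; smoothing damps noise with little shrink", {
  sphere <- makeSphereMesh(8, spacing = 0.8)
  expect_identical(vertices(smoothMesh(sphere, iterations = 0)),
                   vertices(sphere))
  expect_identical(vertices(smoothMesh(sphere, factor = 0)), vertices(sphere))
  sm <- smoothMesh(sphere, 10, 0.2)
  v0 <- meshVolume(sphere)
  expect_lt(abs(meshVolume(sm) - v0) / v0, 0.02) # minor influence on size
  # radius spread (faceting noise) decreases
  spread <- function(m) sd(rowNorms(vertices(m)))
  expect_lt(spread(sm), spread(sphere))
})

test_that("decimation reduces triangles, stays watertight and within tolerance", {
  sphere <- makeSphereMesh(8, spacing = 1.0)
  dec <- decimateMesh(sphere, tolerance = 0.0375, edgeAngle = 10,
                      iterations = 3)
  expect_lt(nrow(faces(dec)), nrow(faces(sphere)))
  expect_true(isWatertight(dec))
  # every decimated vertex is a kept original vertex, so the decimated
  # surface deviates from the original surface by at most the tolerance at
  # its vertices; verify by brute force against the original surface
  set.seed(1)
  idx <- sample(nrow(vertices(dec)), 40)
  d <- bruteClosestDistances(vertices(dec)[idx, , drop = FALSE], sphere)
  expect_lte(max(d), 0.0375 + 1e-12)
  # and removed original vertices stay within tolerance of the new surface
  cp <- ramus3d:::cpp_closest_point(vertices(sphere), vertices(dec),
                                    faces(dec))
  expect_lte(max(cp$distance), 0.0375 + 1e-9)
})

test_that("face components separate disjoint shells", {
  two <- makeCube()
  far <- makeCube(origin = c(5, 0, 0))
  merged <- surfaceMesh(rbind(vertices(two), vertices(far)),
                        rbind(faces(two), faces(far) + nrow(vertices(two))))
  comp <- ramus3d:::faceComponents(merged)
  expect_equal(max(comp), 2)
  expect_equal(unname(table(comp)), c(12L, 12L), ignore_attr = TRUE)
})
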