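test_that("surface distances: identity, analytic offset and brute-force oracle", {
  cube <- makeCube()
  # identical meshes: all distances zero
  d0 <- surfaceDistances(cube, cube)
  expect_true(all(d0$absolute == 0))
  # a flat patch offset along its normal reports exactly the offset
  sq <- surfaceMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                    matrix(c(1, 2, 3, 1, 3, 4), ncol = 3, byrow = TRUE))
  sqUp <- applyTransform(sq, rigidTransform(diag(3), c(0, 0, 0.25)))
  dd <- surfaceDistances(sq, sqUp)
  expect_lt(max(abs(dd$absolute - 0.25)), 1e-9)
  # signed: source below target surface (target normal +z) -> negative
  expect_true(all(dd$signed == -dd$absolute))
  # brute-force equality on small meshes (<= 500 triangles)
  small <- makeSphereMesh(4, spacing = 2.2)
  expect_lte(nrow(faces(small)), 500)
  probe <- makeSphereMesh(4.5, spacing = 2.0)
  got <- surfaceDistances(probe, small)
  expected <- bruteClosestDistances(vertices(probe), small)
  expect_lt(max(abs(got$absolute - expected)), 1e-10)
  expect_error(surfaceDistances(surfaceMesh(matrix(0, 0, 3),
                                            matrix(0L, 0, 3)), cube), "empty")
})

test_that("regional accuracy is an area-weighted mean with missing-region flags", {
  case <- sharedCase()
  lab <- case@labeling
  mesh <- case@preopMesh
  # aligned identical rami: 0.0 mm in all 22 regions
  dId <- surfaceDistances(mesh, mesh)
  accId <- regionAccuracy(lab, dId, mesh)
  expect_equal(length(accId), 23) # 22 regions + whole
  expect_true(all(accId == 0))
  # a constant distance field reports the constant in every region
  dConst <- list(absolute = rep(0.3, nrow(vertices(mesh))),
                 signed = rep(0.3, nrow(vertices(mesh))))
  accC <- regionAccuracy(lab, dConst, mesh)
  expect_true(all(abs(accC - 0.3) < 1e-12))
  # direct-summation oracle on a random field
  set.seed(8)
  dr <- list(absolute = abs(rnorm(nrow(vertices(mesh)))))
  accR <- regionAccuracy(lab, dr, mesh)
  F <- faces(mesh); ar <- faceAreas(mesh)
  fd <- (dr$absolute[F[, 1]] + dr$absolute[F[, 2]] + dr$absolute[F[, 3]]) / 3
  for (lb in c("condyle", "R07", "R20")) {
    i <- which(lab@labels == lb)
    expect_equal(accR[[lb]], sum(fd[i] * ar[i]) / sum(ar[i]))
  }
  # whole-ramus value equals the area-weighted mean of the regional values
  regionAreas <- vapply(lab@levels, function(lb)
    sum(ar[lab@labels == lb]), numeric(1))
  expect_equal(unname(accR[["whole"]]),
               sum(accR[lab@levels] * regionAreas) / sum(regionAreas))
})

test_that("accuracy metric is invariant under a common rigid transform", {
  case <- sharedCase()
  mesh <- case@preopMesh
  moved <- applyTransform(mesh, rigidFromEuler(c(1, 2, -1), c(0.4, -0.2, 0.3)))
  d1 <- surfaceDistances(mesh, moved)
  G <- rigidFromEuler(c(10, -20, 5), c(30, -10, 12))
  d2 <- surfaceDistances(applyTransform(mesh, G), applyTransform(moved, G))
  expect_lt(max(abs(d1$absolute - d2$absolute)), 1e-6)
})

test_that("percent volume change follows the signed convention", {
  expect_equal(percentVolumeChange(100, 100), 0)
  expect_equal(percentVolumeChange(100, 90), -10)
  expect_equal(percentVolumeChange(c(10, 20), c(11, 18)), c(10, -10))
  expect_true(is.na(percentVolumeChange(0, 5)))
  expect_error(percentVolumeChange(1:3, 1:2), "equal length")
})

test_that("condylar resorption raises condylar distance monotonically while the reference stays quiet", {
  case <- sharedCase()
  lab <- case@labeling
  prev <- -Inf
  for (m in c(0.4, 0.8, 1.2)) {
    post <- applyRemodelling(case, resorptionSpec("condyle", m, falloff = 3,
                                                  affectedFraction = 0.7))
    d <- surfaceDistances(case@preopMesh, post) # perfect registration
    acc <- regionAccuracy(lab, d, case@preopMesh)
    expect_gt(acc[["condyle"]], prev)
    prev <- acc[["condyle"]]
    # reference-band regions stay below one voxel (0.30 mm)
    refRegions <- sprintf("R%02d", 1:8)
    expect_lt(max(acc[refRegions]), 0.30)
  }
})

test_that("distance-map export round-trips scalars and clamps the colour scale", {
  sq <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    matrix(c(1, 2, 3, 1, 3, 4), ncol = 3, byrow = TRUE))
  f <- tempfile(fileext = ".ply")
  # zero field: uniform mid-scale (white) colour
  exportDistanceMap(sq, rep(0, 4), f)
  txt <- readLines(f)
  vlines <- txt[(match("end_header", txt) + 1):(match("end_header", txt) + 4)]
  cols <- t(vapply(strsplit(vlines, " "),
                   function(x) as.integer(tail(x, 3)), integer(3)))
  expect_true(all(cols == 255))
  # scalars round-trip exactly; clamped values saturate the scale
  dd <- c(-5, -0.5, 0.5, 5)
  exportDistanceMap(sq, dd, f, clamp = 2)
  back <- readDistanceMap(f)
  expect_identical(back$distances, dd)
  txt <- readLines(f)
  vlines <- txt[(match("end_header", txt) + 1):(match("end_header", txt) + 4)]
  cols <- t(vapply(strsplit(vlines, " "),
                   function(x) as.integer(tail(x, 3)), integer(3)))
  expect_identical(cols[1, ], cols[1, ] * 0L + c(33L, 102L, 172L)) # deep blue
  expect_identical(cols[4, ], c(178L, 24L, 43L))                   # deep red
  expect_error(exportDistanceMap(sq, 1:3, f), "per vertex")
  unlink(f)
})
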