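test_that("seeded region growing selects exactly the seed's component", {
  arr <- array(0, c(30, 30, 30))
  arr[4:10, 4:10, 4:10] <- 700      # blob A
  arr[18:26, 18:26, 18:26] <- 900   # blob B
  vol <- voxelVolume(arr, spacing = 1, origin = c(0, 0, 0))
  maskA <- segmentBone(vol, seedPoint = c(6, 6, 6), lowerThreshold = 226)
  # flood-fill oracle from the same seed
  oracle <- bruteFloodFill(arr >= 226, c(7, 7, 7), 26)
  expect_identical(voxelData(maskA), oracle)
  expect_equal(sum(voxelData(maskA)), 7^3)
  # seed below threshold and out-of-grid seeds are rejected
  expect_error(segmentBone(vol, c(15, 15, 15)), "below the threshold")
  expect_error(segmentBone(vol, c(6, 6, 6), lowerThreshold = 1000),
               "below the threshold")
  expect_error(segmentBone(vol, c(200, 0, 0)), "outside")
})

test_that("segmenting a noiseless voxelized ramus recovers the occupancy exactly", {
  case <- sharedCaseWithVolume()
  vol <- case@preopVolume
  occ <- meshOccupancy(case@preopMesh, vol)
  seedIdx <- which(voxelData(occ), arr.ind = TRUE)[1000, ]
  seedWorld <- ramus3d:::voxelToWorld(vol, matrix(seedIdx, 1, 3))
  mask <- segmentBone(vol, seedWorld, lowerThreshold = 226)
  expect_identical(voxelData(mask), voxelData(occ))
})

test_that("cavity filling matches a background-component oracle and is idempotent", {
  # hollow voxel sphere
  d <- c(28, 28, 28)
  ctr <- c(14.5, 14.5, 14.5)
  idx <- as.matrix(expand.grid(1:28, 1:28, 1:28))
  r <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  hollow <- array(r <= 10 & r >= 7, d)
  m <- binaryMask(hollow, 1, c(0, 0, 0))
  filled <- fillMask(m)
  # oracle: background voxels not reachable from the boundary are cavity
  reach <- bruteFloodFill(!hollow, c(1, 1, 1), 6)
  cavity <- !hollow & !reach
  expect_identical(voxelData(filled), hollow | cavity)
  expect_gt(sum(cavity), 0)
  # idempotence
  expect_identical(voxelData(fillMask(filled)), voxelData(filled))
  solid <- binaryMask(array(r <= 10, d), 1, c(0, 0, 0))
  expect_identical(voxelData(fillMask(solid)), voxelData(solid))
})

test_that("largest-component filter removes satellite noise", {
  arr <- array(FALSE, c(20, 20, 20))
  arr[5:15, 5:15, 5:15] <- TRUE
  arr[18, 18, 18] <- TRUE
  m <- largestComponent(binaryMask(arr, 1, c(0, 0, 0)))
  expect_equal(sum(voxelData(m)), 11^3)
})

test_that("voxelization of a sphere reproduces the analytic volume within 2%", {
  r <- 10
  sphere <- makeSphereMesh(r, spacing = 0.4)
  vol <- voxelizeMesh(sphere, spacing = 0.3, noiseSd = 0)
  thr <- voxelData(vol) > 400 # bone/background midpoint
  vTrue <- 4 / 3 * pi * r^3
  expect_lt(abs(sum(thr) * 0.3^3 - vTrue) / vTrue, 0.02)
  # interior of a closed mesh is a single foreground component
  lab <- ramus3d:::cpp_label_components(as.logical(thr), dim(voxelData(vol)), 26L)
  expect_equal(attr(lab, "ncomp"), 1L)
  # default spacing of the intensity model is 0.30 mm isotropic
  expect_equal(formals(voxelizeMesh)$spacing, 0.30)
  expect_error(voxelizeMesh(sphere, spacing = 50), "spacing exceeds")
})

test_that("surface reconstruction recovers a sphere within 3% volume", {
  r <- 8
  sphere <- makeSphereMesh(r, spacing = 0.5)
  vol <- voxelizeMesh(sphere, spacing = 0.4)
  mask <- binaryMask(voxelData(vol) > 400, voxelSpacing(vol), voxelOrigin(vol))
  rec <- reconstructSurface(mask, decimIterations = 0)
  expect_true(isWatertight(rec))
  vTrue <- 4 / 3 * pi * r^3
  expect_lt(abs(meshVolume(rec) - vTrue) / vTrue, 0.03)
  # zero smoothing, zero decimation returns the raw isosurface
  raw <- reconstructSurface(mask, smoothIterations = 0, smoothFactor = 0,
                            decimIterations = 0)
  raw2 <- reconstructSurface(mask, smoothIterations = 0, decimIterations = 0)
  expect_identical(vertices(raw), vertices(raw2))
  # decimation reduces triangles and keeps decimated vertices on the original
  dec <- reconstructSurface(mask, decimIterations = 2)
  expect_lt(nrow(faces(dec)), nrow(faces(rec)))
  expect_error(reconstructSurface(binaryMask(array(FALSE, c(4, 4, 4)), 1,
                                             c(0, 0, 0))), "empty")
  # multi-component masks are refused with advice
  arr <- array(FALSE, c(12, 12, 12)); arr[2:4, 2:4, 2:4] <- TRUE
  arr[8:10, 8:10, 8:10] <- TRUE
  expect_error(reconstructSurface(binaryMask(arr, 1, c(0, 0, 0))),
               "component")
})

test_that("reconstruction error decreases monotonically with voxel spacing", {
  r <- 6
  sphere <- makeSphereMesh(r, spacing = 0.4)
  vRef <- meshVolume(sphere) # the digitized object is the ground truth
  errAt <- function(sp) {
    vol <- voxelizeMesh(sphere, spacing = sp)
    mask <- binaryMask(voxelData(vol) > 400, voxelSpacing(vol),
                       voxelOrigin(vol))
    rec <- reconstructSurface(mask, smoothIterations = 4, decimIterations = 0)
    abs(meshVolume(rec) - vRef) / vRef
  }
  errs <- c(errAt(0.6), errAt(0.3), errAt(0.15))
  expect_true(all(diff(errs) < 0))
})
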