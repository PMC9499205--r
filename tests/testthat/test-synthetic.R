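test_that("generation is a pure function of parameters and seed", {
  a <- generateRamus(seed = 7, makeVolume = FALSE)
  b <- generateRamus(seed = 7, makeVolume = FALSE)
  expect_identical(vertices(a@preopMesh), vertices(b@preopMesh))
  expect_identical(faces(a@preopMesh), faces(b@preopMesh))
  expect_identical(a@landmarks@coords, b@landmarks@coords)
  # a different seed gives a (slightly) different phantom
  c <- generateRamus(seed = 8, makeVolume = FALSE)
  expect_false(nrow(vertices(a@preopMesh)) == nrow(vertices(c@preopMesh)) &&
                 isTRUE(all.equal(vertices(a@preopMesh), vertices(c@preopMesh))))
  expect_error(generateRamus(ramusShapeParams(bladeHalfY = -1)), "positive")
})

test_that("phantom meshes are watertight and admit the landmark definitions", {
  for (seed in c(7, 19)) {
    case <- generateRamus(seed = seed, makeVolume = FALSE,
                          side = if (seed == 7) "R" else "L")
    expect_true(isWatertight(case@preopMesh))
    lm <- case@landmarks
    expect_setequal(unique(lm@name),
                    c("C-point", "Go", "Or", "Po", "Con", "Cor", "RP", "RI"))
    # ramal landmarks lie on (or extremely near) the mesh surface
    onMesh <- lm@provenance != "auxiliary"
    d <- ramus3d:::cpp_closest_point(lm@coords[onMesh, , drop = FALSE],
                                     vertices(case@preopMesh),
                                     faces(case@preopMesh))$distance
    expect_lt(max(d), 0.30) # within one (default) voxel of the surface
  }
})

test_that("the C-point equals the brute-force most caudal notch-arc vertex", {
  for (seed in c(7, 13)) {
    case <- generateRamus(seed = seed, makeVolume = FALSE)
    expected <- oracleCPoint(case@preopMesh,
                             ramus3d:::notchWindow(case@shapeParams),
                             halfWidth = 0.5)
    got <- getLandmark(case@landmarks, "C-point", "R")
    expect_equal(got, expected)
  }
})

test_that("preoperative volumes default to 0.30 mm isotropic spacing", {
  expect_equal(eval(formals(generateRamus)$volumeSpacing), 0.30)
  case <- generateRamus(seed = 5, volumeSpacing = 0.30,
                        shapeParams = ramusShapeParams(meshSpacing = 1.3))
  expect_equal(voxelSpacing(case@preopVolume), rep(0.30, 3))
  # bone sits above the standard 226 threshold, background below
  v <- voxelData(case@preopVolume)
  expect_setequal(unique(as.numeric(v)), c(0, 800))
})

test_that("resorption is inward, local, monotone and zero-safe", {
  case <- sharedCase()
  v0 <- bruteMeshVolume(case@preopMesh)
  # magnitude 0 returns the identical mesh
  m0 <- applyRemodelling(case, resorptionSpec("condyle", 0))
  expect_identical(vertices(m0), vertices(case@preopMesh))
  m05 <- applyRemodelling(case, resorptionSpec("condyle", 0.5))
  m10 <- applyRemodelling(case, resorptionSpec("condyle", 1.0))
  expect_true(isWatertight(m10))
  # volume strictly decreases and is monotone in magnitude (brute-force sums)
  expect_lt(bruteMeshVolume(m05), v0)
  expect_lt(bruteMeshVolume(m10), bruteMeshVolume(m05))
  # locality: vertices beyond the falloff margin do not move at all
  spec <- resorptionSpec("condyle", 1.0, falloff = 4)
  moved <- rowNorms(vertices(m10) - vertices(case@preopMesh))
  condFaces <- regionFaces(case@labeling, "condyle")
  condMesh <- submesh(case@preopMesh, condFaces)
  dToRegion <- ramus3d:::cpp_closest_point(vertices(case@preopMesh),
                                           vertices(condMesh),
                                           faces(condMesh))$distance
  expect_true(all(moved[dToRegion >= spec@falloff] == 0))
  expect_equal(moved[which.max(dToRegion)], 0)
  # unknown region label
  expect_error(applyRemodelling(case, resorptionSpec("R99", 1)), "unknown")
})

test_that("per-region volume losses sum to the total loss", {
  case <- sharedCase()
  post <- applyRemodelling(case, resorptionSpec("condyle", 1.0))
  preV <- regionVolumes(case@preopMesh, case@labeling)
  postMesh <- surfaceMesh(vertices(post), faces(post))
  postV <- vapply(case@labeling@levels, function(lb)
    clippedVolume(postMesh, ramus3d:::regionHalfspaces(case@labeling, lb)),
    numeric(1))
  totalLoss <- meshVolume(case@preopMesh) - meshVolume(postMesh)
  expect_gt(totalLoss, 0)
  expect_lt(abs(sum(preV - postV) - totalLoss) / totalLoss, 0.001)
})

test_that("a null case leaves pre and post identical in mesh and volume", {
  case <- generateRamus(seed = 9, volumeSpacing = 0.8)
  case <- buildPostop(case, rigidIdentity(), resorption = NULL)
  expect_identical(vertices(case@postopMesh), vertices(case@preopMesh))
  expect_identical(voxelData(case@postopVolume), voxelData(case@preopVolume))
})

test_that("observer simulation is reproducible and has the configured RMS", {
  case <- sharedCase()
  o1 <- simulateObserver(case, 0.5, seed = 31)
  o2 <- simulateObserver(case, 0.5, seed = 31)
  expect_identical(o1$landmarks@coords, o2$landmarks@coords)
  expect_identical(o1$roiOffsets, o2$roiOffsets)
  o0 <- simulateObserver(case, 0, seed = 31)
  expect_identical(o0$landmarks@coords, case@landmarks@coords)
  expect_error(simulateObserver(case, -1), ">= 0")
  # Monte-Carlo check of the tangential noise model: RMS displacement of the
  # manual landmarks over many draws matches the configured scale within 5%
  scale <- 0.5
  base <- case@landmarks
  keep <- base@provenance != "derived"
  baseMan <- new("LandmarkSet", name = base@name[keep], side = base@side[keep],
                 coords = base@coords[keep, , drop = FALSE],
                 provenance = base@provenance[keep])
  vn <- vertexNormals(case@preopMesh)
  sq <- withr::with_seed(99, {
    acc <- c()
    for (i in 1:1000) {
      p <- ramus3d:::perturbLandmarkSet(case@preopMesh, baseMan, scale, vn)
      acc <- c(acc, rowSums((p@coords - baseMan@coords)^2))
    }
    acc
  })
  expect_lt(abs(sqrt(mean(sq)) - scale) / scale, 0.05)
})
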