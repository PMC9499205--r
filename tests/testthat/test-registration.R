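test_that("reference structure excludes the condyle and is connected", {
  case <- sharedCase()
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes, makeVoxelMask = FALSE)
  expect_gt(length(ref@faces), 100)
  condyleFaces <- regionFaces(case@labeling, "condyle")
  expect_length(intersect(ref@faces, condyleFaces), 0)
  # no selected face lies above the C-plane on the posterior component, and
  # the selection (coronoid + ramal band) is a single connected patch
  comp <- ramus3d:::faceComponents(case@preopMesh, ref@faces)
  expect_equal(max(comp), 1)
  # missing landmark is reported by name
  lm <- case@landmarks
  keep <- lm@name != "Con"
  lm2 <- new("LandmarkSet", name = lm@name[keep], side = lm@side[keep],
             coords = lm@coords[keep, , drop = FALSE],
             provenance = lm@provenance[keep])
  expect_error(buildReferenceStructure(case@preopMesh, lm2, side = "R"), "Con")
})

test_that("voxel ROI and surface selection describe the same region (Dice)", {
  case <- generateRamus(seed = 4, volumeSpacing = 1.0,
                        shapeParams = ramusShapeParams(meshSpacing = 1.6))
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes,
                                 volume = case@preopVolume, voxelBand = 1.5)
  vm <- voxelData(ref@voxelMask)
  # independent voxelization oracle: brute-force distance from voxel centres
  # to the selected faces (coarse mesh keeps the loop feasible)
  sub <- submesh(case@preopMesh, ref@faces)
  vol <- case@preopVolume
  d <- dim(voxelData(vol))
  idx <- which(vm | TRUE, arr.ind = TRUE)
  # candidates: restrict to a bounding box around the selection
  ext <- apply(vertices(sub), 2, range)
  w <- ramus3d:::voxelToWorld(vol, idx)
  inBox <- w[, 1] >= ext[1, 1] - 2 & w[, 1] <= ext[2, 1] + 2 &
    w[, 2] >= ext[1, 2] - 2 & w[, 2] <= ext[2, 2] + 2 &
    w[, 3] >= ext[1, 3] - 2 & w[, 3] <= ext[2, 3] + 2
  cand <- which(inBox)
  V <- vertices(sub); F <- faces(sub)
  fc <- faceCentroids(sub)
  oracle <- logical(length(vm))
  for (i in cand) {
    p <- w[i, ]
    near <- which(rowSums(sweep(fc, 2, p)^2) < (1.5 + 2.5)^2)
    if (!length(near)) next
    dmin <- min(vapply(near, function(t)
      brutePointTriDist(p, V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ]),
      numeric(1)))
    oracle[i] <- dmin <= 1.5
  }
  dice <- 2 * sum(vm & oracle) / (sum(vm) + sum(oracle))
  expect_gte(dice, 0.9)
})

test_that("ICP recovers identity and a known displacement on the reference", {
  case <- sharedCase()
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes, makeVoxelMask = FALSE)
  # moving = fixed, identity init
  resId <- icpRegister(case@preopMesh, case@preopMesh, ref)
  expect_true(resId@converged)
  expect_lt(rotationAngle(resId@transform) * 180 / pi, 1e-6)
  expect_lt(ramus3d:::vnorm(resId@transform@translation), 1e-6)
  # known rigid displacement, landmark prealign initialisation
  disp <- randomRigidTransform(5, 10,
                               center = colMeans(vertices(case@preopMesh)),
                               seed = 17)
  moving <- applyTransform(case@preopMesh, disp)
  init <- prealign(case@landmarks, applyTransform(case@landmarks, disp))
  res <- icpRegister(case@preopMesh, moving, ref, init = init)
  expect_true(res@converged)
  refV <- vertices(submesh(case@preopMesh, ref@faces))
  tre <- targetRegistrationError(res@transform, invertTransform(disp), refV)
  expect_lt(tre, 0.05)
  # a degenerate reference is rejected
  tiny <- new("ReferenceStructure", side = "R", faces = 1L,
              voxelMask = NULL, observer = "obs1")
  expect_error(icpRegister(case@preopMesh, moving, tiny), "too few")
})

test_that("ICP is equivariant under a global rigid change of frame", {
  case <- sharedCase()
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes, makeVoxelMask = FALSE)
  disp <- randomRigidTransform(3, 6, center = colMeans(vertices(case@preopMesh)),
                               seed = 23)
  moving <- applyTransform(case@preopMesh, disp)
  init <- prealign(case@landmarks, applyTransform(case@landmarks, disp))
  base <- icpRegister(case@preopMesh, moving, ref, init = init)
  G <- rigidFromEuler(c(4, -9, 2), c(10, -5, 3))
  resG <- icpRegister(applyTransform(case@preopMesh, G),
                      applyTransform(moving, G), ref,
                      init = composeTransforms(G, composeTransforms(init, invertTransform(G))))
  conj <- composeTransforms(G, composeTransforms(base@transform,
                                                 invertTransform(G)))
  expect_lt(max(abs(transformMatrix(resG@transform) - transformMatrix(conj))),
            1e-3)
})

test_that("NMI registration recovers identity and a small displacement", {
  case <- sharedCaseWithVolume()
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes,
                                 volume = case@preopVolume)
  # moving = fixed at identity init stays at identity
  resId <- miRegister(case@preopVolume, case@preopVolume, ref@voxelMask)
  expect_lt(rotationAngle(resId@transform) * 180 / pi, 0.1)
  expect_lt(ramus3d:::vnorm(resId@transform@translation), 0.1 * 0.6) # 0.1 voxel
  # known small displacement
  disp <- rigidFromEuler(c(2, -3, 4), c(1.5, -1, 2),
                         center = colMeans(vertices(case@preopMesh)))
  case2 <- buildPostop(case, disp)
  init <- prealign(case@landmarks, applyTransform(case@landmarks, disp))
  res <- miRegister(case@preopVolume, case2@postopVolume, ref@voxelMask,
                    init = init)
  refCtr <- colMeans(faceCentroids(case@preopMesh)[ref@faces, , drop = FALSE])
  dd <- transformDiscrepancy(res@transform, invertTransform(disp), at = refCtr)
  expect_lt(dd[["translationMm"]], 0.3)
  expect_lt(dd[["rotationDeg"]], 0.5)
})

test_that("uninformative ROIs raise an explicit insufficient-information failure", {
  case <- sharedCaseWithVolume()
  vol <- case@preopVolume
  d <- dim(voxelData(vol))
  # ROI in a uniform background corner: constant intensity
  m <- array(FALSE, d)
  m[1:12, 1:12, 1:12] <- TRUE
  roi <- binaryMask(m, voxelSpacing(vol), voxelOrigin(vol))
  expect_error(miRegister(vol, vol, roi), class = "insufficientInformation")
  # ROI below the minimum voxel count
  m2 <- array(FALSE, d); m2[30:34, 10:14, 50:54] <- TRUE
  roi2 <- binaryMask(m2, voxelSpacing(vol), voxelOrigin(vol))
  expect_error(miRegister(vol, vol, roi2), class = "insufficientInformation")
})

test_that("residual transform error grows with reference-structure remodelling", {
  case <- sharedCase()
  ref <- buildReferenceStructure(case@preopMesh, case@landmarks, side = "R",
                                 planes = case@planes, makeVoxelMask = FALSE)
  refV <- vertices(submesh(case@preopMesh, ref@faces))
  disp <- randomRigidTransform(4, 8,
                               center = colMeans(vertices(case@preopMesh)),
                               seed = 91)
  init <- prealign(case@landmarks, applyTransform(case@landmarks, disp))
  tres <- vapply(c(0.5, 1.5, 3), function(m) {
    spec <- resorptionSpec("reference_structure", m, falloff = 6,
                           affectedFraction = 0.6)
    post <- applyTransform(applyRemodelling(case, spec), disp)
    reg <- icpRegister(case@preopMesh, post, ref, init = init)
    targetRegistrationError(reg@transform, invertTransform(disp), refV)
  }, numeric(1))
  expect_true(all(diff(tres) > 0))
})
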