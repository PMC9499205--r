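test_that("cutting planes satisfy their defining constraints", {
  case <- sharedCase()
  pl <- case@planes
  lm <- case@landmarks
  # C-plane parallel to Frankfurt and through C-point
  expect_gt(abs(sum(pl@cPlane@normal * pl@frankfurt@normal)), 1 - 1e-9)
  expect_lt(abs(planeDistance(getLandmark(lm, "C-point", "R"), pl@cPlane)), 1e-9)
  # ramus plane contains Con, Cor, Go
  for (nm in c("Con", "Cor", "Go"))
    expect_lt(abs(planeDistance(getLandmark(lm, nm, "R"), pl@ramusPlane)), 1e-9)
  # posterior ramus plane through RP and Con, perpendicular to the ramus plane
  expect_lt(abs(planeDistance(getLandmark(lm, "RP", "R"), pl@posteriorRamus)), 1e-9)
  expect_lt(abs(planeDistance(getLandmark(lm, "Con", "R"), pl@posteriorRamus)), 1e-9)
  expect_lt(abs(sum(pl@posteriorRamus@normal * pl@ramusPlane@normal)), 1e-9)
  # anterior plane through Cor, parallel to posterior
  expect_lt(abs(planeDistance(getLandmark(lm, "Cor", "R"), pl@anteriorRamus)), 1e-9)
  expect_gt(abs(sum(pl@anteriorRamus@normal * pl@posteriorRamus@normal)), 1 - 1e-9)
  # inferior plane through RI, parallel to the C-plane
  expect_lt(abs(planeDistance(getLandmark(lm, "RI", "R"), pl@inferiorRamus)), 1e-9)
  expect_gt(abs(sum(pl@inferiorRamus@normal * pl@cPlane@normal)), 1 - 1e-9)
})

test_that("intermediate planes are equally spaced (brute-force distances)", {
  case <- sharedCase()
  pl <- case@planes
  gapDist <- function(p1, p2) abs(sum((p2@point - p1@point) * p1@normal))
  apSeq <- c(list(pl@posteriorRamus), pl@intermediatesAP, list(pl@anteriorRamus))
  gaps <- vapply(seq_len(length(apSeq) - 1), function(i)
    gapDist(apSeq[[i]], apSeq[[i + 1]]), numeric(1))
  expect_lt(max(gaps) - min(gaps), 1e-9)
  ciSeq <- c(list(pl@cPlane), pl@intermediatesCI, list(pl@inferiorRamus))
  gapsCI <- vapply(seq_len(length(ciSeq) - 1), function(i)
    gapDist(ciSeq[[i]], ciSeq[[i + 1]]), numeric(1))
  expect_lt(max(gapsCI) - min(gapsCI), 1e-9)
  expect_length(pl@intermediatesAP, 3)
})

test_that("missing or degenerate landmarks give informative errors", {
  case <- sharedCase()
  lm <- case@landmarks
  drop1 <- function(nm) {
    keep <- lm@name != nm
    new("LandmarkSet", name = lm@name[keep], side = lm@side[keep],
        coords = lm@coords[keep, , drop = FALSE],
        provenance = lm@provenance[keep])
  }
  expect_error(buildPlanes(drop1("RP"), side = "R"), "RP")
  expect_error(buildPlanes(drop1("Go"), side = "R"), "Go")
  # collinear Con/Cor/Go -> degenerate ramus plane
  bad <- lm
  con <- getLandmark(lm, "Con", "R"); cor <- getLandmark(lm, "Cor", "R")
  bad@coords[bad@name == "Go", ] <- con + 0.5 * (cor - con)
  expect_error(buildPlanes(bad, side = "R"), "collinear")
})

test_that("partition labels every face and yields 20 nonempty subregions", {
  case <- sharedCase()
  lab <- case@labeling
  mesh <- case@preopMesh
  expect_equal(length(lab@labels), nrow(faces(mesh)))
  expect_true(all(nzchar(lab@labels)))
  sub <- grep("^R[0-9]+$", regionLevels(lab), value = TRUE)
  expect_length(sub, 20)
  expect_setequal(sub, sprintf("R%02d", 1:20))
  # labelled area accounts for the total area exactly
  ar <- faceAreas(mesh)
  expect_lt(abs(sum(ar[lab@labels %in% regionLevels(lab)]) - meshArea(mesh)) /
              meshArea(mesh), 1e-6)
  # subregion adjacency forms a 4 x 5 grid: 4 anteroposterior columns appear
  # in every craniocaudal row
  idx <- as.integer(sub("^R", "", lab@labels[grepl("^R", lab@labels)]))
  expect_setequal(unique((idx - 1) %% 4 + 1), 1:4)
  expect_setequal(unique((idx - 1) %/% 4 + 1), 1:5)
})

test_that("capped cell volumes sum to the whole ramal part below the C-plane", {
  case <- sharedCase()
  v <- regionVolumes(case@preopMesh, case@labeling)
  whole <- clippedVolume(case@preopMesh,
                         list(plane3(case@planes@cPlane@point,
                                     -case@planes@cPlane@normal)))
  cells <- v[grep("^R", names(v))]
  expect_lt(abs(sum(cells) - whole) / whole, 0.001)
  # and all regions together account for the full enclosed volume
  expect_lt(abs(sum(v) - meshVolume(case@preopMesh)) /
              meshVolume(case@preopMesh), 0.001)
})

test_that("the literal grid mode produces up to 28 cells", {
  case <- sharedCase()
  pl <- buildPlanes(case@landmarks, side = "R", grid = "literal")
  expect_length(pl@intermediatesCI, 6)
  lab <- partitionRamus(case@preopMesh, pl)
  sub <- grep("^R[0-9]+$", regionLevels(lab), value = TRUE)
  expect_lte(length(sub), 28)
  expect_gt(length(sub), 20)
})

test_that("derived landmarks: definitional ordering, oracle and equivariance", {
  case <- sharedCase()
  lm <- case@landmarks
  ant <- case@planes@anterior
  con <- getLandmark(lm, "Con", "R"); cor <- getLandmark(lm, "Cor", "R")
  expect_lt(sum(con * ant), sum(cor * ant)) # Con posterior to Cor
  # independent oracle: per-face triangle/plane section, most posterior point
  mesh <- case@preopMesh
  V <- vertices(mesh); F <- faces(mesh)
  d <- planeDistance(V, case@planes@cPlane)
  pts <- NULL
  for (t in seq_len(nrow(F))) {
    vs <- F[t, ]; dv <- d[vs]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dv[e[1]]; d2 <- dv[e[2]]
      if (abs(d1) < 1e-9) pts <- rbind(pts, V[vs[e[1]], ])
      else if ((d1 > 0) != (d2 > 0) && abs(d2) >= 1e-9) {
        tt <- d1 / (d1 - d2)
        pts <- rbind(pts, V[vs[e[1]], ] + tt * (V[vs[e[2]], ] - V[vs[e[1]], ]))
      }
    }
  }
  oracleCon <- pts[which.min(pts %*% ant), ]
  expect_lt(ramus3d:::vnorm(con - oracleCon), 1e-9)
  # translating the whole scene shifts Con by exactly the same amount
  shift <- c(5, 0, 0)
  tr <- rigidTransform(diag(3), shift)
  manual <- lm
  keep <- manual@provenance != "derived"
  manual <- new("LandmarkSet", name = lm@name[keep], side = lm@side[keep],
                coords = lm@coords[keep, , drop = FALSE],
                provenance = lm@provenance[keep])
  shifted <- locateDerivedLandmarks(applyTransform(mesh, tr),
                                    applyTransform(manual, tr), side = "R")
  expect_lt(ramus3d:::vnorm(getLandmark(shifted, "Con", "R") - (con + shift)), 1e-9)
})

test_that("partition is side-symmetric under mirroring", {
  caseR <- sharedCase()
  meshL <- mirrorMesh(caseR@preopMesh)
  lmR <- caseR@landmarks
  co <- lmR@coords
  co[, 2] <- -co[, 2]
  sideFlip <- ifelse(lmR@side == "R", "L", "R")
  lmL <- new("LandmarkSet", name = lmR@name, side = sideFlip, coords = co,
             provenance = lmR@provenance)
  plL <- buildPlanes(lmL, side = "L")
  labL <- partitionRamus(meshL, plL)
  # mirrorMesh preserves face order, so labels must agree face by face
  expect_identical(labL@labels, caseR@labeling@labels)
})
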