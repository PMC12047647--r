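# phantom factory: shells, landmarks, montage geometry, mesh, connectome

test_that("sphere phantom nests shells and places landmarks on the scalp", {
  ph <- buildSpherePhantom(c(92, 86, 80, 78, 70),
                           c(0.4, 0.01, 1.8, 0.3, 0.15), spacing = 2)
  labs <- phantomLabels(ph)
  dims <- dim(labs)
  ctr <- (dims + 1) / 2
  expect_equal(labs[ctr[1], ctr[2], ctr[3]], 5L)   # innermost label at centre
  # labels non-increasing along rays from the centre: check +x axis
  ray <- labs[ctr[1]:dims[1], ctr[2], ctr[3]]
  ray <- ray[ray > 0]
  expect_true(all(diff(ray) <= 0))
  # landmarks on the outer boundary within one voxel
  lm <- scalpLandmarks(ph)
  expect_equal(unname(sqrt(rowSums(lm^2))), rep(92, 4), tolerance = 2 / 92)
  expect_equal(unname(lm["nasion", 2]), 92)        # nasion at +y
})

test_that("single-shell phantom is a uniform ball and errors are informative", {
  ph <- buildSpherePhantom(30, 1, spacing = 2, names = "gm")
  labs <- phantomLabels(ph)
  expect_setequal(unique(as.integer(labs)), c(0L, 1L))
  expect_error(buildSpherePhantom(c(92, 86), c(1, 1), spacing = 50),
               "thinner than one voxel")
  expect_error(buildSpherePhantom(c(80, 86), c(1, 1), spacing = 2),
               "decreasing")
})

test_that("voxelized shell volumes match analytic sphere-shell volumes within 5%", {
  radii <- c(92, 86, 80, 78, 70)
  ph <- buildSpherePhantom(radii, c(0.4, 0.01, 1.8, 0.3, 0.15), spacing = 2)
  counts <- tabulate(as.integer(phantomLabels(ph)), 5)
  voxVol <- prod(voxelSpacing(ph))
  outer_ <- radii
  inner_ <- c(radii[-1], 0)
  analytic <- 4 / 3 * pi * (outer_^3 - inner_^3)
  expect_equal(counts * voxVol, analytic, tolerance = 0.05)
})

test_that("10-10 construction: Cz at the pole, 10% arc rule, mirror symmetry", {
  ph <- coarsePhantom()
  mon <- placeElectrodes1010(ph)
  R <- 92
  pos <- electrodePositions(mon)
  expect_lt(sum(abs(pos["Cz", ] - c(0, 0, R))), voxelSpacing(ph)[1])
  # arc(nasion -> Fpz) / arc(nasion -> inion over the scalp) = 0.10
  arc <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  nas <- scalpLandmarks(ph)["nasion", ]
  ini <- scalpLandmarks(ph)["inion", ]
  frac <- arc(nas, pos["Fpz", ]) / pi       # nasion-inion arc spans pi
  expect_equal(frac, 0.10, tolerance = 0.01)
  fracOz <- arc(ini, pos["Oz", ]) / pi
  expect_equal(fracOz, 0.10, tolerance = 0.01)
  # every left/right pair mirrors about the midsagittal (x = 0) plane
  labs <- mon@electrodes$label
  lefts <- grep("7$|5$|3$|1$", labs, value = TRUE)
  for (l in lefts) {
    rlab <- chartr("75318", "86429", l)
    if (!rlab %in% labs) next
    pl <- pos[l, ]; pr <- pos[rlab, ]
    expect_lt(max(abs(pl * c(-1, 1, 1) - pr)), voxelSpacing(ph)[1])
  }
  # midline electrodes in the midsagittal plane
  expect_lt(max(abs(pos[c("Fz", "Cz", "Pz"), 1])), 1e-6)
})

test_that("degenerate landmarks are rejected", {
  ph <- coarsePhantom()
  ph@landmarks["rpa", ] <- ph@landmarks["nasion", ]   # collinear frame
  ph@landmarks["lpa", ] <- ph@landmarks["inion", ]
  expect_error(placeElectrodes1010(ph), "landmark")
})

test_that("cortical tessellation is a quasi-uniform icosphere with full region cover", {
  ph <- coarsePhantom()
  mesh <- tessellateCortex(ph, 162, nRegions = 24L)
  expect_equal(nrow(meshVertices(mesh)), 162)
  expect_equal(nrow(mesh@triangles), 320)
  rMid <- mean(c(74, 66))                   # mid-GM radius of the fixture
  rad <- sqrt(rowSums(meshVertices(mesh)^2))
  expect_equal(rad, rep(rMid, 162), tolerance = 0.01, ignore_attr = TRUE)
  # normals parallel to vertex directions on the sphere
  nd <- rowSums(meshNormals(mesh) * meshVertices(mesh)) / rad
  expect_equal(nd, rep(1, 162), tolerance = 1e-9, ignore_attr = TRUE)
  # every region occupied when vertices >> regions
  dense <- tessellateCortex(ph, 2562, nRegions = 24L)
  expect_equal(sort(unique(meshRegions(dense))), 1:24)
})

test_that("synthetic connectome: symmetry, zero diagonal, hemisphere structure", {
  con <- synthConnectome(24L, decayMm = 40, interhemisphericScale = 0,
                         seed = 3)
  w <- scWeights(con)
  expect_true(isSymmetric(unname(w)))
  expect_true(all(diag(w) == 0))
  cross <- outer(con@hemisphere, con@hemisphere, "!=")
  expect_true(all(w[cross] == 0))           # scale 0 disconnects hemispheres
  expect_true(all(w >= 0))
  # lengths are the Euclidean centroid distances
  expect_equal(unname(scLengths(con)),
               unname(as.matrix(dist(scCentroids(con)))))
})

test_that("generators are bit-identical under the same seed", {
  c1 <- synthConnectome(16L, seed = 42)
  c2 <- synthConnectome(16L, seed = 42)
  expect_identical(scWeights(c1), scWeights(c2))
  p1 <- buildSpherePhantom(c(50, 44), c(0.4, 0.3), spacing = 2)
  p2 <- buildSpherePhantom(c(50, 44), c(0.4, 0.3), spacing = 2)
  expect_identical(phantomLabels(p1), phantomLabels(p2))
  m1 <- placeElectrodes1010(coarsePhantom())
  m2 <- placeElectrodes1010(coarsePhantom())
  expect_identical(electrodeTable(m1), electrodeTable(m2))
})
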