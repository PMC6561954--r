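test_that("ring builders produce the documented sign patterns", {
  sym <- buildRing(6, 2.5, "symmetric_oop")
  expect_equal(sym@disp, rep(1, 6))
  anti <- buildRing(6, 2.5, "antisymmetric_oop")
  expect_equal(anti@disp, c(1, -1, 1, -1, 1, -1))
  ## para pairs (opposite atoms) vibrate in opposite directions
  expect_equal(anti@disp[1:3], -anti@disp[4:6])
  expect_error(buildRing(5, 2.5, "antisymmetric_oop"), "even")
  expect_error(buildRing(1, 2.5), "at least 2")
  ## default frequencies of the out-of-plane pair
  expect_equal(sym@frequency, 664)
  expect_equal(anti@frequency, 835)
})

test_that("analytic density matches an independent closed-form evaluation", {
  mol <- buildRing(3, 1.8, "symmetric_oop", sigmaXY = 0.6, sigmaZ = 0.3)
  probe <- c(0.7, -0.4, 0.25)
  ## independent re-implementation of the lobe formula
  expected <- 0 + 0i
  for (i in 1:3) {
    d <- probe - mol@positions[i, ]
    expected <- expected + mol@amplitudes[i] * mol@disp[i] *
      (d[3] / 0.3) * exp(-(d[1]^2 + d[2]^2) / (2 * 0.6^2) -
                         d[3]^2 / (2 * 0.3^2))
  }
  expect_equal(analyticDensity(mol, probe), expected, tolerance = 1e-14)
})

test_that("out-of-plane densities are odd across the molecular plane", {
  mol <- buildRing(6, 2.5, "antisymmetric_oop")
  pts <- cbind(runif(20, -3, 3), runif(20, -3, 3), runif(20, 0.1, 2))
  above <- analyticDensity(mol, pts)
  below <- analyticDensity(mol, cbind(pts[, 1:2], -pts[, 3]))
  expect_equal(below, -above, tolerance = 1e-14)
  ## exact node on the plane
  expect_true(all(analyticDensity(mol, cbind(pts[, 1:2], 0)) == 0))
})

test_that("in-plane densities are odd along the displacement direction", {
  mol <- buildRing(4, 2, "inplane")
  ## atom 1 at (2, 0, 0), tangent (0, 1, 0): density odd in (y - 0)
  p <- c(2, 0.4, 0.2)
  m <- c(2, -0.4, 0.2)
  ## only atom 1 contributes appreciably at this probe
  one <- ToyMolecule(mol@positions[1, , drop = FALSE],
                     tangents = mol@tangents[1, , drop = FALSE],
                     modeKind = "inplane")
  expect_equal(analyticDensity(one, m), -analyticDensity(one, p),
               tolerance = 1e-14)
})

test_that("default rasters use the documented box conventions", {
  mol <- buildRing(6, 2.5, "symmetric_oop")
  rd <- rasterizeDensity(mol)
  g <- fieldGrid(rd)
  expect_equal(gridStep(g), c(0.4, 0.4, 0.1))
  ## 3 Angstrom margins beyond the extreme atoms
  expect_lte(gridOrigin(g)[1], min(mol@positions[, 1]) - 3 + 1e-9)
  hi <- gridOrigin(g) + (gridCounts(g) - 1L) * gridStep(g)
  expect_gte(hi[1], max(mol@positions[, 1]) + 3 - 1e-9)
})

test_that("both out-of-plane families are far-field silent on their grids", {
  for (mode in c("symmetric_oop", "antisymmetric_oop")) {
    rd <- ringDensity(mode)
    scale <- sum(Mod(fieldValues(rd))) * voxelVolume(fieldGrid(rd))
    expect_lt(Mod(farField(rd)), 1e-10 * scale)
  }
})

test_that("refining the grid reduces the discretization error of the norm", {
  ## single lobe: the integral of |density| has the closed form
  ## 2 * sigma_z * 2 * pi * sigma_xy^2 (amplitude 1)
  mol <- ToyMolecule(matrix(0, 1, 3), sigmaXY = 0.5, sigmaZ = 0.4)
  exact <- 2 * 0.4 * 2 * pi * 0.5^2
  norm1 <- function(g) {
    rd <- rasterizeDensity(mol, g)
    sum(Mod(fieldValues(rd))) * voxelVolume(g)
  }
  coarse <- GridSpec(origin = rep(-3, 3), step = 0.3, counts = 21L)
  fine <- GridSpec(origin = rep(-3, 3), step = 0.15, counts = 41L)
  errC <- abs(norm1(coarse) - exact)
  errF <- abs(norm1(fine) - exact)
  expect_lt(errF, errC / 2)
})

test_that("displacement cube pairs are linear in Q and file-faithful", {
  dir <- withr::local_tempdir()
  mol <- buildRing(4, 1.5, "antisymmetric_oop")
  g <- GridSpec(origin = c(-3, -3, -1.6), step = c(0.4, 0.4, 0.2),
                counts = c(16L, 16L, 17L))
  truth <- rasterizeDensity(mol, g)
  for (dQ in c(0.01, 0.005)) {
    paths <- pairedDisplacementCubes(mol, dQ = dQ, dir = dir, grid = g)
    plus <- readCube(paths$plusRe, "real")
    minus <- readCube(paths$minusRe, "real")
    rd <- centralDifference(plus, minus, dQ = dQ)
    mx <- max(Mod(fieldValues(truth)))
    ## the construction is exactly linear in Q, so the only deviation is
    ## the cube file's 6-digit precision
    expect_lt(max(Mod(fieldValues(rd) - fieldValues(truth))), 2e-6 * mx)
    ## swapped files negate the derivative
    neg <- centralDifference(minus, plus, dQ = dQ)
    expect_identical(fieldValues(neg), -fieldValues(rd))
  }
})

test_that("hotspots sit near but not exactly on the atoms", {
  ## continuous radial intensity profile through the atom at (2.5, 0):
  ## the maximum is displaced off the atom radius by a small, sub-sigma
  ## amount (finer than any practical scan raster)
  rd <- ringDensity("symmetric_oop")
  r <- seq(2.2, 2.8, by = 0.005)
  prof <- vapply(r, function(x)
    tersIntensity(rd, NearField(fwhm = 1.3, center = c(x, 0, 1))),
    numeric(1))
  offset <- abs(r[which.max(prof)] - 2.5)
  expect_gt(offset, 0.005)  # displaced off the atom...
  expect_lt(offset, 0.5)    # ...but by less than a lobe width
})

test_that("far-field-silent modes are activated by a confined field", {
  rd <- ringDensity("antisymmetric_oop")
  expect_lt(Mod(farField(rd)),
            1e-10 * sum(Mod(fieldValues(rd))) * voxelVolume(fieldGrid(rd)))
  plan <- ScanPlan(c(-3.5, 3.5), c(-3.5, 3.5), step = 0.5, height = 1,
                   field = NearField(fwhm = 1.3))
  expect_gt(max(imageIntensities(scanImage(rd, plan))), 0)
})

test_that("the resonant fixture's imaginary part sits below the plane", {
  mol <- buildRing(6, 2.5, "antisymmetric_oop", imagScale = 0.2)
  rd <- rasterizeDensity(mol)
  z <- gridCoordinates(fieldGrid(rd))[, 3L]
  im <- abs(as.vector(Im(fieldValues(rd))))
  expect_gt(sum(im[z < 0]), 2 * sum(im[z > 0]))
})

test_that("fixture bundles contain everything the pipeline ingests", {
  dir <- withr::local_tempdir()
  mols <- list(buildRing(6, 2.5, "symmetric_oop"),
               buildRing(6, 2.5, "antisymmetric_oop"))
  bundle <- writeFixtureBundle(mols, dir)
  expect_true(file.exists(bundle$xyz))
  expect_true(file.exists(bundle$modeTable))
  modes <- readModeTable(bundle$modeTable)
  expect_length(modes, 2L)
  expect_equal(unname(vapply(modes, modeFrequency, numeric(1))),
               c(664, 835))
  f <- readCube(bundle$cubes$mode2$plusRe, "real")
  expect_s4_class(f, "VolumetricField")
  g <- readXYZ(bundle$xyz)
  expect_equal(nrow(g$positions), 6L)
})
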