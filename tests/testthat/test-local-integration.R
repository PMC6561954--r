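test_that("effective density is the F^2-weighted density", {
  rd <- ringDensity("antisymmetric_oop")
  g <- fieldGrid(rd)
  ## near-uniform field leaves the density essentially unchanged
  wide <- NearField(fwhm = 1e6, center = c(0, 0, 0))
  eff <- effectiveDensity(rd, wide)
  expect_equal(fieldValues(eff), fieldValues(rd), tolerance = 1e-5)
  ## matches the explicit product voxel by voxel
  nf <- NearField(fwhm = 1.3, center = c(2.5, 0, 1))
  w <- sampleOnGrid(nf, g)
  expect_equal(fieldValues(effectiveDensity(rd, nf)),
               fieldValues(rd) * as.numeric(w * w), tolerance = 1e-14)
})

test_that("local polarizability equals the exhaustive voxel sum", {
  mol <- buildRing(4, 1.5, "antisymmetric_oop")
  g <- GridSpec(origin = c(-3, -3, -2), step = c(0.5, 0.5, 0.4),
                counts = c(13L, 13L, 11L))
  rd <- rasterizeDensity(mol, g)
  nf <- NearField(fwhm = c(1.3, 1.7, 1.1), center = c(0.9, -0.3, 1))
  brute <- 0 + 0i
  vals <- fieldValues(rd)
  for (i in seq_len(13)) for (j in seq_len(13)) for (k in seq_len(11)) {
    p <- c(axisCoords(g, 1)[i], axisCoords(g, 2)[j], axisCoords(g, 3)[k])
    f <- evaluateNearField(nf, p)
    brute <- brute + vals[i, j, k] * f * f
  }
  brute <- brute * voxelVolume(g)
  expect_equal(localPolarizability(rd, nf), brute, tolerance = 1e-12)
})

test_that("a symmetric field on the symmetry plane gives zero polarizability", {
  rd <- ringDensity("antisymmetric_oop")
  ## plane-symmetric profile centred in the molecular plane: the odd density
  ## integrates to zero — the symmetry-breaking mechanism run in reverse
  nf <- NearField(fwhm = 2, center = c(0, 0, 0))
  scale <- sum(Mod(fieldValues(rd))) * voxelVolume(fieldGrid(rd))
  expect_lt(Mod(localPolarizability(rd, nf)), 1e-10 * scale)
})

test_that("off-centre field activates the mode, matching a refined oracle", {
  mol <- buildRing(6, 2.5, "antisymmetric_oop")
  nf <- NearField(fwhm = 1.3, center = c(2.5, 0, 1))
  coarse <- GridSpec(origin = c(-4.5, -4.5, -2), step = c(0.3, 0.3, 0.1),
                     counts = c(31L, 31L, 41L))
  fine <- GridSpec(origin = c(-4.5, -4.5, -2),
                   step = c(0.075, 0.075, 0.025),
                   counts = c(121L, 121L, 161L))
  aC <- localPolarizability(rasterizeDensity(mol, coarse), nf)
  aF <- localPolarizability(rasterizeDensity(mol, fine), nf)
  expect_gt(Mod(aC), 0)
  expect_equal(Re(aC), Re(aF), tolerance = 0.01)
})

test_that("far field equals the uniform-field local polarizability", {
  rd <- ringDensity("symmetric_oop")
  wide <- NearField(fwhm = 1e6, center = c(0, 0, 0))
  expect_equal(localPolarizability(rd, wide), farField(rd),
               tolerance = 1e-4)
  ## all-positive lobe: positive real far field
  g <- smallGrid(n = 11L, step = 0.4)
  r2 <- rowSums(gridCoordinates(g)^2)
  pos <- VolumetricField(g, exp(-r2))
  expect_gt(Re(farField(pos)), 0)
  expect_equal(Im(farField(pos)), 0)
})

test_that("intensity is |alpha|^2 with quadratic scaling", {
  rd <- ringDensity("antisymmetric_oop")
  nf <- NearField(fwhm = 1.3, center = c(2.5, 0, 1))
  zero <- RamanDensity(VolumetricField(fieldGrid(rd), 0), densityMode(rd))
  expect_identical(tersIntensity(zero, nf), 0)

  i1 <- tersIntensity(rd, nf)
  scaled <- rd; scaled@values <- (2 - 1i) * rd@values
  expect_equal(tersIntensity(scaled, nf), Mod(2 - 1i)^2 * i1,
               tolerance = 1e-12)

  ## purely imaginary polarizability: intensity is the squared magnitude
  a <- localPolarizability(rd, nf)
  imag <- rd; imag@values <- 1i * rd@values
  expect_equal(tersIntensity(imag, nf), Mod(a)^2, tolerance = 1e-12)
})

test_that("tip scans match brute-force pixel evaluation", {
  mol <- buildRing(4, 1.5, "antisymmetric_oop")
  g <- GridSpec(origin = c(-3, -3, -1.6), step = c(0.4, 0.4, 0.4),
                counts = c(16L, 16L, 9L))
  rd <- rasterizeDensity(mol, g)
  plan <- ScanPlan(c(-1, 1), c(-1, 1), step = 0.5, height = 1,
                   field = NearField(fwhm = 1.3))
  img <- scanImage(rd, plan)
  co <- imageCoords(img)
  vox <- voxelVolume(g)
  vals <- fieldValues(rd)
  cx <- axisCoords(g, 1); cy <- axisCoords(g, 2); cz <- axisCoords(g, 3)
  ref <- matrix(0, length(co$x), length(co$y))
  for (i in seq_along(co$x)) for (j in seq_along(co$y)) {
    nf <- NearField(fwhm = 1.3, center = c(co$x[i], co$y[j], 1))
    acc <- 0 + 0i
    for (ix in seq_along(cx)) for (iy in seq_along(cy))
      for (iz in seq_along(cz)) {
        f <- evaluateNearField(nf, c(cx[ix], cy[iy], cz[iz]))
        acc <- acc + vals[ix, iy, iz] * f * f
      }
    ref[i, j] <- Mod(acc * vox)^2
  }
  expect_lt(max(abs(imageIntensities(img) - ref)) / max(ref), 1e-10)
})

test_that("images are non-negative and scale quartically with the density", {
  rd <- ringDensity("antisymmetric_oop")
  plan <- ScanPlan(c(-3, 3), c(-3, 3), step = 1, height = 1,
                   field = NearField(fwhm = 1.3))
  img <- scanImage(rd, plan)
  expect_true(all(imageIntensities(img) >= 0))
  scaled <- rd; scaled@values <- 3 * rd@values
  img9 <- scanImage(scaled, plan)
  expect_equal(imageIntensities(img9), 9 * imageIntensities(img),
               tolerance = 1e-12)
})

test_that("scans are translation-equivariant", {
  shift <- c(1, 1, 0)
  mol <- buildRing(6, 2.5, "antisymmetric_oop")
  g <- boundingGrid(mol@positions)
  rd <- rasterizeDensity(mol, g)
  molS <- mol; molS@positions <- sweep(mol@positions, 2, -shift)
  gS <- GridSpec(gridOrigin(g) + shift, gridStep(g), gridCounts(g))
  rdS <- rasterizeDensity(molS, gS)
  plan <- ScanPlan(c(-2, 2), c(-2, 2), step = 0.5, height = 1,
                   field = NearField(fwhm = 1.3))
  planS <- ScanPlan(c(-2, 2) + shift[1], c(-2, 2) + shift[2], step = 0.5,
                    height = 1, field = NearField(fwhm = 1.3))
  expect_equal(imageIntensities(scanImage(rdS, planS)),
               imageIntensities(scanImage(rd, plan)), tolerance = 1e-10)
})

test_that("C2-symmetric densities give C2-symmetric images", {
  ## 4-ring with alternating signs: C2 rotation about z maps the density
  ## onto itself
  mol <- buildRing(4, 2, "antisymmetric_oop")
  half <- 10L * 0.3
  g <- GridSpec(origin = c(-half, -half, -1.5),
                step = c(0.3, 0.3, 0.15),
                counts = c(21L, 21L, 21L))
  rd <- rasterizeDensity(mol, g)
  plan <- ScanPlan(c(-2, 2), c(-2, 2), step = 0.4, height = 1,
                   field = NearField(fwhm = 1.3))
  I <- imageIntensities(scanImage(rd, plan))
  rot <- I[rev(seq_len(nrow(I))), rev(seq_len(ncol(I)))]
  expect_equal(I, rot, tolerance = 1e-8)
})

test_that("the uniform-field limit reproduces |far field|^2 per pixel", {
  ## a density with non-zero far field, so the relative limit is meaningful
  g <- smallGrid(n = 13L, step = 0.4)
  co <- gridCoordinates(g)
  blob <- VolumetricField(g, complex(real = exp(-rowSums(co^2)),
                                     imaginary = 0.3 * exp(-rowSums(co^2))))
  plan <- ScanPlan(c(-2, 2), c(-2, 2), step = 1, height = 1,
                   field = NearField(fwhm = 1e6))
  img <- scanImage(blob, plan)
  target <- Mod(farField(blob))^2
  expect_gt(target, 0)
  expect_equal(as.numeric(imageIntensities(img)),
               rep(target, length(imageIntensities(img))),
               tolerance = 1e-4)
})

test_that("shrinking the FWHM sharpens the image (entropy decreases)", {
  rd <- ringDensity("antisymmetric_oop")
  ent <- vapply(c(4, 2.5, 1.3), function(w) {
    plan <- ScanPlan(c(-4, 4), c(-4, 4), step = 0.4, height = 1,
                     field = NearField(fwhm = w))
    imageEntropy(scanImage(rd, plan))
  }, numeric(1))
  expect_true(all(diff(ent) < 0))
})

test_that("a scan window fully outside the grid warns and is near zero", {
  rd <- ringDensity("antisymmetric_oop")
  plan <- ScanPlan(c(50, 52), c(50, 52), step = 1, height = 1,
                   field = NearField(fwhm = 1.3))
  expect_warning(img <- scanImage(rd, plan), "outside")
  expect_lt(max(imageIntensities(img)),
            1e-6 * max(imageIntensities(
              scanImage(rd, ScanPlan(c(-3, 3), c(-3, 3), step = 1,
                                     height = 1,
                                     field = NearField(fwhm = 1.3))))))
})

test_that("multi-mode scans return one image per mode on a shared grid", {
  g <- boundingGrid(buildRing(6, 2.5, "symmetric_oop")@positions)
  rds <- list(rasterizeDensity(buildRing(6, 2.5, "symmetric_oop"), g),
              rasterizeDensity(buildRing(6, 2.5, "antisymmetric_oop"), g))
  plan <- ScanPlan(c(-2, 2), c(-2, 2), step = 1, height = 1,
                   field = NearField(fwhm = 1.3))
  imgs <- scanImage(rds, plan)
  expect_length(imgs, 2L)
  expect_equal(imageProvenance(imgs[[2L]])$frequencies, 835)
  other <- rasterizeDensity(buildRing(6, 2.5, "inplane"),
                            GridSpec(step = 0.5, counts = 11L))
  expect_error(scanImage(list(rds[[1L]], other), plan), "share")
})
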