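## Shared fixtures, built in code. Rasterized densities are cached per run.

.fixtureCache <- new.env(parent = emptyenv())

cachedDensity <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

## 6-atom ring densities on the default grid conventions
ringDensity <- function(mode = "antisymmetric_oop", ...) {
  key <- paste0("ring-", mode, "-", paste(c(...), collapse = "-"))
  cachedDensity(key, function()
    rasterizeDensity(buildRing(6, 2.5, mode, ...)))
}

## a small plane-symmetric grid around the origin (odd z count so z = 0 is
## a voxel plane)
smallGrid <- function(n = 13L, step = 0.5) {
  half <- (n - 1L) / 2
  GridSpec(origin = -half * rep(step, 3), step = step, counts = n)
}

## deterministic pseudo-random complex field for linearity/property tests
randomField <- function(grid, seed = 1L) {
  set.seed(seed)
  n <- prod(gridCounts(grid))
  VolumetricField(grid, complex(real = stats::rnorm(n),
                                imaginary = stats::rnorm(n)))
}

## Shannon entropy of a normalized intensity map (sharpness measure)
imageEntropy <- function(img) {
  p <- imageIntensities(img)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

## pixel closest to scan coordinates (x0, y0)
pixelAt <- function(img, x0, y0) {
  co <- imageCoords(img)
  imageIntensities(img)[which.min(abs(co$x - x0)),
                        which.min(abs(co$y - y0))]
}
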