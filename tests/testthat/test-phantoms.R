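test_that("phantom metrics are exact on analytic maps", {
  ## uniform slab
  t0 <- matrix(0, 40, 40)
  t0[11:20, 11:20] <- 700
  m <- phantomMetrics(t0, 38)
  expect_equal(m$volume, 100 * 38^2 * 700 / 1e9)
  expect_equal(m$maxThickness, 0.7)
  expect_equal(m$meanThickness, 0.7)
  ## discretized sphere: volume within 1 percent of 4/3 pi r^3
  n <- 80; r <- 30
  x <- seq_len(n) - (n + 1) / 2
  q <- r^2 - outer(x^2, x^2, "+")
  ts <- 2 * sqrt(pmax(q, 0))   # in pixels
  ms <- phantomMetrics(ts * 38, 38)
  expect_equal(ms$volume, 4 / 3 * pi * (r * 38)^3 / 1e9, tolerance = 1e-2)
  ## empty map
  me <- phantomMetrics(matrix(0, 8, 8), 38)
  expect_equal(me$volume, 0)
  expect_true(is.na(me$meanThickness))
})

test_that("metrics are invariant under grid translation", {
  t0 <- matrix(0, 64, 64); t0[21:30, 21:30] <- 500
  t1 <- matrix(0, 64, 64); t1[41:50, 5:14] <- 500
  expect_equal(phantomMetrics(t0, 38), phantomMetrics(t1, 38))
})

test_that("generated particle phantom reproduces the printed metrics", {
  ph <- makeParticlePhantom(phantomSpec2D(seed = 1))
  m <- ph$metrics
  expect_lt(abs(m$volume / 19.8 - 1), 0.02)
  expect_lt(abs(m$maxThickness / 3.8 - 1), 0.02)
  expect_lt(abs(m$meanThickness / 1.2 - 1), 0.02)
  expect_true(all(ph$thickness >= 0))
  ## zero outside a central support
  expect_equal(ph$thickness[1, ], rep(0, 140))
  expect_equal(ph$thickness[, 140], rep(0, 140))
})

test_that("phantom generation is deterministic per seed", {
  a <- makeParticlePhantom(phantomSpec2D(seed = 7))
  b <- makeParticlePhantom(phantomSpec2D(seed = 7))
  expect_identical(a$thickness, b$thickness)
  c2 <- makeParticlePhantom(phantomSpec2D(seed = 8))
  expect_gt(max(abs(a$thickness - c2$thickness)), 1)
  ## different seeds still match the metrics
  expect_lt(abs(c2$metrics$volume / 19.8 - 1), 0.02)
  ## seeding does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makeParticlePhantom(phantomSpec2D(seed = 3)))
  expect_identical(runif(1), before)
})

test_that("infeasible phantom specs are rejected", {
  expect_error(phantomSpec2D(meanThickness = 4, maxThickness = 3.8))
  expect_error(makeParticlePhantom(phantomSpec2D(grid = 40L)), "grid")
})

test_that("3-D tomo phantom places labeled particles of the right volume", {
  pv <- makeTomoPhantom(nParticles = 3, particleVolume = 1.2,
                        densityContrast = 20, cylinderRadius = 2200,
                        voxel = 40, dims = c(128L, 128L, 128L), seed = 5)
  lab <- labels(pv)
  expect_equal(max(lab), 3)
  vols <- tabulate(lab[lab > 0]) * 40^3 / 1e9
  expect_true(all(abs(vols / 1.2 - 1) < 0.02))
  ## density structure: background + contrast inside particles
  d <- densityMap(pv)
  expect_equal(unique(d[lab > 0]), 310.25 + 20)
  expect_equal(max(d), 330.25)
  ## reproducibility and the empty case
  pv2 <- makeTomoPhantom(nParticles = 3, particleVolume = 1.2,
                         densityContrast = 20, cylinderRadius = 2200,
                         voxel = 40, dims = c(128L, 128L, 128L), seed = 5)
  expect_identical(densityMap(pv), densityMap(pv2))
  pv0 <- makeTomoPhantom(nParticles = 0, dims = c(32L, 32L, 32L),
                         cylinderRadius = 500, voxel = 40)
  expect_equal(max(labels(pv0)), 0)
  expect_equal(sort(unique(as.numeric(densityMap(pv0)))), c(0, 310.25))
})

test_that("impossible particle packings fail with guidance", {
  expect_error(
    makeTomoPhantom(nParticles = 20, particleVolume = 4,
                    cylinderRadius = 1200, voxel = 40,
                    dims = c(64L, 64L, 64L), seed = 1, maxTries = 20),
    "fewer or smaller")
})

test_that("volume projections feed the hologram simulation consistently", {
  ## a homogeneous phantom volume projected along the beam equals a
  ## thickness map scaled by the density; both simulation paths agree
  pv <- makeTomoPhantom(nParticles = 0, cylinderRadius = 900, voxel = 40,
                        dims = c(64L, 64L, 64L), backgroundDensity = 310.25)
  sg <- projectVolume(pv, 0)
  D <- matrix(sg@data[1, , ], 64, 64)
  thick <- D / 310.25
  oc <- opticalConstants(deltaFromDensity(310.25, 0.165), 5.5e-9, 0.165)
  h1 <- simulateHologram(thick, oc, 0.165, 5e-3, padTo = 128)
  h2 <- simulateHologramFromProjection(D, 0.165, 5e-3, cprime(oc),
                                       padTo = 128)
  expect_equal(intensity(h1), intensity(h2), tolerance = 1e-9)
})
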