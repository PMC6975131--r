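test_that("angular interpolation inserts exact linear midpoints", {
  d <- array(0, c(2, 1, 4))
  d[1, 1, ] <- c(1, 2, 3, 4)
  d[2, 1, ] <- c(3, 6, 9, 12)
  st <- sinogramStack(d, c(0, 90), 38)
  out <- angularInterpolate(st, 2L)
  expect_equal(angles(out), c(0, 45, 90))
  expect_equal(out@data[2, 1, ], c(2, 4, 6, 8))
  expect_equal(out@data[1, 1, ], d[1, 1, ])   # originals preserved
  expect_equal(out@data[3, 1, ], d[2, 1, ])
  ## factor 1 is the identity; constant stacks stay constant
  expect_identical(angularInterpolate(st, 1L), st)
  cst <- sinogramStack(array(5, c(3, 2, 4)), c(0, 60, 120), 38)
  expect_equal(unique(as.numeric(angularInterpolate(cst, 3L)@data)), 5)
  expect_equal(length(angles(angularInterpolate(cst, 3L))), 3 * 2 + 1)
  expect_error(angularInterpolate(st, 0L), "factor")
})

test_that("truncation padding repeats the outermost pixels", {
  d <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  st <- sinogramStack(d, c(0, 90), 38)
  out <- extendTruncated(st, 4L)
  expect_equal(dim(out@data)[3], 5 + 8)
  expect_equal(out@data[, , 5:9], d)                     # interior identical
  for (p in 1:4) {
    expect_equal(out@data[, , p], d[, , 1])
    expect_equal(out@data[, , 9 + p], d[, , 5])
  }
  expect_identical(extendTruncated(st, 0L), st)
})

test_that("wavelet-Fourier filter removes stripes but spares structure", {
  set.seed(5)
  nA <- 200; ns <- 128
  m <- matrix(rnorm(nA * ns, 100, 5), nA, ns)
  clean <- sinogramStack(array(m, c(nA, 1, ns)),
                         seq(0, 179, length.out = nA), 38)
  f1 <- removeRingsWavelet(clean)
  expect_equal(dim(f1@data), dim(clean@data))
  ## selectivity: a stripe-free sinogram passes nearly unchanged
  expect_lt(sqrt(sum((f1@data - clean@data)^2) / sum(clean@data^2)), 0.01)
  ## a constant column offset (ring artifact) is damped by >= 10x
  stripeAmp <- 40
  ms <- m; ms[, 60] <- ms[, 60] + stripeAmp
  fs <- removeRingsWavelet(sinogramStack(array(ms, c(nA, 1, ns)),
                                         seq(0, 179, length.out = nA), 38))
  residual <- mean(fs@data[, 1, 60] - f1@data[, 1, 60])
  expect_lt(abs(residual), stripeAmp / 10)
  expect_error(removeRingsWavelet(clean, wavelet = "nope"), "supported")
})

test_that("FBP recovers an analytic uniform disk within 1 percent", {
  n <- 128; vox <- 40; rho0 <- 300; rad <- 40 * vox
  nA <- 400
  ang <- seq(0, 180, length.out = nA + 1)[seq_len(nA)]
  s <- (seq_len(n) - (n + 1) / 2) * vox
  p <- 2 * rho0 * sqrt(pmax(0, rad^2 - s^2))
  dat <- array(0, c(nA, 1, n))
  for (a in seq_len(nA)) dat[a, 1, ] <- p
  vol <- fbpReconstruct(sinogramStack(dat, ang, vox), "ramp")
  d <- densityMap(vol)[, , 1]
  rr <- sqrt(outer(s^2, s^2, "+"))
  expect_equal(mean(d[rr < 0.8 * rad]), rho0, tolerance = 1e-2)
  expect_lt(mean(abs(d[rr > 1.3 * rad])), 0.05 * rho0)
  ## zero sinogram reconstructs to zero
  z <- fbpReconstruct(sinogramStack(dat * 0, ang, vox))
  expect_equal(max(abs(densityMap(z))), 0)
  expect_error(fbpReconstruct(sinogramStack(dat[1, , , drop = FALSE],
                                            0, vox)), "angles")
})

test_that("forward projection and FBP localize a point source", {
  dens <- array(0, c(64, 64, 3)); dens[40, 25, 2] <- 500
  sg <- projectVolume(volumeMap(dens, 40), seq(0, 179.1, length.out = 180))
  d2 <- densityMap(fbpReconstruct(sg))[, , 2]
  expect_equal(as.integer(which(d2 == max(d2), arr.ind = TRUE)),
               c(40L, 25L))
})

test_that("edge extension reduces cupping in truncated reconstructions", {
  ## wide disk, narrow detector: classic region-of-interest truncation
  vox <- 40; rho0 <- 300; rad <- 90 * vox; n <- 128
  nA <- 300
  ang <- seq(0, 180, length.out = nA + 1)[seq_len(nA)]
  s <- (seq_len(n) - (n + 1) / 2) * vox
  p <- 2 * rho0 * sqrt(pmax(0, rad^2 - s^2))   # truncated: disk wider
  dat <- array(0, c(nA, 1, n))
  for (a in seq_len(nA)) dat[a, 1, ] <- p
  st <- sinogramStack(dat, ang, vox)
  flatness <- function(pad) {
    v <- fbpReconstruct(if (pad > 0) extendTruncated(st, pad) else st)
    d <- densityMap(v)[, , 1]
    nn <- nrow(d); c0 <- (nn - n) %/% 2
    d <- d[c0 + seq_len(n), c0 + seq_len(n)]
    rr <- sqrt(outer(s^2, s^2, "+"))
    sd(d[rr < 0.5 * n / 2 * vox])   # interior flatness
  }
  expect_lt(flatness(96L), flatness(0L))
})

test_that("mean shift is an idempotent pure offset", {
  set.seed(1)
  v <- volumeMap(array(rnorm(8^3, 300, 4), c(8, 8, 8)), 40)
  s1 <- shiftMean(v, 310.25)
  expect_equal(mean(densityMap(s1)), 310.25)
  expect_equal(sd(densityMap(s1)), sd(densityMap(v)), tolerance = 1e-13)
  expect_equal(densityMap(shiftMean(s1, 310.25)), densityMap(s1))
})

test_that("intensity projections take slab extremes", {
  a <- array(0, c(4, 4, 12))
  a[2, 3, 6] <- 9; a[2, 3, 2] <- 99
  v <- volumeMap(a + 1, 40)
  mp <- intensityProjection(v, depth = 11, mode = "max", start = 2)
  expect_equal(mp[2, 3], 100)
  expect_true(all(mp >= intensityProjection(v, depth = 11, mode = "min",
                                            start = 2)))
  ## depth 1 returns the slice itself
  expect_equal(intensityProjection(v, depth = 1, start = 6),
               a[, , 6] + 1)
  ## constant volume gives a constant image
  cv <- volumeMap(array(7, c(4, 4, 4)), 40)
  expect_equal(unique(as.numeric(intensityProjection(cv, depth = 3))), 7)
  expect_error(intensityProjection(v, depth = 13), "depth")
  expect_error(intensityProjection(v, depth = 4, start = 11), "outside")
})
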