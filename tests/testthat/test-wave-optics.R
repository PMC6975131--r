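test_that("exit wave of trivial objects", {
  oc <- opticalConstants(4e-6, 1e-8, 0.165)
  z <- matrix(0, 8, 8)
  expect_equal(exitWave(z, oc, 0.165)@values, matrix(1 + 0i, 8, 8))
  t0 <- matrix(runif(64) * 1000, 8, 8)
  ## pure phase object has unit modulus
  pure <- opticalConstants(4e-6, 0, 0.165)
  expect_equal(Mod(exitWave(t0, pure, 0.165)@values), matrix(1, 8, 8),
               tolerance = 1e-14)
  ## absorption only attenuates
  expect_true(all(Mod(exitWave(t0, oc, 0.165)@values) <= 1))
  expect_error(exitWave(-t0, oc, 0.165), "non-negative")
})

test_that("Fresnel propagation is unitary and invertible", {
  set.seed(42)
  v <- matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)),
              64, 64)
  fl <- new("ComplexField", values = v, pixelEff = 38, wavelength = 0.165)
  p <- fresnelPropagate(fl, 3e-4)
  expect_lt(abs(sum(Mod(p@values)^2) / sum(Mod(v)^2) - 1), 1e-10)
  back <- fresnelPropagate(p, 3e-4, conjugate = TRUE)
  expect_lt(max(Mod(back@values - v)), 1e-10)
  ## plane wave is invariant
  u <- new("ComplexField", values = matrix(1 + 0i, 32, 32), pixelEff = 38,
           wavelength = 0.165)
  expect_equal(fresnelPropagate(u, 1e-3)@values, u@values,
               tolerance = 1e-12)
})

test_that("propagation kernels are additive in 1/F", {
  set.seed(7)
  v <- matrix(complex(real = rnorm(32^2), imaginary = rnorm(32^2)), 32, 32)
  fl <- new("ComplexField", values = v, pixelEff = 38, wavelength = 0.165)
  F1 <- 2e-3; F2 <- 5e-3
  Fc <- 1 / (1 / F1 + 1 / F2)
  two <- fresnelPropagate(fresnelPropagate(fl, F1), F2)
  one <- fresnelPropagate(fl, Fc)
  expect_equal(two@values, one@values, tolerance = 1e-12)
})

test_that("a Gaussian beam spreads by the analytic width", {
  n <- 256; w0 <- 6; Fr <- 6e-3
  x <- seq_len(n) - (n / 2 + 0.5)
  r2 <- outer(x^2, x^2, "+")
  fl <- new("ComplexField",
            values = matrix(complex(real = exp(-r2 / w0^2)), n, n),
            pixelEff = 1, wavelength = 0.1)
  p <- fresnelPropagate(fl, Fr)
  I <- Mod(p@values)^2
  ## beam waist from the intensity second moment: sigma^2 = w^2 / 4
  sig2 <- sum(I * outer(x^2, rep(1, n))) / sum(I)
  wMeas <- 2 * sqrt(sig2)
  wTheory <- w0 * sqrt(1 + (1 / (Fr * pi * w0^2))^2)
  expect_equal(wMeas, wTheory, tolerance = 1e-2)
})

test_that("simulated holograms behave like flat-field corrected data", {
  oc <- opticalConstants(4e-6, 1e-8, 0.165)
  ## empty phantom gives a unit hologram
  h0 <- simulateHologram(matrix(0, 16, 16), oc, 0.165, 3e-3, padTo = 64)
  expect_equal(intensity(h0), matrix(1, 64, 64), tolerance = 1e-12)
  expect_error(simulateHologram(matrix(0, 70, 70), oc, 0.165, 3e-3,
                                padTo = 64), "pad")
  ## pure phase object conserves total intensity exactly
  t0 <- smoothDensityMap(32, amplitude = 800)
  hp <- simulateHologram(t0, opticalConstants(4e-6, 0, 0.165), 0.165,
                         4e-3, padTo = 256)
  expect_lt(abs(mean(intensity(hp)) - 1), 1e-12)
  ## weak absorption keeps the padded-grid mean near 1
  ha <- simulateHologram(t0, oc, 0.165, 4e-3, padTo = 256)
  expect_lt(abs(mean(intensity(ha)) - 1), 1e-3)
})

test_that("full propagation converges to the linear model as O(s^2)", {
  bc <- bloodConstants()
  lam <- energyToWavelength(7.5)
  Fr <- 4e-3
  t0 <- smoothDensityMap(48, amplitude = 2500)  # thickness map, nm
  holos <- function(s) {
    hFull <- simulateHologram(s * t0, bc$constants, lam, Fr, padTo = 256)
    D <- bc$electronDensity * s * t0
    Dp <- matrix(0, 256, 256)
    Dp[105:152, 105:152] <- D
    hLin <- linearHologramModel(Dp, lam, Fr, bc$cprime)
    list(full = intensity(hFull), lin = intensity(hLin))
  }
  ## weak object (peak phase ~0.1 rad): linear model within 5 percent
  hw <- holos(0.2)
  expect_lt(sqrt(sum((hw$full - hw$lin)^2) / sum((hw$lin - 1)^2)), 0.05)
  ## absolute L2 distance decays quadratically with object strength
  errAbs <- function(s) { h <- holos(s); sqrt(sum((h$full - h$lin)^2)) }
  e1 <- errAbs(1); e2 <- errAbs(0.5); e3 <- errAbs(0.25)
  expect_lt(e2, 0.30 * e1)      # ratio 0.25 for a pure s^2 law
  expect_lt(e3, 0.30 * e2)
})

test_that("thickness and projected-density simulations agree exactly", {
  ## for a homogeneous material, exp(-ik(delta - i beta) t) equals
  ## exp(-(i lambda + lambda^3 C') r0 D) with D = rho_e t
  bc <- bloodConstants()
  lam <- energyToWavelength(6.5)
  t0 <- smoothDensityMap(32, amplitude = 1800)
  h1 <- simulateHologram(t0, bc$constants, lam, 4e-3, padTo = 128)
  h2 <- simulateHologramFromProjection(bc$electronDensity * t0, lam, 4e-3,
                                       bc$cprime, padTo = 128)
  expect_equal(intensity(h1), intensity(h2), tolerance = 1e-9)
})

test_that("linear model trivial cases", {
  h <- linearHologramModel(matrix(0, 32, 32), 0.165, 3e-3, 0.13)
  expect_equal(intensity(h), matrix(1, 32, 32))
  ## real output for real input
  D <- smoothDensityMap(32)
  expect_true(is.numeric(intensity(linearHologramModel(D, 0.165, 3e-3, 0.13))))
})

test_that("Poisson noise stage is seeded and off by default", {
  oc <- opticalConstants(4e-6, 1e-8, 0.165)
  t0 <- smoothDensityMap(16, amplitude = 500)
  set.seed(99)
  h1 <- simulateHologram(t0, oc, 0.165, 4e-3, padTo = 64, photons = 1e4)
  set.seed(99)
  h2 <- simulateHologram(t0, oc, 0.165, 4e-3, padTo = 64, photons = 1e4)
  expect_identical(intensity(h1), intensity(h2))
  expect_gt(sd(intensity(h1) - intensity(
    simulateHologram(t0, oc, 0.165, 4e-3, padTo = 64))), 0)
})
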