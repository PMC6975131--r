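test_that("CTF kernel values and roots", {
  lam <- 0.165; cp <- 0.1326
  fq <- freqGridSq(64)
  k <- ctfKernel(lam, 3e-4, cp, fq)
  ## DC value lambda^3 C'
  expect_equal(k[1, 1], lam^3 * cp)
  ## with C' = 0 the kernel vanishes exactly at chi = m pi
  Fr <- 3e-4
  nuZero <- sqrt(2 * Fr)              # chi = pi (nu^2 / F) = 2 pi... m = 2
  chi <- chirpPhase(fq, Fr)
  k0 <- ctfKernel(lam, Fr, 0, fq)
  nearZero <- abs(chi - pi) < 1e-6
  expect_true(all(abs(k0[abs(chi - pi) < 1e-3]) < lam * 1.1e-3))
  ## first root beyond DC satisfies tan(chi) = -lambda^2 C'
  kr <- function(chi) lam * sin(chi) + lam^3 * cp * cos(chi)
  root <- uniroot(kr, c(pi / 2 + 1e-6, pi), tol = 1e-12)$root
  expect_equal(tan(root), -lam^2 * cp, tolerance = 1e-8)
  expect_equal(root, pi - atan(lam^2 * cp), tolerance = 1e-8)
})

test_that("step regularization geometry", {
  cfg <- retrievalConfig(energies_keV = studyEnergies,
                         fresnelNumbers = studyFresnel, cprime = 0.1326)
  fq <- freqGridSq(128)
  a <- regularizationAlpha(fq, cfg)
  expect_equal(a[1, 1], 0)                    # zero at DC
  expect_equal(a[65, 65], 1e-4)               # amplitude at Nyquist
  ## rotational symmetry: depends on |nu| only
  nu <- sqrt(fq)
  expect_true(all(a[nu < 0.01] == 0 | nu[nu < 0.01] >= min(nu[a > 0])))
  expect_identical(a, t(a))
  ## the cut sits at the first maximum of the mean-channel kernel
  mc <- holoctf:::.meanChannel(cfg)
  nu1 <- sqrt(atan(1 / (mc$wavelength^2 * 0.1326)) * mc$fresnel / pi)
  expect_true(all(a[nu < nu1] == 0))
  expect_true(all(a[nu >= nu1] == 1e-4))
  ## smooth transition option stays within [0, amplitude] and is small at DC
  asmooth <- regularizationAlpha(fq, cfg, transition = 0.01)
  expect_true(all(asmooth >= 0 & asmooth <= 1e-4))
  expect_lt(asmooth[1, 1], 0.5e-4)
})

test_that("reconstruction of unit holograms is zero", {
  cfg <- retrievalConfig(energies_keV = 7.5, fresnelNumbers = 3e-4,
                         cprime = 0.13)
  h <- new("Hologram", intensity = matrix(1, 32, 32), wavelength = 0.165,
           fresnelNumber = 3e-4, pixelEff = 38)
  pm <- reconstructMultiE(h, cfg)
  expect_equal(densityMap(pm), matrix(0, 32, 32), tolerance = 1e-12)
})

test_that("single channel reduces to the classical CTF inversion", {
  bc <- bloodConstants()
  lam <- energyToWavelength(7)
  Fr <- 2.84e-4
  D <- smoothDensityMap(128)
  h <- linearHologramModel(D, lam, Fr, bc$cprime)
  cfg <- retrievalConfig(wavelengths_nm = lam, fresnelNumbers = Fr,
                         cprime = bc$cprime)
  pm <- reconstructMultiE(h, cfg)
  ## direct transcription of the single-hologram quotient
  fq <- freqGridSq(128)
  k <- ctfKernel(lam, Fr, bc$cprime, fq)
  alpha <- regularizationAlpha(fq, cfg)
  direct <- Re(stats::fft(-stats::fft(intensity(h) - 1) * k /
                          (2 * k^2 + alpha), inverse = TRUE)) / 128^2 /
    classicalElectronRadius()
  expect_equal(densityMap(pm), direct, tolerance = 1e-12)
})

test_that("multi-energy round trip on linear-model holograms", {
  bc <- bloodConstants()
  cfg <- retrievalConfig(energies_keV = studyEnergies,
                         fresnelNumbers = studyFresnel, cprime = bc$cprime)
  D <- matrix(0, 512, 512)
  D[187:326, 187:326] <- smoothDensityMap(140, amplitude = 4e5)
  hl <- lapply(seq_len(7), function(i)
    linearHologramModel(D, cfg@channels$wavelength[i],
                        cfg@channels$fresnelNumber[i], bc$cprime))
  rec <- reconstructMultiE(hl, cfg)
  relL2 <- sqrt(sum((densityMap(rec) - D)^2) / sum(D^2))
  expect_lt(relL2, 1e-3)
})

test_that("reconstruction is linear in the hologram contrast", {
  bc <- bloodConstants()
  lam <- energyToWavelength(c(7, 8))
  cfg <- retrievalConfig(wavelengths_nm = lam,
                         fresnelNumbers = c(2.84e-4, 3.24e-4),
                         cprime = bc$cprime)
  D <- smoothDensityMap(64)
  hl <- lapply(1:2, function(i)
    linearHologramModel(D, lam[i], cfg@channels$fresnelNumber[i],
                        bc$cprime))
  rec1 <- densityMap(reconstructMultiE(hl, cfg))
  a <- 0.37
  hlScaled <- lapply(hl, function(h)
    new("Hologram", intensity = a * (intensity(h) - 1) + 1,
        wavelength = wavelength(h), fresnelNumber = fresnelNumber(h),
        pixelEff = 38))
  rec2 <- densityMap(reconstructMultiE(hlScaled, cfg))
  expect_equal(rec2, a * rec1, tolerance = 1e-10)
})

test_that("multi-channel inversion beats the worst single channel", {
  bc <- bloodConstants()
  cfg <- retrievalConfig(energies_keV = studyEnergies,
                         fresnelNumbers = studyFresnel, cprime = bc$cprime)
  D <- matrix(0, 256, 256)
  D[59:198, 59:198] <- smoothDensityMap(140, amplitude = 4e5)
  hl <- lapply(seq_len(7), function(i)
    linearHologramModel(D, cfg@channels$wavelength[i],
                        cfg@channels$fresnelNumber[i], bc$cprime))
  err <- function(rec) sqrt(sum((densityMap(rec) - D)^2) / sum(D^2))
  eMulti <- err(reconstructMultiE(hl, cfg))
  eSingle <- vapply(seq_len(7), function(i) {
    ci <- retrievalConfig(wavelengths_nm = cfg@channels$wavelength[i],
                          fresnelNumbers = cfg@channels$fresnelNumber[i],
                          cprime = bc$cprime)
    err(reconstructMultiE(hl[[i]], ci))
  }, numeric(1))
  expect_lt(eMulti, max(eSingle))
  expect_lt(eMulti, min(eSingle) * 1.05)  # spectral coverage helps everywhere
})

test_that("shape and channel mismatches are rejected", {
  cfg <- retrievalConfig(energies_keV = c(7, 8),
                         fresnelNumbers = c(2.8e-4, 3.2e-4), cprime = 0.13)
  h1 <- new("Hologram", intensity = matrix(1, 16, 16), wavelength = 0.17,
            fresnelNumber = 2.8e-4, pixelEff = 38)
  h2 <- new("Hologram", intensity = matrix(1, 32, 32), wavelength = 0.155,
            fresnelNumber = 3.2e-4, pixelEff = 38)
  expect_error(reconstructMultiE(list(h1, h2), cfg), "share grid")
  expect_error(reconstructMultiE(list(h1), cfg), "mismatch")
})

test_that("density from projection handles windows and errors", {
  pm <- new("ProjectionMap", density = matrix(330 * 500, 64, 64),
            pixelEff = 38)
  thick <- matrix(500, 64, 64)
  out <- densityFromProjection(pm, thick, window = 10)
  expect_equal(out$meanDensity, 330)
  ## zero thickness inside the window errors
  hole <- thick; hole[30:34, 30:34] <- 0
  expect_error(densityFromProjection(pm, hole, window = 16), "zero")
  expect_error(densityFromProjection(pm, thick, window = 100), "window")
})
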