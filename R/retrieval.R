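## Multi-energy CTF inversion: kernels, step regularization, and the
## regularized Fourier quotient returning projected electron density.

#' Construct a retrieval configuration
#'
#' Channels may be given as photon energies (keV) or wavelengths (nm), with
#' one Fresnel number per channel.
#'
#' @param energies_keV photon energies in keV (alternative to
#'   \code{wavelengths_nm}).
#' @param fresnelNumbers per-pixel Fresnel numbers, one per channel.
#' @param cprime homogeneous-object coupling C' in 1/nm^2.
#' @param alphaAmplitude step-regularization amplitude (default 1e-4).
#' @param meanRule \code{"mean_energy"} (default) evaluates the mean channel
#'   at the arithmetic mean photon energy; \code{"mean_wavelength"} at the
#'   arithmetic mean wavelength.
#' @param wavelengths_nm wavelengths in nm (alternative to
#'   \code{energies_keV}).
#' @return a [RetrievalConfig-class].
#' @export
#' @examples
#' retrievalConfig(energies_keV = c(6, 7.5, 9),
#'                 fresnelNumbers = c(2.43e-4, 3.04e-4, 3.65e-4),
#'                 cprime = 0.1326)
retrievalConfig <- function(energies_keV = NULL, fresnelNumbers, cprime,
                            alphaAmplitude = 1e-4,
                            meanRule = c("mean_energy", "mean_wavelength"),
                            wavelengths_nm = NULL) {
  meanRule <- match.arg(meanRule)
  if (is.null(wavelengths_nm)) {
    if (is.null(energies_keV))
      stop("give either energies_keV or wavelengths_nm")
    wavelengths_nm <- energyToWavelength(energies_keV)
  }
  if (length(wavelengths_nm) != length(fresnelNumbers))
    stop("need one Fresnel number per channel (",
         length(wavelengths_nm), " wavelengths, ",
         length(fresnelNumbers), " Fresnel numbers)")
  new("RetrievalConfig",
      channels = data.frame(wavelength = wavelengths_nm,
                            fresnelNumber = fresnelNumbers),
      cprime = cprime, alphaAmplitude = alphaAmplitude, meanRule = meanRule)
}

## mean channel (wavelength, Fresnel number) under the configured rule.
## F is linear in photon energy at fixed geometry, so the arithmetic mean
## Fresnel number corresponds to the arithmetic mean energy.
.meanChannel <- function(config) {
  ch <- config@channels
  lbar <- if (config@meanRule == "mean_energy")
    energyToWavelength(mean(wavelengthToEnergy(ch$wavelength)))
  else mean(ch$wavelength)
  list(wavelength = lbar, fresnel = mean(ch$fresnelNumber))
}

#' CTF kernel of one channel
#'
#' \eqn{k(\nu) = \lambda\sin\chi + \lambda^3 C'\cos\chi} with
#' \eqn{\chi = \pi|\nu|^2/F}.  At DC the kernel equals \eqn{\lambda^3 C'},
#' so the absorption term keeps the lowest frequencies invertible.
#'
#' @param wavelength wavelength in nm.
#' @param fresnel per-pixel Fresnel number.
#' @param cprime coupling C' in 1/nm^2.
#' @param freqSq squared-frequency grid from [freqGridSq()].
#' @return real matrix of kernel values.
#' @export
ctfKernel <- function(wavelength, fresnel, cprime, freqSq) {
  chi <- chirpPhase(freqSq, fresnel)
  wavelength * sin(chi) + wavelength^3 * cprime * cos(chi)
}

#' Step regularization of the CTF quotient
#'
#' Radially symmetric, zero inside the first maximum of the mean-channel
#' CTF and equal to \code{amplitude} outside (a hard step whose inner hole
#' has full width equal to the distance between the first two symmetric CTF
#' maxima).  The first maximum sits at
#' \eqn{\chi_1 = \arctan(1/(\bar\lambda^2 C'))}, i.e.
#' \eqn{\nu_1 = \sqrt{\chi_1 \bar F / \pi}}.  An optional error-function
#' transition of width \code{transition} (in cycles/pixel) smooths the step;
#' the default is the hard step.
#'
#' @param freqSq squared-frequency grid from [freqGridSq()].
#' @param config a [RetrievalConfig-class].
#' @param transition if > 0, half-width of a smooth erf-like transition.
#' @return real matrix of regularization values.
#' @export
regularizationAlpha <- function(freqSq, config, transition = 0) {
  stopifnot(is(config, "RetrievalConfig"))
  mc <- .meanChannel(config)
  chi1 <- atan(1 / (mc$wavelength^2 * config@cprime))
  nu1 <- sqrt(chi1 * mc$fresnel / pi)
  nu <- sqrt(freqSq)
  if (transition > 0)
    config@alphaAmplitude * 0.5 * (1 + .erf((nu - nu1) / transition))
  else
    config@alphaAmplitude * (nu >= nu1)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Multi-energy CTF reconstruction of projected electron density
#'
#' Inverts a set of flat-field corrected holograms sharing one geometry but
#' recorded at different photon energies:
#' \deqn{r_0 D = \mathcal{F}^{-1}\left[
#'   \frac{-\sum_i \mathcal{F}[I_i - 1]\, k_i}
#'        {\sum_i 2 k_i^2 + \alpha}\right],}
#' with per-channel kernels \eqn{k_i} from [ctfKernel()] and the step
#' regularization \eqn{\alpha} from [regularizationAlpha()].  With a single
#' channel this reduces algebraically to the classical single-hologram CTF
#' inversion.  All kernels live on the shared frequency grid; no
#' registration or rescaling between channels is performed.
#'
#' The absolute offset of the result is only meaningful for untruncated
#' objects fully inside the field of view; truncated projections yield
#' relative values.
#'
#' @param holograms a [Hologram-class] or list of them, dimensions equal.
#' @param config a [RetrievalConfig-class] whose channels align one-to-one
#'   with \code{holograms}.
#' @param transition passed to [regularizationAlpha()].
#' @return a [ProjectionMap-class] in electrons/nm^2 (the classical
#'   electron radius is divided out).
#' @export
reconstructMultiE <- function(holograms, config, transition = 0) {
  if (is(holograms, "Hologram")) holograms <- list(holograms)
  stopifnot(length(holograms) >= 1L, is(config, "RetrievalConfig"))
  ch <- config@channels
  if (length(holograms) != nrow(ch))
    stop("channel/hologram count mismatch: ", nrow(ch), " channels, ",
         length(holograms), " holograms")
  dims <- dim(holograms[[1]]@intensity)
  px <- holograms[[1]]@pixelEff
  for (h in holograms) {
    stopifnot(is(h, "Hologram"))
    if (!identical(dim(h@intensity), dims))
      stop("holograms must share grid shape")
  }
  freqSq <- freqGridSq(dims[1], dims[2])
  num <- matrix(0i, dims[1], dims[2])
  den <- matrix(0, dims[1], dims[2])
  for (i in seq_along(holograms)) {
    k <- ctfKernel(ch$wavelength[i], ch$fresnelNumber[i], config@cprime,
                   freqSq)
    num <- num - .fft2(holograms[[i]]@intensity - 1) * k
    den <- den + 2 * k^2
  }
  alpha <- regularizationAlpha(freqSq, config, transition)
  D <- Re(.ifft2(num / (den + alpha))) / classicalElectronRadius()
  new("ProjectionMap", density = D, pixelEff = px)
}

#' Mean electron density from a projection and a known thickness
#'
#' Divides the retrieved projected electron density pixelwise by the known
#' projected thickness and averages over a centered square window (default
#' 40 x 40 pixels).  The thickness map may be smaller than the projection;
#' it is then taken as centered (as produced by [simulateHologram()]
#' padding) and the window refers to the common center.
#'
#' @param projection a [ProjectionMap-class] (electrons/nm^2).
#' @param thickness thickness map in nm.
#' @param window linear size of the centered evaluation window in pixels.
#' @return list with \code{meanDensity} (electrons/nm^3), \code{window}
#'   (the window size actually used) and \code{densityMap} (the windowed
#'   pixelwise ratio).
#' @export
densityFromProjection <- function(projection, thickness, window = 40L) {
  stopifnot(is(projection, "ProjectionMap"), is.matrix(thickness))
  D <- projection@density
  if (any(dim(thickness) > dim(D)))
    stop("thickness map larger than the projection")
  if (window > min(dim(thickness)))
    stop("window larger than the thickness map")
  Dw <- .cropCenter(D, window, window)
  tw <- .cropCenter(thickness, window, window)
  if (any(tw <= 0))
    stop("projected thickness is zero inside the evaluation window")
  ratio <- Dw / tw
  list(meanDensity = mean(ratio), window = as.integer(window),
       densityMap = ratio)
}
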