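## Exit-wave construction, paraxial Fresnel propagation, hologram simulation,
## and the linearized CTF forward model.

#' Exit wave of a single-material object
#'
#' For a thickness map t (nm per pixel) of a homogeneous material the
#' transmission function is
#' \eqn{\tau = \exp(-i k \delta(\lambda) t) \exp(-k \beta(\lambda) t)}
#' with \eqn{k = 2\pi/\lambda}; delta and beta are rescaled from the
#' reference wavelength with their \eqn{\lambda^2}/\eqn{\lambda^4} laws
#' before use.
#'
#' @param thickness matrix of projected thickness in nm (>= 0).
#' @param constants an [OpticalConstants-class].
#' @param wavelength wavelength in nm.
#' @param pixelEff pixel size in nm (carried as metadata, default NA).
#' @return a [ComplexField-class].
#' @export
exitWave <- function(thickness, constants, wavelength, pixelEff = NA_real_) {
  stopifnot(is.matrix(thickness), is(constants, "OpticalConstants"),
            wavelength > 0)
  if (any(thickness < 0)) stop("thickness must be non-negative")
  dl <- deltaRescaled(constants, wavelength)
  bl <- betaRescaled(constants, wavelength)
  k <- 2 * pi / wavelength
  ## exp(-k beta t) * exp(-i k delta t); arithmetic keeps matrix dims
  tau <- exp(-k * bl * thickness) * exp(-1i * (k * dl) * thickness)
  new("ComplexField", values = tau, pixelEff = as.numeric(pixelEff),
      wavelength = wavelength)
}

#' Paraxial Fresnel propagation
#'
#' Multiplies the field spectrum by \eqn{\exp(-i\chi)} with
#' \eqn{\chi = \pi|\nu|^2/F} (per-pixel Fresnel number F, frequencies in
#' cycles/pixel).  The physically irrelevant global phase
#' \eqn{\exp(ik\Delta)} is omitted.  Propagation with \code{conjugate =
#' TRUE} applies the inverse (back) propagator.
#'
#' @param field a [ComplexField-class].
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param conjugate propagate backwards if TRUE.
#' @return the propagated [ComplexField-class].
#' @export
fresnelPropagate <- function(field, fresnel, conjugate = FALSE) {
  stopifnot(is(field, "ComplexField"), fresnel > 0)
  chi <- chirpPhase(freqGridSq(nrow(field@values), ncol(field@values)),
                    fresnel)
  if (conjugate) chi <- -chi
  out <- .ifft2(.fft2(field@values) * exp(-1i * chi))
  new("ComplexField", values = out, pixelEff = field@pixelEff,
      wavelength = field@wavelength)
}

#' Simulate a flat-field corrected hologram
#'
#' Embeds the object thickness map centrally in a unit (empty-beam)
#' background of size \code{padTo}, builds the exit wave, Fresnel-propagates
#' it and records the squared modulus.  The output corresponds directly to a
#' flat-field divided recording.  An optional raised-cosine edge taper
#' and a seeded Poisson noise stage (photons per pixel) are available;
#' both are off by default since the reference simulation is noise free.
#'
#' @param thickness object thickness map in nm.
#' @param constants an [OpticalConstants-class].
#' @param wavelength wavelength in nm.
#' @param fresnel per-pixel Fresnel number.
#' @param padTo linear size of the padded grid (must be >= both object
#'   dimensions).  For the propagator to be adequately sampled choose
#'   \code{padTo >= 1/fresnel}.
#' @param pixelEff pixel size in nm (metadata).
#' @param taper width in pixels of an optional raised-cosine taper applied
#'   to the object edge region (0 disables; default 0).
#' @param photons if non-NULL, expected photons per pixel for a Poisson
#'   noise stage applied to the intensity.
#' @return a [Hologram-class] of size \code{padTo} x \code{padTo}.
#' @export
simulateHologram <- function(thickness, constants, wavelength, fresnel,
                             padTo = 4096, pixelEff = NA_real_,
                             taper = 0, photons = NULL) {
  stopifnot(is.matrix(thickness))
  if (padTo < max(dim(thickness)))
    stop("padTo (", padTo, ") smaller than the phantom grid (",
         paste(dim(thickness), collapse = "x"), ")")
  if (taper > 0) {
    w <- .cosineTaper(nrow(thickness), ncol(thickness), taper)
    thickness <- thickness * w
  }
  tpad <- .embed(thickness, padTo, padTo, fill = 0)
  tau <- exitWave(tpad, constants, wavelength, pixelEff)
  psi <- fresnelPropagate(tau, fresnel)
  I <- Mod(psi@values)^2
  if (!is.null(photons)) {
    stopifnot(photons > 0)
    I <- matrix(stats::rpois(length(I), I * photons) / photons,
                nrow(I), ncol(I))
  }
  new("Hologram", intensity = I, wavelength = wavelength,
      fresnelNumber = fresnel, pixelEff = as.numeric(pixelEff))
}

## raised-cosine window rolling the outermost `w` pixels down to zero
.cosineTaper <- function(nr, nc, w) {
  ramp <- function(n) {
    x <- rep(1, n)
    i <- seq_len(min(w, n))
    x[i] <- 0.5 * (1 - cos(pi * (i - 0.5) / w))
    x[n + 1 - i] <- x[i]
    x
  }
  outer(ramp(nr), ramp(nc))
}

#' Simulate a hologram from a projected electron density map
#'
#' Full (non-linearized) Fresnel simulation for a homogeneous object given
#' directly as projected electron density: the exit wave is
#' \eqn{\tau = \exp(-i\lambda r_0 D - \lambda^3 C' r_0 D)}, embedded in a
#' unit background, propagated and squared.  Used by the tomographic
#' synthetic loop where projections of a 3-D phantom stand in for thickness
#' maps.
#'
#' @param D projected electron density in electrons/nm^2.
#' @param wavelength wavelength in nm.
#' @param fresnel per-pixel Fresnel number.
#' @param cprime homogeneous-object coupling in 1/nm^2.
#' @param padTo linear size of the padded grid.
#' @param pixelEff pixel size in nm (metadata).
#' @return a [Hologram-class] of size \code{padTo} x \code{padTo}.
#' @export
simulateHologramFromProjection <- function(D, wavelength, fresnel, cprime,
                                           padTo = 2 * max(dim(D)),
                                           pixelEff = NA_real_) {
  stopifnot(is.matrix(D), wavelength > 0, fresnel > 0)
  if (padTo < max(dim(D)))
    stop("padTo smaller than the projection grid")
  Dr <- classicalElectronRadius() * .embed(D, padTo, padTo, fill = 0)
  tau <- exp(-(wavelength^3 * cprime) * Dr) * exp(-1i * wavelength * Dr)
  fld <- new("ComplexField", values = tau, pixelEff = as.numeric(pixelEff),
             wavelength = wavelength)
  psi <- fresnelPropagate(fld, fresnel)
  new("Hologram", intensity = Mod(psi@values)^2, wavelength = wavelength,
      fresnelNumber = fresnel, pixelEff = as.numeric(pixelEff))
}

#' Linearized CTF forward model
#'
#' First-order (weak, homogeneous object) hologram: in Fourier space
#' \deqn{\tilde I(\nu) = \delta(\nu) - 2 [\lambda\sin\chi +
#'   \lambda^3 C'\cos\chi]\, r_0\tilde D(\nu),}
#' the model the CTF inversion solves exactly.  Used as the test oracle for
#' the full Fresnel simulation and for round-trip checks of
#' [reconstructMultiE()].
#'
#' @param D projected electron density map in electrons/nm^2 (real matrix).
#' @param wavelength wavelength in nm.
#' @param fresnel per-pixel Fresnel number.
#' @param cprime homogeneous-object coupling in 1/nm^2.
#' @param pixelEff pixel size in nm (metadata).
#' @return a [Hologram-class] with the same dimensions as \code{D}.
#' @export
linearHologramModel <- function(D, wavelength, fresnel, cprime,
                                pixelEff = NA_real_) {
  stopifnot(is.matrix(D), is.numeric(D), wavelength > 0, fresnel > 0)
  chi <- chirpPhase(freqGridSq(nrow(D), ncol(D)), fresnel)
  kern <- wavelength * sin(chi) + wavelength^3 * cprime * cos(chi)
  Dr <- classicalElectronRadius() * D
  I <- 1 + Re(.ifft2(-2 * kern * .fft2(Dr)))
  I[I < 0] <- 0  # guard against tiny negative overshoot of the linear model
  new("Hologram", intensity = I, wavelength = wavelength,
      fresnelNumber = fresnel, pixelEff = as.numeric(pixelEff))
}
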