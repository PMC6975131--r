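## Cone-beam geometry and the Fresnel scaling theorem.

#' Construct a cone-beam geometry
#'
#' @param z01_mm source-to-sample distance in mm.
#' @param z12_mm sample-to-detector distance in mm.
#' @param pixelPitch_um physical detector pixel size in micrometers.
#' @return a [ConeBeamGeometry-class].
#' @export
#' @examples
#' coneBeamGeometry(30, 5090, 6.5)
coneBeamGeometry <- function(z01_mm, z12_mm, pixelPitch_um) {
  new("ConeBeamGeometry", z01 = as.numeric(z01_mm), z12 = as.numeric(z12_mm),
      pixelPitch = as.numeric(pixelPitch_um))
}

#' Effective parallel-beam geometry
#'
#' By the Fresnel scaling theorem a magnified cone-beam hologram equals a
#' parallel-beam hologram at the effective propagation distance
#' \eqn{z_{eff} = z_{12}/M} sampled with the demagnified pixel
#' \eqn{d_{eff} = d/M}, where \eqn{M = (z_{01}+z_{12})/z_{01}}.
#'
#' @param geom a [ConeBeamGeometry-class].
#' @return an [EffectiveGeometry-class] (pixel in nm, distance in mm).
#' @export
#' @examples
#' effectiveGeometry(coneBeamGeometry(30, 5090, 6.5))
effectiveGeometry <- function(geom) {
  stopifnot(is(geom, "ConeBeamGeometry"))
  if (geom@z01 == 0) stop("z01 must be positive")
  M <- (geom@z01 + geom@z12) / geom@z01
  new("EffectiveGeometry",
      magnification = M,
      zEff = geom@z12 / M,
      pixelEff = geom@pixelPitch * 1000 / M)
}

#' Per-pixel Fresnel numbers of an effective geometry
#'
#' Convenience wrapper: one effective pixel is the resolution element.
#'
#' @param eff an [EffectiveGeometry-class].
#' @param energies_keV photon energies in keV (vectorized).
#' @return Fresnel numbers, one per energy.
#' @export
geometryFresnelNumbers <- function(eff, energies_keV) {
  stopifnot(is(eff, "EffectiveGeometry"))
  fresnelNumber(eff@pixelEff, eff@zEff, energyToWavelength(energies_keV))
}
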