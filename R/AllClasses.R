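## S4 container classes. All lengths in nm unless a slot name says otherwise.

#' Single-material description
#'
#' Stoichiometry plus mass density; electron density and optical constants
#' derive from these (see [electronDensity()], [deltaFromDensity()]).
#'
#' @slot name material name.
#' @slot formula named numeric vector of element counts.
#' @slot massDensity mass density in g/cm^3.
#' @exportClass Material
setClass("Material",
  representation(name = "character", formula = "numeric",
                 massDensity = "numeric"))

setValidity("Material", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(object@formula) < 1L || is.null(names(object@formula)))
    msg <- c(msg, "formula must be a named count vector")
  else if (any(object@formula < 1))
    msg <- c(msg, "all element counts must be >= 1")
  if (length(object@massDensity) != 1L || object@massDensity <= 0)
    msg <- c(msg, "massDensity must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Refractive-index components at a reference wavelength
#'
#' The X-ray refractive index is \eqn{n = 1 - \delta + i\beta}.  Away from
#' absorption edges \eqn{\delta \propto \lambda^2} and
#' \eqn{\beta \propto \lambda^4}; [deltaRescaled()] and [betaRescaled()]
#' apply these laws from the stored reference wavelength.
#'
#' @slot delta refractive index decrement (dimensionless, > 0).
#' @slot beta absorption component (dimensionless, >= 0).
#' @slot wavelengthRef reference wavelength in nm.
#' @exportClass OpticalConstants
setClass("OpticalConstants",
  representation(delta = "numeric", beta = "numeric",
                 wavelengthRef = "numeric"))

setValidity("OpticalConstants", function(object) {
  msg <- character()
  if (length(object@delta) != 1L || object@delta <= 0)
    msg <- c(msg, "delta must be a single positive number")
  if (length(object@beta) != 1L || object@beta < 0)
    msg <- c(msg, "beta must be a single non-negative number")
  if (length(object@wavelengthRef) != 1L || object@wavelengthRef <= 0)
    msg <- c(msg, "wavelengthRef must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Cone-beam recording geometry
#'
#' @slot z01 source-to-sample distance in mm.
#' @slot z12 sample-to-detector distance in mm.
#' @slot pixelPitch physical detector pixel size in micrometers.
#' @seealso [effectiveGeometry()]
#' @exportClass ConeBeamGeometry
setClass("ConeBeamGeometry",
  representation(z01 = "numeric", z12 = "numeric", pixelPitch = "numeric"))

setValidity("ConeBeamGeometry", function(object) {
  msg <- character()
  if (object@z01 <= 0) msg <- c(msg, "z01 must be > 0")
  if (object@z12 < 0) msg <- c(msg, "z12 must be >= 0")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
  if (length(msg)) msg else TRUE
})

#' Effective parallel-beam geometry (Fresnel scaling theorem)
#'
#' @slot magnification geometric magnification M = (z01+z12)/z01.
#' @slot zEff effective propagation distance z12/M in mm.
#' @slot pixelEff effective (demagnified) pixel size in nm.
#' @exportClass EffectiveGeometry
setClass("EffectiveGeometry",
  representation(magnification = "numeric", zEff = "numeric",
                 pixelEff = "numeric"))

setValidity("EffectiveGeometry", function(object) {
  msg <- character()
  if (object@magnification < 1) msg <- c(msg, "magnification must be >= 1")
  if (object@zEff < 0) msg <- c(msg, "zEff must be >= 0")
  if (object@pixelEff <= 0) msg <- c(msg, "pixelEff must be > 0")
  if (length(msg)) msg else TRUE
})

#' Complex wave field on a regular grid
#'
#' @slot values complex matrix of field amplitudes.
#' @slot pixelEff effective pixel size in nm (NA if unknown).
#' @slot wavelength wavelength in nm.
#' @exportClass ComplexField
setClass("ComplexField",
  representation(values = "matrix", pixelEff = "numeric",
                 wavelength = "numeric"))

setValidity("ComplexField", function(object) {
  msg <- character()
  if (!is.complex(object@values)) msg <- c(msg, "values must be complex")
  if (any(!is.finite(Mod(object@values))))
    msg <- c(msg, "values must be finite")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Flat-field corrected hologram
#'
#' Intensity normalized by the illumination, so an empty beam gives 1.
#' Carries its wavelength and the per-pixel Fresnel number (resolution
#' element = one effective pixel).
#'
#' @slot intensity non-negative intensity matrix.
#' @slot wavelength wavelength in nm.
#' @slot fresnelNumber per-pixel Fresnel number.
#' @slot pixelEff effective pixel size in nm (NA if unknown).
#' @exportClass Hologram
setClass("Hologram",
  representation(intensity = "matrix", wavelength = "numeric",
                 fresnelNumber = "numeric", pixelEff = "numeric"))

setValidity("Hologram", function(object) {
  msg <- character()
  if (any(object@intensity < 0)) msg <- c(msg, "intensity must be >= 0")
  m <- mean(object@intensity)
  if (is.finite(m) && (m < 0.5 || m > 1.5))
    msg <- c(msg, "flat-field corrected intensity should have mean in [0.5, 1.5]")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@fresnelNumber <= 0) msg <- c(msg, "fresnelNumber must be > 0")
  if (length(msg)) msg else TRUE
})

#' Retrieved projected electron density
#'
#' The map \eqn{\int \rho'(\xi) dz} in electrons/nm^2 (the classical electron
#' radius has been divided out of the raw CTF quotient).
#'
#' @slot density real matrix, electrons/nm^2.
#' @slot pixelEff effective pixel size in nm.
#' @exportClass ProjectionMap
setClass("ProjectionMap",
  representation(density = "matrix", pixelEff = "numeric"))

setValidity("ProjectionMap", function(object) {
  if (any(!is.finite(object@density))) "density must be finite" else TRUE
})

#' Angle-indexed stack of projected-density sinograms
#'
#' \code{data[a, r, s]} holds, for rotation angle \code{a}, the projected
#' electron density at detector row \code{r} (= reconstruction slice) and
#' lateral position \code{s}.
#'
#' @slot data numeric 3-D array (angle x row x column), electrons/nm^2.
#' @slot angles rotation angles in degrees, strictly increasing in [0, 180).
#' @slot pixelEff effective pixel size in nm.
#' @exportClass SinogramStack
setClass("SinogramStack",
  representation(data = "array", angles = "numeric", pixelEff = "numeric"))

setValidity("SinogramStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be 3-D")
  else if (dim(object@data)[1] != length(object@angles))
    msg <- c(msg, "first dimension must match length(angles)")
  if (length(object@angles) > 1 && any(diff(object@angles) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (any(object@angles < 0 | object@angles >= 180))
    msg <- c(msg, "angles must lie in [0, 180)")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' Reconstructed 3-D electron density
#'
#' @slot density numeric 3-D array, electrons/nm^3, dimensions
#'   (x, y, slice) with the rotation axis along the third dimension.
#' @slot voxel voxel edge length in nm.
#' @exportClass VolumeMap
setClass("VolumeMap",
  representation(density = "array", voxel = "numeric"))

setValidity("VolumeMap", function(object) {
  msg <- character()
  if (length(dim(object@density)) != 3L) msg <- c(msg, "density must be 3-D")
  if (any(!is.finite(object@density))) msg <- c(msg, "density must be finite")
  if (object@voxel <= 0) msg <- c(msg, "voxel must be > 0")
  if (length(msg)) msg else TRUE
})

#' Labeled particle volume
#'
#' Integer labels, 0 = background, particles numbered consecutively from 1.
#'
#' @slot labels integer 3-D array.
#' @slot voxel voxel edge length in nm.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", voxel = "numeric"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be 3-D")
  lab <- sort(unique(as.integer(object@labels)))
  lab <- lab[lab != 0L]
  if (length(lab) && !identical(lab, seq_along(lab)))
    msg <- c(msg, "labels must be consecutive positive integers")
  if (object@voxel <= 0) msg <- c(msg, "voxel must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic 3-D multi-particle phantom
#'
#' @slot density electrons/nm^3 array (x, y, slice).
#' @slot labels ground-truth particle labels (same dimensions).
#' @slot voxel voxel edge length in nm.
#' @slot backgroundDensity embedding-medium density in electrons/nm^3.
#' @exportClass PhantomVolume3D
setClass("PhantomVolume3D",
  representation(density = "array", labels = "array", voxel = "numeric",
                 backgroundDensity = "numeric"))

setValidity("PhantomVolume3D", function(object) {
  msg <- character()
  if (!identical(dim(object@density), dim(object@labels)))
    msg <- c(msg, "density and labels must share dimensions")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of the 2-D single-particle phantom
#'
#' @slot targetVolume particle volume in fL (1 fL = 1 um^3).
#' @slot maxThickness maximum projected thickness in um.
#' @slot meanThickness mean projected thickness over the support in um.
#' @slot grid linear grid size in pixels (square map).
#' @slot pixelEff pixel size in nm.
#' @slot seed integer seed controlling the lobe jitter.
#' @exportClass PhantomSpec2D
setClass("PhantomSpec2D",
  representation(targetVolume = "numeric", maxThickness = "numeric",
                 meanThickness = "numeric", grid = "integer",
                 pixelEff = "numeric", seed = "integer"))

setValidity("PhantomSpec2D", function(object) {
  msg <- character()
  if (object@targetVolume <= 0) msg <- c(msg, "targetVolume must be > 0")
  if (object@meanThickness > object@maxThickness)
    msg <- c(msg, "meanThickness must not exceed maxThickness")
  if (object@grid < 16L) msg <- c(msg, "grid too small")
  if (object@pixelEff <= 0) msg <- c(msg, "pixelEff must be > 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of the multi-energy CTF inversion
#'
#' @slot channels data.frame with columns \code{wavelength} (nm) and
#'   \code{fresnelNumber}, one row per hologram.
#' @slot cprime homogeneous-object coupling C' = beta/(delta lambda_r^2)
#'   in 1/nm^2.
#' @slot alphaAmplitude amplitude of the step regularization (default 1e-4).
#' @slot meanRule how the mean channel for C'/regularization is defined:
#'   \code{"mean_energy"} (arithmetic mean photon energy) or
#'   \code{"mean_wavelength"}.
#' @exportClass RetrievalConfig
setClass("RetrievalConfig",
  representation(channels = "data.frame", cprime = "numeric",
                 alphaAmplitude = "numeric", meanRule = "character"))

setValidity("RetrievalConfig", function(object) {
  msg <- character()
  ch <- object@channels
  if (nrow(ch) < 1L) msg <- c(msg, "at least one channel required")
  if (!all(c("wavelength", "fresnelNumber") %in% names(ch)))
    msg <- c(msg, "channels needs columns wavelength, fresnelNumber")
  else {
    if (any(ch$wavelength <= 0)) msg <- c(msg, "wavelengths must be > 0")
    if (any(ch$fresnelNumber <= 0)) msg <- c(msg, "Fresnel numbers must be > 0")
  }
  if (object@cprime < 0) msg <- c(msg, "cprime must be >= 0")
  if (object@alphaAmplitude < 0) msg <- c(msg, "alphaAmplitude must be >= 0")
  if (!object@meanRule %in% c("mean_energy", "mean_wavelength"))
    msg <- c(msg, "meanRule must be 'mean_energy' or 'mean_wavelength'")
  if (length(msg)) msg else TRUE
})
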