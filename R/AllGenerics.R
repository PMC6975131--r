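## Generics and accessors. Slot access from user code goes through these.

#' @title Accessors for holoctf containers
#' @description Small accessor generics: \code{intensity()} (hologram
#'   intensity matrix), \code{densityMap()} (density array of a projection or
#'   volume), \code{wavelength()}, \code{pixelSize()}, \code{voxelSize()},
#'   \code{angles()}, \code{magnification()}.
#' @param object a holoctf container object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("densityMap", function(object) standardGeneric("densityMap"))

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("magnification", function(object) standardGeneric("magnification"))

#' Fresnel number
#'
#' For numeric input, computes \eqn{F = a^2/(\Delta\,\lambda)} for resolution
#' element \code{a} (nm), propagation distance \code{distance} (mm) and
#' wavelength (nm).  For a [Hologram-class] or [ComplexField-class], returns
#' the per-pixel Fresnel number carried by the object.
#'
#' @param object resolution element in nm, or a container object.
#' @param distance propagation distance in mm (numeric method).
#' @param wavelength wavelength in nm (numeric method).
#' @return dimensionless Fresnel number.
#' @export
#' @examples
#' fresnelNumber(38, 29, energyToWavelength(6))  # about 2.4e-4
setGeneric("fresnelNumber",
  function(object, distance, wavelength) standardGeneric("fresnelNumber"))

#' @rdname accessors
#' @export
setMethod("intensity", "Hologram", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("densityMap", "ProjectionMap", function(object) object@density)

#' @rdname accessors
#' @export
setMethod("densityMap", "VolumeMap", function(object) object@density)

#' @rdname accessors
#' @export
setMethod("densityMap", "PhantomVolume3D", function(object) object@density)

#' @rdname accessors
#' @export
setMethod("wavelength", "Hologram", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelength", "ComplexField", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("pixelSize", "Hologram", function(object) object@pixelEff)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ProjectionMap", function(object) object@pixelEff)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SinogramStack", function(object) object@pixelEff)

#' @rdname accessors
#' @export
setMethod("pixelSize", "EffectiveGeometry", function(object) object@pixelEff)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeMap", function(object) object@voxel)

#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelVolume", function(object) object@voxel)

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomVolume3D", function(object) object@voxel)

#' @rdname accessors
#' @export
setMethod("angles", "SinogramStack", function(object) object@angles)

#' @rdname accessors
#' @export
setMethod("magnification", "EffectiveGeometry",
  function(object) object@magnification)

#' @rdname fresnelNumber
#' @export
setMethod("fresnelNumber", signature("Hologram", "missing", "missing"),
  function(object, distance, wavelength) object@fresnelNumber)

#' @describeIn fresnelNumber compute from resolution element, distance and
#'   wavelength.
#' @export
setMethod("fresnelNumber", signature("numeric", "numeric", "numeric"),
  function(object, distance, wavelength) {
    stopifnot(all(object > 0), all(distance > 0), all(wavelength > 0))
    object^2 / (distance * 1e6 * wavelength)
  })

#' Extract particle labels
#'
#' @param object a [LabelVolume-class] or [PhantomVolume3D-class].
#' @param ... unused.
#' @return the integer label array.
#' @export
labels.LabelVolume <- function(object, ...) object@labels

#' @rdname labels.LabelVolume
#' @export
labels.PhantomVolume3D <- function(object, ...) object@labels

setMethod("show", "Material", function(object) {
  f <- paste0(names(object@formula),
              ifelse(object@formula > 1, object@formula, ""), collapse = "")
  cat(sprintf("Material '%s': %s, %.4g g/cm^3, %.4g electrons/nm^3\n",
              object@name, f, object@massDensity, electronDensity(object)))
})

setMethod("show", "OpticalConstants", function(object) {
  cat(sprintf(
    "OpticalConstants: delta %.4g, beta %.4g at lambda_ref %.5g nm (%.3g keV)\n",
    object@delta, object@beta, object@wavelengthRef,
    wavelengthToEnergy(object@wavelengthRef)))
})

setMethod("show", "ConeBeamGeometry", function(object) {
  cat(sprintf("ConeBeamGeometry: z01 %.4g mm, z12 %.4g mm, pixel %.4g um\n",
              object@z01, object@z12, object@pixelPitch))
})

setMethod("show", "EffectiveGeometry", function(object) {
  cat(sprintf(
    "EffectiveGeometry: M %.5g, z_eff %.4g mm, pixel_eff %.4g nm\n",
    object@magnification, object@zEff, object@pixelEff))
})

setMethod("show", "Hologram", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "Hologram %dx%d: lambda %.5g nm (%.3g keV), F %.4g, mean intensity %.4f\n",
    d[1], d[2], object@wavelength, wavelengthToEnergy(object@wavelength),
    object@fresnelNumber, mean(object@intensity)))
})

setMethod("show", "ProjectionMap", function(object) {
  d <- dim(object@density)
  cat(sprintf(
    "ProjectionMap %dx%d (electrons/nm^2), pixel %.4g nm, range [%.4g, %.4g]\n",
    d[1], d[2], object@pixelEff, min(object@density), max(object@density)))
})

setMethod("show", "SinogramStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SinogramStack: %d angles [%.4g..%.4g deg], %d rows x %d columns\n",
    d[1], min(object@angles), max(object@angles), d[2], d[3]))
})

setMethod("show", "VolumeMap", function(object) {
  d <- dim(object@density)
  cat(sprintf(
    "VolumeMap %dx%dx%d (electrons/nm^3), voxel %.4g nm, mean %.4g\n",
    d[1], d[2], d[3], object@voxel, mean(object@density)))
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume %s: %d particle(s), voxel %.4g nm\n",
              paste(dim(object@labels), collapse = "x"),
              max(object@labels), object@voxel))
})

setMethod("show", "PhantomVolume3D", function(object) {
  cat(sprintf(
    "PhantomVolume3D %s: %d particle(s), background %.4g electrons/nm^3\n",
    paste(dim(object@density), collapse = "x"),
    max(object@labels), object@backgroundDensity))
})

setMethod("show", "RetrievalConfig", function(object) {
  cat(sprintf(
    "RetrievalConfig: %d channel(s), C' %.4g /nm^2, alpha %.3g (%s rule)\n",
    nrow(object@channels), object@cprime, object@alphaAmplitude,
    object@meanRule))
})

setMethod("show", "PhantomSpec2D", function(object) {
  cat(sprintf(
    "PhantomSpec2D: %.3g fL, max %.3g um, mean %.3g um on %d^2 px @ %.3g nm (seed %d)\n",
    object@targetVolume, object@maxThickness, object@meanThickness,
    object@grid, object@pixelEff, object@seed))
})
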