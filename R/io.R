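## Container I/O. Images travel as 32-bit float TIFF (single- or
## multi-page); numeric metadata (wavelength, Fresnel number, pixel size,
## angles, value range) lives in a YAML sidecar next to the image file.
## TIFF float samples are stored normalized to [0, 1] with the range in the
## sidecar, so round trips are exact to 32-bit float precision (~1e-7
## relative).

.sidecarPath <- function(path) paste0(path, ".yaml")

.writeImagePages <- function(pages, path, meta) {
  rng <- range(vapply(pages, range, numeric(2)))
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  scaled <- lapply(pages, function(p) (p - rng[1]) / (rng[2] - rng[1]))
  suppressWarnings(tiff::writeTIFF(
    if (length(scaled) == 1L) scaled[[1]] else scaled,
    path, bits.per.sample = 32L))
  meta$value_min <- rng[1]
  meta$value_max <- rng[2]
  meta$pages <- length(pages)
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

.readImagePages <- function(path, required = character()) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc)
  meta <- yaml::read_yaml(sc)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("metadata attribute(s) missing from ", sc, ": ",
         paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p)
    p * (meta$value_max - meta$value_min) + meta$value_min)
  list(pages = pages, meta = meta)
}

#' Write / read a hologram
#'
#' Single-page 32-bit float TIFF plus a YAML sidecar carrying
#' \code{wavelength_nm}, \code{fresnel_number} and \code{pixel_eff_nm}.
#'
#' @param hologram a [Hologram-class].
#' @param path TIFF file path (sidecar written next to it).
#' @return \code{writeHologram}: the path, invisibly. \code{readHologram}:
#'   a [Hologram-class].
#' @export
writeHologram <- function(hologram, path) {
  stopifnot(is(hologram, "Hologram"))
  .writeImagePages(list(hologram@intensity), path,
                   list(type = "hologram",
                        wavelength_nm = hologram@wavelength,
                        fresnel_number = hologram@fresnelNumber,
                        pixel_eff_nm = hologram@pixelEff))
}

#' @rdname writeHologram
#' @export
readHologram <- function(path) {
  x <- .readImagePages(path, c("wavelength_nm", "fresnel_number"))
  new("Hologram", intensity = x$pages[[1]],
      wavelength = x$meta$wavelength_nm,
      fresnelNumber = x$meta$fresnel_number,
      pixelEff = x$meta$pixel_eff_nm %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a projected electron density map
#'
#' @param projection a [ProjectionMap-class].
#' @param path TIFF file path.
#' @return \code{writeProjection}: the path, invisibly.
#'   \code{readProjection}: a [ProjectionMap-class].
#' @export
writeProjection <- function(projection, path) {
  stopifnot(is(projection, "ProjectionMap"))
  .writeImagePages(list(projection@density), path,
                   list(type = "projection",
                        pixel_eff_nm = projection@pixelEff))
}

#' @rdname writeProjection
#' @export
readProjection <- function(path) {
  x <- .readImagePages(path, "pixel_eff_nm")
  new("ProjectionMap", density = x$pages[[1]],
      pixelEff = x$meta$pixel_eff_nm)
}

#' Write / read a sinogram stack
#'
#' One TIFF page per angle; the sidecar stores the angle list and pixel
#' size.
#'
#' @param stack a [SinogramStack-class].
#' @param path TIFF file path.
#' @return \code{writeSinogram}: the path, invisibly. \code{readSinogram}:
#'   a [SinogramStack-class].
#' @export
writeSinogram <- function(stack, path) {
  stopifnot(is(stack, "SinogramStack"))
  d <- dim(stack@data)
  pages <- lapply(seq_len(d[1]), function(a)
    matrix(stack@data[a, , ], d[2], d[3]))
  .writeImagePages(pages, path,
                   list(type = "sinogram",
                        angles_deg = as.list(stack@angles),
                        pixel_eff_nm = stack@pixelEff))
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  x <- .readImagePages(path, c("angles_deg", "pixel_eff_nm"))
  angles <- unlist(x$meta$angles_deg)
  d2 <- dim(x$pages[[1]])
  data <- array(0, c(length(x$pages), d2[1], d2[2]))
  for (a in seq_along(x$pages)) data[a, , ] <- x$pages[[a]]
  sinogramStack(data, angles, x$meta$pixel_eff_nm)
}

#' Write / read a reconstructed volume
#'
#' One TIFF page per slice (third array dimension); the sidecar stores the
#' voxel size.
#'
#' @param volume a [VolumeMap-class].
#' @param path TIFF file path.
#' @return \code{writeVolume}: the path, invisibly. \code{readVolume}: a
#'   [VolumeMap-class].
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeMap"))
  d <- dim(volume@density)
  pages <- lapply(seq_len(d[3]), function(k) volume@density[, , k])
  .writeImagePages(pages, path,
                   list(type = "volume", voxel_nm = volume@voxel))
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  x <- .readImagePages(path, "voxel_nm")
  d2 <- dim(x$pages[[1]])
  dens <- array(0, c(d2[1], d2[2], length(x$pages)))
  for (k in seq_along(x$pages)) dens[, , k] <- x$pages[[k]]
  volumeMap(dens, x$meta$voxel_nm)
}
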