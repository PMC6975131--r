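## Threshold-based particle segmentation with erosion/dilation, and
## per-particle volume / excess-density statistics.

#' Segment particles in a reconstructed volume
#'
#' Pipeline: binarize at \code{threshold}, erode \code{nErode} times
#' (6-connected cross), label 26-connected components, dilate labels
#' \code{nDilate} times constrained to the original binary mask, then drop
#' components smaller than \code{minVoxels}.  Erosion followed by
#' constrained dilation separates touching particles while restoring most
#' of their volume.
#'
#' @param volume a [VolumeMap-class].
#' @param threshold density threshold in electrons/nm^3.
#' @param nErode erosion steps (>= 0, default 2).
#' @param nDilate constrained dilation steps (>= 0, default 2).
#' @param minVoxels minimum component size kept (default 50).
#' @return a [LabelVolume-class]; an empty result (no labels) is valid.
#' @export
segmentParticles <- function(volume, threshold, nErode = 2L, nDilate = 2L,
                             minVoxels = 50L) {
  stopifnot(is(volume, "VolumeMap"))
  nErode <- as.integer(nErode); nDilate <- as.integer(nDilate)
  if (nErode < 0 || nDilate < 0) stop("nErode/nDilate must be >= 0")
  dims <- dim(volume@density)
  mask0 <- volume@density > threshold
  mask <- mask0
  for (i in seq_len(nErode))
    mask <- array(.erode6Cpp(mask, dims), dims)
  lab <- .label26Cpp(mask, dims)
  for (i in seq_len(nDilate))
    lab <- .dilateLabelsCpp(lab, mask0, dims)
  ## size filter and relabeling to consecutive ids
  if (max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= minVoxels)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
  }
  new("LabelVolume", labels = lab, voxel = volume@voxel)
}

#' Per-particle volume and excess-density statistics
#'
#' @param labelVol a [LabelVolume-class].
#' @param volume the [VolumeMap-class] the labels refer to (same grid).
#' @param referenceDensity reference (embedding medium) density in
#'   electrons/nm^3; excess densities are reported relative to it.
#' @param ids particle ids to report (default: all).
#' @return data.frame with columns \code{label}, \code{voxels},
#'   \code{volume_fL} and \code{excessDensity} (electrons/nm^3).
#' @export
particleStats <- function(labelVol, volume, referenceDensity, ids = NULL) {
  stopifnot(is(labelVol, "LabelVolume"), is(volume, "VolumeMap"))
  if (!identical(dim(labelVol@labels), dim(volume@density)))
    stop("labels and volume must share grids")
  nmax <- max(labelVol@labels)
  if (is.null(ids)) ids <- seq_len(nmax)
  if (length(ids) && any(ids < 1L | ids > max(1L, nmax)))
    stop("label id(s) absent from the label volume: ",
         paste(setdiff(ids, seq_len(nmax)), collapse = ", "))
  lab <- as.integer(labelVol@labels)
  dens <- as.numeric(volume@density)
  voxVol <- labelVol@voxel^3 / 1e9   # nm^3 -> fL
  counts <- tabulate(lab, nbins = max(1L, nmax))
  sums <- vapply(ids, function(i) sum(dens[lab == i]), numeric(1))
  data.frame(label = as.integer(ids),
             voxels = counts[ids],
             volume_fL = counts[ids] * voxVol,
             excessDensity = sums / counts[ids] - referenceDensity)
}
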