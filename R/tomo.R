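## Sinogram conditioning and tomographic reconstruction: angular
## interpolation, truncation padding, wavelet-Fourier ring removal,
## filtered backprojection, mean calibration, intensity projections.

#' Construct a sinogram stack
#'
#' @param data numeric 3-D array (angle x row x column) of projected
#'   electron densities in electrons/nm^2.
#' @param angles rotation angles in degrees, strictly increasing, in
#'   [0, 180).
#' @param pixelEff effective pixel size in nm.
#' @return a [SinogramStack-class].
#' @export
sinogramStack <- function(data, angles, pixelEff) {
  new("SinogramStack", data = data, angles = as.numeric(angles),
      pixelEff = as.numeric(pixelEff))
}

#' Construct a volume map
#'
#' @param density numeric 3-D array in electrons/nm^3.
#' @param voxel voxel edge length in nm.
#' @return a [VolumeMap-class].
#' @export
volumeMap <- function(density, voxel) {
  new("VolumeMap", density = density, voxel = as.numeric(voxel))
}

#' Parallel-beam forward projection of a volume
#'
#' Projects a 3-D density (effective parallel-beam coordinates, rotation
#' axis along the third array dimension) at the given angles, returning
#' line integrals of the density in electrons/nm^2.  The projection of
#' slice k at angle a fills \code{data[a, k, ]}.
#'
#' @param volume a [VolumeMap-class] or [PhantomVolume3D-class].
#' @param angles_deg rotation angles in degrees.
#' @return a [SinogramStack-class].
#' @export
projectVolume <- function(volume, angles_deg) {
  dens <- densityMap(volume)
  vox <- voxelSize(volume)
  d <- dim(dens)
  if (d[1] != d[2]) stop("slices must be square")
  rad <- angles_deg * pi / 180
  out <- array(0, c(length(rad), d[3], d[1]))
  for (k in seq_len(d[3]))
    out[, k, ] <- .radonForwardCpp(dens[, , k], rad, d[1]) * vox
  sinogramStack(out, angles_deg, vox)
}

#' Angular interpolation of a sinogram stack
#'
#' Linear interpolation between adjacent angles; with factor f the angle
#' count becomes f (N - 1) + 1 and the original angles (and data) are
#' preserved exactly.
#'
#' @param stack a [SinogramStack-class].
#' @param factor integer interpolation factor (>= 1; 1 is the identity).
#' @return a [SinogramStack-class].
#' @export
angularInterpolate <- function(stack, factor = 2L) {
  stopifnot(is(stack, "SinogramStack"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L || length(stack@angles) == 1L) return(stack)
  nA <- length(stack@angles)
  newAngles <- numeric(factor * (nA - 1) + 1)
  d <- dim(stack@data)
  out <- array(0, c(length(newAngles), d[2], d[3]))
  for (i in seq_len(nA - 1)) {
    for (s in 0:(factor - 1)) {
      w <- s / factor
      j <- factor * (i - 1) + s + 1
      newAngles[j] <- (1 - w) * stack@angles[i] + w * stack@angles[i + 1]
      out[j, , ] <- (1 - w) * stack@data[i, , ] + w * stack@data[i + 1, , ]
    }
  }
  newAngles[length(newAngles)] <- stack@angles[nA]
  out[length(newAngles), , ] <- stack@data[nA, , ]
  sinogramStack(out, newAngles, stack@pixelEff)
}

#' Extend truncated sinograms by edge repetition
#'
#' Pads every sinogram row on both lateral sides with its outermost pixel
#' value, the standard conditioning step for region-of-interest
#' (truncated) projections before filtered backprojection.
#'
#' @param stack a [SinogramStack-class].
#' @param pad number of pixels added on each side (>= 0).
#' @return a [SinogramStack-class] widened by \code{2 pad}.
#' @export
extendTruncated <- function(stack, pad) {
  stopifnot(is(stack, "SinogramStack"))
  pad <- as.integer(pad)
  if (pad < 0) stop("pad must be >= 0")
  if (pad == 0L) return(stack)
  d <- dim(stack@data)
  out <- array(0, c(d[1], d[2], d[3] + 2L * pad))
  out[, , pad + seq_len(d[3])] <- stack@data
  out[, , seq_len(pad)] <- stack@data[, , 1]
  out[, , pad + d[3] + seq_len(pad)] <- stack@data[, , d[3]]
  sinogramStack(out, stack@angles, stack@pixelEff)
}

#' Wavelet-Fourier ring (stripe) removal
#'
#' Combined wavelet-Fourier filtering of angle-constant stripes: each
#' sinogram is decomposed with a periodized orthogonal wavelet; at every
#' level the band that is smooth along the angle axis but detailed along
#' the lateral axis (where stripes concentrate) is Fourier-transformed
#' along the angle axis and its low angular frequencies damped with
#' \eqn{1 - \exp(-f^2 / 2\sigma^2)}; the stack is then reconstructed.
#'
#' @param stack a [SinogramStack-class].
#' @param wavelet one of \code{"haar"}, \code{"d4"}, \code{"d8"}
#'   (Daubechies orthogonal filters with 2, 4 and 8 taps).
#' @param levels number of decomposition levels (>= 1).
#' @param dampingSigma Gaussian damping width in frequency bins.
#' @return the filtered [SinogramStack-class] (same shape).
#' @export
removeRingsWavelet <- function(stack, wavelet = "d4", levels = 4L,
                               dampingSigma = 2) {
  stopifnot(is(stack, "SinogramStack"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  h <- .waveletFilter(wavelet)
  d <- dim(stack@data)
  out <- stack@data
  for (k in seq_len(d[2])) {
    out[, k, ] <- .destripe(stack@data[, k, , drop = TRUE], h, levels,
                            dampingSigma)
  }
  sinogramStack(out, stack@angles, stack@pixelEff)
}

.waveletFilter <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    d4 = c(0.4829629131445341, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604),
    d8 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
           -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet '", name, "'; supported: haar, d4, d8"))
}

## periodized single-level analysis along columns of m; returns rbind(A, D)
.dwtCols <- function(m, h) {
  n <- nrow(m)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  half <- n / 2
  A <- matrix(0, half, ncol(m)); D <- A
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_len(L)) {
    idx <- (base + k - 1) %% n + 1
    A <- A + h[k] * m[idx, , drop = FALSE]
    D <- D + g[k] * m[idx, , drop = FALSE]
  }
  rbind(A, D)
}

## periodized single-level synthesis (transpose of the analysis operator)
.idwtCols <- function(AD, h) {
  n <- nrow(AD)
  half <- n / 2
  L <- length(h)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  A <- AD[seq_len(half), , drop = FALSE]
  D <- AD[half + seq_len(half), , drop = FALSE]
  out <- matrix(0, n, ncol(AD))
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_len(L)) {
    idx <- (base + k - 1) %% n + 1
    contrib <- h[k] * A + g[k] * D
    for (r in seq_len(half))
      out[idx[r], ] <- out[idx[r], ] + contrib[r, ]
  }
  out
}

## pad to a multiple of 2^levels along both axes by edge replication
.padPow <- function(m, levels) {
  mult <- 2^levels
  padTo <- function(n) ceiling(n / mult) * mult
  nr <- padTo(nrow(m)); nc <- padTo(ncol(m))
  if (nr > nrow(m)) m <- rbind(m, m[rep(nrow(m), nr - nrow(m)), ,
                                    drop = FALSE])
  if (nc > ncol(m)) m <- cbind(m, m[, rep(ncol(m), nc - ncol(m)),
                                    drop = FALSE])
  m
}

## wavelet-Fourier destriping of one sinogram (rows = angles, cols = s)
.destripe <- function(m, h, levels, sigma) {
  nr0 <- nrow(m); nc0 <- ncol(m)
  m <- .padPow(m, levels)
  dec <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    ## analyze along angle axis (columns of cur are s-profiles)
    tmp <- .dwtCols(cur, h)
    na <- nrow(tmp) / 2
    Aa <- tmp[seq_len(na), , drop = FALSE]
    Da <- tmp[na + seq_len(na), , drop = FALSE]
    ## analyze along s axis
    Aa2 <- t(.dwtCols(t(Aa), h)); Da2 <- t(.dwtCols(t(Da), h))
    ns <- ncol(Aa2) / 2
    dec[[l]] <- list(AD = Aa2[, ns + seq_len(ns), drop = FALSE],  # stripes
                     DA = Da2[, seq_len(ns), drop = FALSE],
                     DD = Da2[, ns + seq_len(ns), drop = FALSE])
    cur <- Aa2[, seq_len(ns), drop = FALSE]
  }
  ## damp stripe bands: FFT along the angle axis, suppress low frequencies
  for (l in seq_len(levels)) {
    B <- dec[[l]]$AD
    f <- fftFreq(nrow(B)) * nrow(B)   # frequency index in bins
    damp <- 1 - exp(-f^2 / (2 * sigma^2))
    dec[[l]]$AD <- Re(stats::mvfft(stats::mvfft(B) * damp,
                                   inverse = TRUE)) / nrow(B)
  }
  ## reconstruct
  for (l in rev(seq_len(levels))) {
    AD <- dec[[l]]$AD; DA <- dec[[l]]$DA; DD <- dec[[l]]$DD
    Aa <- t(.idwtCols(t(cbind(cur, AD)), h))
    Da <- t(.idwtCols(t(cbind(DA, DD)), h))
    cur <- .idwtCols(rbind(Aa, Da), h)
  }
  cur[seq_len(nr0), seq_len(nc0)]
}

#' Filtered backprojection
#'
#' Slice-wise parallel-beam filtered backprojection over the stack's
#' angles.  Projections are ramp-filtered in Fourier space (optionally with
#' a Hann window) after zero padding, then backprojected with bilinear
#' interpolation.  The sinogram's electrons/nm^2 line integrals are
#' converted back to electrons/nm^3 using the stack's pixel size, which
#' becomes the voxel size of the result.
#'
#' @param stack a [SinogramStack-class] (>= 2 angles).
#' @param filter \code{"ramp"} or \code{"hann"} (Hann-weighted ramp).
#' @return a [VolumeMap-class] with \code{ns x ns} slices.
#' @export
fbpReconstruct <- function(stack, filter = c("ramp", "hann")) {
  stopifnot(is(stack, "SinogramStack"))
  filter <- match.arg(filter)
  d <- dim(stack@data)
  if (d[1] < 2) stop("need at least 2 angles")
  ns <- d[3]
  nfft <- 2^ceiling(log2(2 * ns))
  ## band-limited ramp: FFT of the discrete impulse response
  ## h[0] = 1/4, h[n odd] = -1/(pi n)^2, h[n even] = 0
  ## (sampling |nu| directly would misweight DC and cause cupping)
  idx <- fftFreq(nfft) * nfft        # signed sample offsets
  h <- numeric(nfft)
  h[idx == 0] <- 0.25
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi * idx[odd])^2
  H <- Re(stats::fft(h))
  if (filter == "hann") H <- H * 0.5 * (1 + cos(pi * fftFreq(nfft) / 0.5))
  rad <- stack@angles * pi / 180
  vol <- array(0, c(ns, ns, d[2]))
  for (k in seq_len(d[2])) {
    sino <- stack@data[, k, , drop = TRUE] / stack@pixelEff  # voxel units
    if (d[1] == 1) sino <- matrix(sino, 1)
    padded <- matrix(0, nfft, d[1])
    padded[seq_len(ns), ] <- t(sino)
    filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / nfft
    vol[, , k] <- .backprojectCpp(t(filt[seq_len(ns), , drop = FALSE]),
                                  rad, ns)
  }
  volumeMap(vol, stack@pixelEff)
}

#' Shift a volume's mean to a reference density
#'
#' Adds the constant that makes the volume mean equal the expected
#' embedding-medium density (the calibration used for truncated
#' region-of-interest tomograms, where the reconstruction is only defined
#' up to an offset).  Idempotent; leaves the variance untouched.
#'
#' @param volume a [VolumeMap-class].
#' @param referenceDensity target mean in electrons/nm^3.
#' @return the shifted [VolumeMap-class].
#' @export
shiftMean <- function(volume, referenceDensity) {
  stopifnot(is(volume, "VolumeMap"))
  volumeMap(volume@density + (referenceDensity - mean(volume@density)),
            volume@voxel)
}

#' Maximum / minimum intensity projection
#'
#' Per-pixel extreme over a slab of \code{depth} voxels along one axis,
#' the standard visualization of reconstructed slices.
#'
#' @param volume a [VolumeMap-class].
#' @param depth slab depth in voxels (default 11).
#' @param mode \code{"max"} or \code{"min"}.
#' @param axis array dimension the slab runs along (default 3).
#' @param start first voxel of the slab (default: centered).
#' @return a 2-D matrix.
#' @export
intensityProjection <- function(volume, depth = 11L, mode = c("max", "min"),
                                axis = 3L, start = NULL) {
  stopifnot(is(volume, "VolumeMap"))
  mode <- match.arg(mode)
  depth <- as.integer(depth)
  n <- dim(volume@density)[axis]
  if (depth < 1L || depth > n)
    stop("depth must be between 1 and ", n)
  if (is.null(start)) start <- (n - depth) %/% 2 + 1L
  if (start < 1L || start + depth - 1L > n)
    stop("slab [", start, ", ", start + depth - 1L, "] outside the volume")
  idx <- start:(start + depth - 1L)
  slab <- switch(axis,
                 volume@density[idx, , , drop = FALSE],
                 volume@density[, idx, , drop = FALSE],
                 volume@density[, , idx, drop = FALSE])
  apply(slab, setdiff(1:3, axis), if (mode == "max") max else min)
}
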