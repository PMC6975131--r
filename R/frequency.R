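## FFT frequency-grid helpers. DC sits at index (1,1); no fftshift is applied
## anywhere inside computational kernels.

#' FFT sample frequencies
#'
#' Frequencies in cycles per sample for an n-point FFT, in the native FFT
#' ordering (DC first, negative frequencies in the upper half).
#'
#' @param n number of samples.
#' @return numeric vector of length n in [-1/2, 1/2).
#' @export
fftFreq <- function(n) {
  stopifnot(n >= 1)
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
}

#' Squared radial frequency grid
#'
#' \eqn{|\nu|^2 = \nu_x^2 + \nu_y^2} in (cycles/pixel)^2 on an nr x nc grid,
#' FFT layout.  This is the grid on which the chirp phase
#' \eqn{\chi = \pi|\nu|^2/F} and the CTF kernels are evaluated.
#'
#' @param nr,nc grid dimensions (nc defaults to nr).
#' @return nr x nc matrix.
#' @export
freqGridSq <- function(nr, nc = nr) {
  fr <- fftFreq(nr)
  fc <- fftFreq(nc)
  outer(fr^2, fc^2, "+")
}

#' Chirp phase of the paraxial propagator
#'
#' \eqn{\chi(\nu) = \pi |\nu|^2 / F} with \eqn{\nu} in cycles per pixel and
#' F the per-pixel Fresnel number.  Equal to the physical form
#' \eqn{\pi \lambda \Delta f^2} with f in cycles per unit length.
#'
#' @param freqSq squared-frequency grid from [freqGridSq()].
#' @param fresnel per-pixel Fresnel number (> 0).
#' @return matrix of chirp phases in radians.
#' @export
chirpPhase <- function(freqSq, fresnel) {
  stopifnot(fresnel > 0)
  pi * freqSq / fresnel
}

## centered embedding of a small matrix into a value-filled larger one
.embed <- function(m, nr, nc = nr, fill = 0) {
  if (nr < nrow(m) || nc < ncol(m))
    stop("pad size smaller than the embedded grid (",
         nrow(m), "x", ncol(m), " into ", nr, "x", nc, ")")
  out <- matrix(fill, nr, nc)
  i0 <- (nr - nrow(m)) %/% 2
  j0 <- (nc - ncol(m)) %/% 2
  out[i0 + seq_len(nrow(m)), j0 + seq_len(ncol(m))] <- m
  out
}

## central crop, inverse of .embed
.cropCenter <- function(m, nr, nc = nr) {
  i0 <- (nrow(m) - nr) %/% 2
  j0 <- (ncol(m) - nc) %/% 2
  m[i0 + seq_len(nr), j0 + seq_len(nc)]
}

.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)
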