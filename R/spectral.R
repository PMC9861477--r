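#' Frequency bands
#'
#' The default analysis bands: theta 4-8 Hz, alpha 8-14 Hz, beta 14-30 Hz.
#' Band intervals are half-open, `[low, high)`, so the shared printed
#' boundaries (8 Hz, 14 Hz) belong to exactly one band.
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return `band_definition()` returns a `band_definition` list;
#'   `default_bands()` the named list of the three defaults.
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 14),
       beta  = band_definition("beta", 14, 30))
}

#' Discrete Fourier transform of an epoch
#'
#' The unnormalised DFT `X_k = sum_n x_n exp(-i 2 pi k n / N)`,
#' `k = 0 ... N-1`, computed with the FFT; identical (to rounding) to the
#' direct quadratic-time sum.  Given a matrix, channels are rows and each
#' row is transformed.
#'
#' @param x numeric vector of N samples, or channels x N matrix.
#' @return Complex vector/matrix of the same shape, with attribute
#'   `resolution` (Hz per bin) when `rate` is supplied.
#' @param rate optional sampling rate, used to tag the frequency resolution.
#' @export
dft_epoch <- function(x, rate = NULL) {
  if (is.matrix(x)) {
    if (!all(is.finite(x))) stop("non-finite samples in epoch")
    X <- t(mvfft(t(x)))
  } else {
    if (length(x) < 2) stop("an epoch needs at least 2 samples")
    if (!all(is.finite(x))) stop("non-finite samples in epoch")
    X <- fft(x)
  }
  if (!is.null(rate)) attr(X, "resolution") <- rate / (if (is.matrix(x)) ncol(x) else length(x))
  X
}

#' Mean band amplitude of a spectrum
#'
#' Mean of `|X_k|` over the positive-frequency bins whose frequency f
#' satisfies `low <= f < high`.  Only bins up to the Nyquist frequency are
#' used; by conjugate symmetry of real signals the negative-frequency bins
#' carry no extra information.
#'
#' @param spec complex DFT coefficients (vector, or channels x N matrix).
#' @param band a [band_definition()].
#' @param rate sampling rate in Hz (may be omitted when `spec` carries a
#'   `resolution` attribute).
#' @return scalar (or per-channel vector) of mean band amplitude.
#' @export
band_amplitude <- function(spec, band, rate = NULL) {
  stopifnot(inherits(band, "band_definition"))
  N <- if (is.matrix(spec)) ncol(spec) else length(spec)
  res <- if (!is.null(rate)) rate / N else attr(spec, "resolution")
  if (is.null(res)) stop("supply rate or a spectrum with a resolution attribute")
  nyquist <- res * N / 2
  if (band$high > nyquist + 1e-9)
    stop("band ", band$name, " [", band$low, ",", band$high,
         ") exceeds the Nyquist frequency ", nyquist, " Hz")
  k <- 0:floor(N / 2)
  sel <- k[k * res >= band$low & k * res < band$high]
  if (length(sel) == 0)
    stop("band ", band$name, " contains no frequency bins at resolution ",
         res, " Hz")
  if (is.matrix(spec)) rowMeans(abs(spec[, sel + 1, drop = FALSE]))
  else mean(abs(spec[sel + 1]))
}

#' Per-epoch band-amplitude vectors
#'
#' For every epoch and band, the per-channel mean absolute DFT coefficient
#' over the band's bins.
#'
#' @param eps an `eeg_epochs`.
#' @param bands named list of [band_definition()]s (default
#'   [default_bands()]).
#' @return numeric array n_epochs x channels x bands with dimnames.
#' @export
epoch_band_amplitudes <- function(eps, bands = default_bands()) {
  stopifnot(inherits(eps, "eeg_epochs"))
  d <- dim(eps$epochs)
  out <- array(0, dim = c(d[1], d[2], length(bands)),
               dimnames = list(NULL, eps$channel_names, names(bands)))
  for (e in seq_len(d[1])) {
    X <- dft_epoch(matrix(eps$epochs[e, , ], nrow = d[2]), rate = eps$rate)
    for (b in seq_along(bands))
      out[e, , b] <- band_amplitude(X, bands[[b]], rate = eps$rate)
  }
  out
}
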