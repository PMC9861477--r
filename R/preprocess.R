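#' Resample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-aliasing low-pass) and inverted on the new time
#' grid.  DC is preserved exactly and the output sample count is
#' `floor(n * target_rate / rate)`.  Resampling at the original rate returns
#' the recording unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_rate new rate in Hz; must be positive and not exceed the
#'   recording rate (this is a down-sampler, matching acquisition at a high
#'   native rate followed by analysis at 256 Hz).
#' @return An `eeg_recording` at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a single positive number")
  if (target_rate > rec$rate)
    stop("target_rate (", target_rate, ") exceeds recording rate (", rec$rate, ")")
  if (target_rate == rec$rate) return(rec)
  n <- ncol(rec$data)
  m <- floor(n * target_rate / rec$rate)
  if (m < 1) stop("recording too short to resample")
  X <- t(mvfft(t(rec$data)))              # channels x n spectra
  Y <- matrix(0 + 0i, nrow(X), m)
  half <- floor((m - 1) / 2)
  Y[, 1] <- X[, 1]
  if (half >= 1) {
    Y[, 2:(half + 1)] <- X[, 2:(half + 1)]
    Y[, (m - half + 1):m] <- X[, (n - half + 1):n]
  }
  if (m %% 2 == 0) Y[, m / 2 + 1] <- Re(X[, m / 2 + 1])  # new Nyquist bin
  Y <- Y * (m / n)
  y <- Re(t(mvfft(t(Y), inverse = TRUE))) / m
  recording(y, target_rate, rec$channel_names, rec$patient_id, rec$session)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping segments of `epoch_seconds` (default 1 s,
#' i.e. 256 samples at 256 Hz).  The trailing partial epoch is discarded and
#' the per-channel mean of each epoch is removed (none of the analysed bands
#' reaches DC, and a DC offset would distort coherence estimates).
#'
#' @param rec an `eeg_recording`.
#' @param epoch_seconds epoch length in seconds (default 1).
#' @return An `eeg_epochs` with `n_epochs = floor(samples / (rate *
#'   epoch_seconds))`.
#' @export
segment_epochs <- function(rec, epoch_seconds = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(rec$rate * epoch_seconds)
  n <- ncol(rec$data)
  n_ep <- floor(n / len)
  if (n_ep < 1)
    stop("recording (", n, " samples) shorter than one epoch (", len, " samples)")
  nch <- nrow(rec$data)
  eps <- array(0, dim = c(n_ep, nch, len))
  for (e in seq_len(n_ep)) {
    seg <- rec$data[, ((e - 1) * len + 1):(e * len), drop = FALSE]
    eps[e, , ] <- seg - rowMeans(seg)
  }
  epoch_set(eps, rec$rate, rec$channel_names, rec$patient_id, rec$session)
}
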