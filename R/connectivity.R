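#' Magnitude-squared coherence connectivity matrix
#'
#' For every channel pair (x, y), the squared coherence
#' `Coh_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` is estimated with Welch's
#' method (Hann-windowed overlapping segments, averaged cross- and
#' auto-spectra), averaged over each analysis band's frequency bins, and -
#' for the default `"merged"` tag - averaged over the theta/alpha/beta
#' bands into one channels x channels matrix.  At least two Welch windows
#' are required: single-window coherence is identically 1.
#'
#' @param x numeric channels x samples matrix (one epoch or a longer
#'   concatenated segment), or an `eeg_recording`.
#' @param rate sampling rate in Hz (taken from the recording if given one).
#' @param bands named list of [band_definition()]s (default
#'   [default_bands()]).
#' @param window Welch window length in samples (default 64; at 256 Hz the
#'   frequency resolution is then 4 Hz and a 1-s epoch yields 7 windows).
#' @param overlap fractional window overlap in \[0, 1) (default 0.5).
#' @param tag `"merged"` (mean over bands, default) or the name of a single
#'   band in `bands`.
#' @param channel_names labels for the rows of `x`.
#' @return A `coherence_matrix`: symmetric channels x channels matrix with
#'   unit diagonal and entries in \[0, 1\], with attribute `band`.
#' @export
coherence_matrix <- function(x, rate = NULL, bands = default_bands(),
                             window = 64, overlap = 0.5, tag = "merged",
                             channel_names = NULL) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate; channel_names <- x$channel_names; x <- x$data
  }
  x <- as.matrix(x)
  if (is.null(rate)) stop("rate is required")
  if (is.null(channel_names))
    channel_names <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  n <- ncol(x); nch <- nrow(x)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(window * (1 - overlap)))
  if (n < 2 * window)
    stop("segment (", n, " samples) shorter than two Welch windows (",
         2 * window, ")")
  starts <- seq(1L, n - window + 1L, by = step)
  K <- length(starts)
  if (K < 2) stop("need at least 2 Welch windows")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / (window - 1))  # Hann

  res <- rate / window
  bin_sets <- lapply(bands, function(b) {
    k <- 0:floor(window / 2)
    sel <- k[k * res >= b$low & k * res < b$high]
    if (length(sel) == 0)
      stop("band ", b$name, " has no bins at Welch resolution ", res, " Hz")
    if (b$high > rate / 2 + 1e-9)
      stop("band ", b$name, " exceeds the Nyquist frequency")
    sel + 1L
  })
  use_bands <- if (identical(tag, "merged")) seq_along(bands)
               else which(names(bands) == tag)
  if (length(use_bands) == 0) stop("unknown band tag: ", tag)
  bins <- sort(unique(unlist(bin_sets[use_bands])))

  # windowed FFTs of every channel: window x (K * nch)
  segs <- matrix(0, window, K * nch)
  for (ki in seq_len(K)) {
    seg <- x[, starts[ki]:(starts[ki] + window - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)                      # constant detrend
    segs[, (ki - 1) * nch + seq_len(nch)] <- t(seg) * w
  }
  FF <- mvfft(segs)

  # per analysed bin: averaged cross-spectral matrix and per-bin coherence
  coh_bin <- array(0, dim = c(nch, nch, length(bins)))
  zero_power <- rep(TRUE, nch)
  for (bi in seq_along(bins)) {
    Wf <- matrix(FF[bins[bi], ], nrow = K, byrow = TRUE)   # K x nch
    P <- crossprod(Conj(Wf), Wf) / K                       # nch x nch, P[x,y] = mean conj(X) Y
    pxx <- Re(diag(P))
    zero_power <- zero_power & (pxx < 1e-300)
    denom <- outer(pxx, pxx)
    co <- Mod(P)^2 / ifelse(denom > 0, denom, NA_real_)
    coh_bin[, , bi] <- co
  }
  if (any(zero_power))
    stop("zero-power channel(s) in analysed bands: ",
         paste(channel_names[zero_power], collapse = ", "))

  # band means, then mean over the selected bands
  cm <- matrix(0, nch, nch)
  for (b in use_bands) {
    sel <- match(bin_sets[[b]], bins)
    cm <- cm + apply(coh_bin[, , sel, drop = FALSE], c(1, 2), mean) /
      length(use_bands)
  }
  if (anyNA(cm)) {
    bad <- channel_names[which(apply(is.na(cm), 1, any))]
    stop("coherence undefined (zero power) for channel(s): ",
         paste(bad, collapse = ", "))
  }
  cm <- (cm + t(cm)) / 2
  cm[cm < 0] <- 0; cm[cm > 1] <- 1
  diag(cm) <- 1
  dimnames(cm) <- list(channel_names, channel_names)
  structure(cm, band = if (identical(tag, "merged")) "merged" else tag,
            class = c("coherence_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coherence matrices for every epoch
#'
#' @param eps an `eeg_epochs`.
#' @param ... passed to [coherence_matrix()].
#' @return numeric array n_epochs x channels x channels.
#' @export
epoch_coherence_matrices <- function(eps, ...) {
  stopifnot(inherits(eps, "eeg_epochs"))
  d <- dim(eps$epochs)
  out <- array(0, dim = c(d[1], d[2], d[2]),
               dimnames = list(NULL, eps$channel_names, eps$channel_names))
  for (e in seq_len(d[1]))
    out[e, , ] <- coherence_matrix(matrix(eps$epochs[e, , ], nrow = d[2]),
                                   rate = eps$rate,
                                   channel_names = eps$channel_names, ...)
  out
}

#' Threshold a coherence matrix into a binary graph
#'
#' An (undirected) edge joins two distinct channels when their squared
#' coherence is strictly greater than `tau` (default 0.75, the
#' visualisation threshold); the diagonal is excluded.
#'
#' @param cm a `coherence_matrix`.
#' @param tau threshold in \[0, 1\].
#' @return logical symmetric hollow adjacency matrix with attribute
#'   `edges`: a data frame `ch_a,ch_b,coherence` of the upper-triangle
#'   edges.
#' @export
threshold_graph <- function(cm, tau = 0.75) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]")
  a <- unclass(cm) > tau
  diag(a) <- FALSE
  idx <- which(upper.tri(a) & a, arr.ind = TRUE)
  nm <- rownames(cm) %||% paste0("ch", seq_len(nrow(cm)))
  edges <- data.frame(ch_a = nm[idx[, 1]], ch_b = nm[idx[, 2]],
                      coherence = unclass(cm)[idx], stringsAsFactors = FALSE)
  attr(a, "edges") <- edges
  a
}

#' Average coherence matrices
#'
#' Element-wise mean of matrices with identical shape and band tag (e.g.
#' across epochs or patients); all coherence-matrix invariants are
#' preserved.
#'
#' @param cms list of `coherence_matrix` objects, or an n x ch x ch array.
#' @return A `coherence_matrix`.
#' @export
average_connectivity <- function(cms) {
  if (is.array(cms) && length(dim(cms)) == 3) {
    if (dim(cms)[1] == 0) stop("empty sequence of matrices")
    out <- apply(cms, c(2, 3), mean)
    dimnames(out) <- dimnames(cms)[2:3]
    return(structure(out, band = "merged",
                     class = c("coherence_matrix", "matrix", "array")))
  }
  if (length(cms) == 0) stop("empty sequence of matrices")
  d <- dim(cms[[1]]); tag <- attr(cms[[1]], "band")
  for (m in cms[-1]) {
    if (!identical(dim(m), d)) stop("matrices have different shapes")
    if (!identical(attr(m, "band"), tag)) stop("matrices have different band tags")
  }
  out <- Reduce(`+`, lapply(cms, unclass)) / length(cms)
  structure(out, band = tag, class = c("coherence_matrix", "matrix", "array"))
}

#' Export a coherence matrix / graph
#'
#' @param cm a `coherence_matrix`.
#' @param path output CSV path.
#' @param tau when non-`NULL`, write the edge list of the thresholded graph
#'   instead of the full matrix.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path, tau = NULL) {
  if (is.null(tau)) {
    write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  } else {
    write.csv(attr(threshold_graph(cm, tau), "edges"), path, row.names = FALSE)
  }
  invisible(path)
}
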