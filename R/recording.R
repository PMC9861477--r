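#' EEG recordings and epoch sets
#'
#' A recording is one patient/session multichannel time series; an epoch set
#' is a stack of fixed-length 1-s segments cut from a recording, the unit of
#' classification throughout the package.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channel_names character vector aligned with the rows of `data`.
#' @param patient_id patient identifier.
#' @param session `"pre"` or `"post"`.
#' @return `recording()` returns an object of class `eeg_recording`.
#' @export
recording <- function(data, rate, channel_names, patient_id = "p1",
                      session = c("pre", "post")) {
  session <- match.arg(session)
  data <- as.matrix(data)
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names))
    stop("data has ", nrow(data), " rows but ", length(channel_names),
         " channel names")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- channel_names
  structure(list(patient_id = as.character(patient_id), session = session,
                 rate = rate, data = data, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$session, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

#' Construct an epoch set
#'
#' @param epochs numeric array, n_epochs x channels x epoch_len.
#' @param rate sampling rate in Hz.
#' @param channel_names channel labels aligned with the second dimension.
#' @param patient_id,session provenance carried with every epoch.
#' @return An object of class `eeg_epochs`.
#' @rdname recording
#' @export
epoch_set <- function(epochs, rate, channel_names, patient_id = "p1",
                      session = c("pre", "post")) {
  session <- match.arg(session)
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  if (dim(epochs)[1] < 1L) stop("an epoch set needs at least one epoch")
  if (dim(epochs)[2] != length(channel_names))
    stop("epoch channel dimension does not match channel_names")
  structure(list(epochs = epochs, rate = rate, epoch_len = dim(epochs)[3],
                 channel_names = as.character(channel_names),
                 patient_id = as.character(patient_id), session = session),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s/%s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$patient_id, x$session, dim(x$epochs)[1], dim(x$epochs)[2],
              x$epoch_len, x$rate))
  invisible(x)
}

#' Write / read recordings in the package array dialect
#'
#' Recordings are stored as a single RDS file holding the plain list
#' `{data, rate, channel_names, patient_id, session}`; the reader also
#' accepts EDF-free plain-text export (`.csv` of samples with a JSON
#' side-car) produced by [write_recording()] with `format = "csv"`.
#'
#' @param rec an `eeg_recording`.
#' @param path output path (`.rds`, or `.csv` when `format = "csv"`).
#' @param format `"rds"` (default) or `"csv"`.
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path, format = c("rds", "csv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(unclass(rec), path)
  } else {
    write.csv(data.frame(channel = rec$channel_names, rec$data,
                         check.names = FALSE, row.names = NULL),
              path, row.names = FALSE)
    meta <- list(rate = rec$rate, patient_id = rec$patient_id,
                 session = rec$session)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    x <- readRDS(path)
    return(recording(x$data, x$rate, x$channel_names, x$patient_id, x$session))
  }
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recording(as.matrix(df[, -1, drop = FALSE]), meta$rate, df$channel,
            meta$patient_id, meta$session)
}

#' Read a behavioural table
#'
#' Expects a CSV with columns `patient_id,tfi_baseline,tfi_post`.
#'
#' @param path CSV path.
#' @return data frame with those three columns.
#' @export
read_behavioural <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tfi_baseline", "tfi_post")
  if (!all(need %in% names(df)))
    stop("behavioural table must have columns ", paste(need, collapse = ","))
  df[, need]
}
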