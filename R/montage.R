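#' Electrode montages
#'
#' A montage records the channel names and idealised unit-sphere electrode
#' coordinates of an EEG cap.  The packaged default is a 64-channel extended
#' international 10/20 layout (BioSemi label set) with the vertex electrode
#' Cz at the top of the sphere.
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions_3d numeric matrix (channels x 3) of unit-sphere
#'   coordinates; rows must have non-zero norm.
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `name`, `x`, `y`, `z`.
#' @examples
#' m <- default_montage()
#' nrow(m)  # 64
#' @export
montage <- function(channel_names, positions_3d) {
  channel_names <- as.character(channel_names)
  positions_3d <- as.matrix(positions_3d)
  if (length(channel_names) < 3L)
    stop("a montage needs at least 3 channels")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (nrow(positions_3d) != length(channel_names) || ncol(positions_3d) != 3L)
    stop("positions_3d must be a (channels x 3) matrix aligned with channel_names")
  if (!all(is.finite(positions_3d)))
    stop("electrode coordinates must be finite")
  if (any(sqrt(rowSums(positions_3d^2)) < 1e-9))
    stop("electrode coordinates must have non-zero norm")
  out <- data.frame(name = channel_names,
                    x = positions_3d[, 1], y = positions_3d[, 2], z = positions_3d[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Read a montage from a CSV file
#'
#' The file format is plain CSV with header `name,x,y,z`, one row per
#' channel, coordinates on (or near) the unit sphere.
#'
#' @param path path to the montage CSV.
#' @return An `eeg_montage` (see [montage()]); row order is preserved.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage file must have columns name,x,y,z")
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(xyz)) stop("montage coordinates must be numeric")
  montage(df$name, xyz)
}

#' Write a montage to CSV
#'
#' Inverse of [load_montage()]; a write/load round trip reproduces names and
#' coordinates exactly.
#'
#' @param m an `eeg_montage`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  df <- as.data.frame(m)
  # full precision so the round trip is bit-exact
  txt <- c("name,x,y,z",
           sprintf("%s,%s,%s,%s", df$name,
                   formatC(df$x, format = "g", digits = 17),
                   formatC(df$y, format = "g", digits = 17),
                   formatC(df$z, format = "g", digits = 17)))
  writeLines(txt, path)
  invisible(path)
}

#' The packaged 64-channel extended 10/20 montage
#'
#' Idealised spherical coordinates for the 64-label BioSemi-style extended
#' 10/20 layout (Fp1 ... O2, including the FC/CP/AF/PO rows, P9/P10 and Iz).
#'
#' @return An `eeg_montage` with 64 channels.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_10_20_64.csv", package = "eegoutcome")
  load_montage(path)
}

#' Project electrodes to the plane
#'
#' Azimuthal-equidistant projection from the vertex: an electrode at
#' inclination theta (radians from the +z axis) maps to planar radius
#' `theta / (pi/2)`, preserving its azimuth.  Cz (the vertex) maps to the
#' origin and left/right mirror-symmetric electrodes get mirrored x
#' coordinates.
#'
#' @param m an `eeg_montage`.
#' @return numeric matrix (channels x 2) with columns `x`, `y` and row names
#'   set to the channel names.
#' @export
project_to_2d <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  xyz <- as.matrix(m[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  theta <- acos(pmin(1, pmax(-1, xyz[, 3])))
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  r2 <- theta / (pi / 2)
  u <- cbind(ifelse(rho < 1e-12, 0, xyz[, 1] / rho),
             ifelse(rho < 1e-12, 0, xyz[, 2] / rho))
  out <- cbind(x = r2 * u[, 1], y = r2 * u[, 2])
  rownames(out) <- m$name
  d <- as.matrix(stats::dist(out))
  diag(d) <- Inf
  if (min(d) < 1e-9) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    stop("electrodes project to coincident points: ",
         m$name[ij[1]], " and ", m$name[ij[2]])
  }
  out
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", nrow(x), " channels: ",
      paste(head(x$name, 6), collapse = ", "),
      if (nrow(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
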