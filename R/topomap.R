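#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson triangulation, used to build the scalp
#' interpolation grid.  Exactly co-circular point sets (the electrode rings
#' of an idealised montage) are handled by a tiny deterministic
#' symmetry-breaking perturbation applied during triangulation only; the
#' returned triangle list is a valid triangulation of the original points.
#'
#' @param pts numeric matrix (n x 2), n >= 3, not all collinear.
#' @return integer matrix (n_triangles x 3) of row indices into `pts`.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate point set")
  # collinearity check on the raw points (cross products with the first edge)
  if (all(abs((pts[, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2]) -
              (pts[, 2] - pts[1, 2]) * (pts[2, 1] - pts[1, 1])) <
          1e-9 * scale^2))
    stop("points are collinear; cannot triangulate")
  # deterministic jitter breaks co-circular ties
  jit <- matrix(sin(1e4 * seq_len(2 * n)) * 1e-7 * scale, ncol = 2)
  p <- pts + jit

  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  r <- 20 * scale
  super <- rbind(c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  p <- rbind(p, super)
  si <- n + 1:3

  circum <- function(tri) {
    a <- p[tri[1], ]; b <- p[tri[2], ]; c <- p[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }

  tris <- list(si)
  ccs <- list(circum(si))
  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    bad <- which(vapply(ccs, function(cc)
      (px - cc[1])^2 + (py - cc[2])^2 < cc[3] * (1 - 1e-12), logical(1)))
    # boundary = edges of the cavity appearing exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(c(tr[1], tr[2])), sort(c(tr[2], tr[3])), sort(c(tr[3], tr[1])))))
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris[bad] <- NULL; ccs[bad] <- NULL
    for (k in seq_len(nrow(keep))) {
      tr <- c(keep[k, ], i)
      tris[[length(tris) + 1]] <- tr
      ccs[[length(ccs) + 1]] <- circum(tr)
    }
  }
  out <- do.call(rbind, tris)
  out <- out[!apply(out, 1, function(tr) any(tr %in% si)), , drop = FALSE]
  # orient counter-clockwise
  for (k in seq_len(nrow(out))) {
    a <- pts[out[k, 1], ]; b <- pts[out[k, 2], ]; c <- pts[out[k, 3], ]
    if ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]) < 0)
      out[k, ] <- out[k, c(1, 3, 2)]
  }
  unname(out)
}

#' Precompute the topographic interpolation operator
#'
#' For a fixed electrode layout and grid size, pixel values are a linear map
#' of the per-electrode values: each in-hull pixel takes the barycentric
#' (piecewise-linear) interpolant of its Delaunay triangle's vertex values,
#' out-of-hull pixels take the fill value.  The operator is computed once
#' and reused for every epoch/band.
#'
#' @param coords planar electrode coordinates (channels x 2), e.g. from
#'   [project_to_2d()].
#' @param grid_size pixels per side (default 32).
#' @param margin fractional margin added around the electrode bounding
#'   square (default 0.05).
#' @return list with `weights` (grid_size^2 x channels matrix), `mask`
#'   (logical grid_size x grid_size, TRUE inside the hull), `grid_x`,
#'   `grid_y`, `triangles`, and `pixel_triangle` (triangle index per pixel,
#'   NA outside).
#' @export
topomap_operator <- function(coords, grid_size = 32, margin = 0.05) {
  coords <- as.matrix(coords)
  nch <- nrow(coords)
  tri <- delaunay_triangulation(coords)
  lo <- min(coords); hi <- max(coords)
  m <- margin * (hi - lo)
  g <- seq(lo - m, hi + m, length.out = grid_size)
  px <- rep(g, times = grid_size)          # x varies within a column-block
  py <- rep(g, each = grid_size)
  npix <- grid_size^2
  W <- matrix(0, npix, nch)
  owner <- rep(NA_integer_, npix)
  for (k in seq_len(nrow(tri))) {
    a <- coords[tri[k, 1], ]; b <- coords[tri[k, 2], ]; c <- coords[tri[k, 3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    l1 <- ((b[2] - c[2]) * (px - c[1]) + (c[1] - b[1]) * (py - c[2])) / det
    l2 <- ((c[2] - a[2]) * (px - c[1]) + (a[1] - c[1]) * (py - c[2])) / det
    l3 <- 1 - l1 - l2
    inside <- is.na(owner) & l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(inside)) {
      owner[inside] <- k
      W[cbind(which(inside), tri[k, 1])] <- l1[inside]
      W[cbind(which(inside), tri[k, 2])] <- l2[inside]
      W[cbind(which(inside), tri[k, 3])] <- l3[inside]
    }
  }
  mask <- matrix(!is.na(owner), grid_size, grid_size)  # [x index, y index]
  list(weights = W, mask = mask, grid_x = g, grid_y = g,
       triangles = tri, pixel_triangle = matrix(owner, grid_size, grid_size))
}

#' Interpolate one topographic image
#'
#' @param values per-channel values (length = rows of `coords`).
#' @param coords planar electrode coordinates (channels x 2).
#' @param grid_size pixels per side (default 32).
#' @param fill value for pixels outside the electrode convex hull
#'   (default 0).
#' @param op optional precomputed [topomap_operator()] for these coords.
#' @param tag band tag stored on the image (e.g. `"alpha"`, `"merged"`).
#' @return `grid_size x grid_size` matrix of class `topomap_image` with
#'   attributes `mask`, `fill` and `band`.  The first index is the x
#'   (left-right) pixel, the second the y (posterior-anterior) pixel.
#' @export
interpolate_topomap <- function(values, coords, grid_size = 32, fill = 0,
                                op = NULL, tag = "band") {
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords))
    stop("values (", length(values), ") and coords (", nrow(coords),
         ") lengths differ")
  if (!all(is.finite(values))) stop("non-finite electrode values")
  if (is.null(op)) op <- topomap_operator(coords, grid_size)
  img <- matrix(op$weights %*% values, grid_size, grid_size)
  img[!op$mask] <- fill
  structure(img, mask = op$mask, fill = fill, band = tag,
            class = c("topomap_image", "matrix", "array"))
}

#' Merge per-band topographic images
#'
#' Pixel-wise arithmetic mean of the (theta, alpha, beta) images; the output
#' carries the tag `"merged"`.
#'
#' @param theta,alpha,beta `topomap_image`s on the same grid and hull mask.
#' @return `topomap_image` tagged `"merged"`.
#' @export
merge_band_images <- function(theta, alpha, beta) {
  imgs <- list(theta, alpha, beta)
  d <- dim(imgs[[1]])
  for (im in imgs[-1]) {
    if (!identical(dim(im), d)) stop("band images have different sizes")
    if (!identical(attr(im, "mask"), attr(imgs[[1]], "mask")))
      stop("band images have different hull masks")
  }
  out <- (unclass(theta) + unclass(alpha) + unclass(beta)) / 3
  structure(out, mask = attr(theta, "mask"), fill = attr(theta, "fill"),
            band = "merged", class = class(theta))
}

#' Topographic images for every epoch
#'
#' Composition of the spectral and interpolation steps: per epoch, the DFT
#' band-mean amplitudes of each channel are interpolated over the scalp for
#' each band and the three band images are averaged into one merged
#' `grid_size x grid_size` image, the classifier input.
#'
#' @param eps an `eeg_epochs` whose channels cover the montage.
#' @param m an `eeg_montage`.
#' @param bands named list of three [band_definition()]s.
#' @param grid_size pixels per side (default 32).
#' @param normalize if `TRUE`, apply global min-max scaling fitted on the
#'   images indexed by `fit_idx` (all images when `NULL`).  Fitting on the
#'   training subset only avoids test-set leakage; per-image scaling is
#'   deliberately not offered because it would erase the between-group
#'   amplitude differences the classifier relies on.
#' @param fit_idx integer indices of the images used to fit the scaling.
#' @return numeric array n_epochs x grid_size x grid_size with attributes
#'   `mask` and (when normalized) `norm_range`.
#' @export
epochs_to_images <- function(eps, m, bands = default_bands(), grid_size = 32,
                             normalize = FALSE, fit_idx = NULL) {
  stopifnot(inherits(eps, "eeg_epochs"), inherits(m, "eeg_montage"))
  if (!setequal(eps$channel_names, m$name))
    stop("epoch channels do not match the montage")
  perm <- match(m$name, eps$channel_names)
  amps <- epoch_band_amplitudes(eps, bands)[, perm, , drop = FALSE]
  op <- topomap_operator(project_to_2d(m), grid_size)
  n <- dim(amps)[1]
  flat <- matrix(0, grid_size^2, n)
  for (b in seq_along(bands)) {
    fb <- op$weights %*% t(matrix(amps[, , b], nrow = n))
    fb[!op$mask, ] <- 0
    flat <- flat + fb / length(bands)
  }
  out <- array(0, dim = c(n, grid_size, grid_size))
  for (e in seq_len(n)) out[e, , ] <- matrix(flat[, e], grid_size, grid_size)
  attr(out, "mask") <- op$mask
  if (normalize) {
    idx <- if (is.null(fit_idx)) seq_len(n) else fit_idx
    rng <- range(out[idx, , ])
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    out2 <- (out - rng[1]) / (rng[2] - rng[1])
    attr(out2, "mask") <- op$mask
    attr(out2, "norm_range") <- rng
    return(out2)
  }
  out
}
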