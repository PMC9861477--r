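test_that("the DFT matches its closed forms", {
  # constant input: all energy in the k = 0 bin
  X <- dft_epoch(rep(3, 256), rate = 256)
  expect_equal(Mod(X[1]), 256 * 3, tolerance = 1e-9)
  expect_lt(max(Mod(X[-1])), 1e-9)
  # integer-frequency cosine: two conjugate bins of height N/2
  x <- cos(2 * pi * 10 * (0:255) / 256)
  X <- dft_epoch(x, rate = 256)
  expect_equal(Mod(X[11]), 128, tolerance = 1e-9)   # k = 10
  expect_equal(Mod(X[247]), 128, tolerance = 1e-9)  # k = 246
  expect_lt(max(Mod(X[-c(11, 247)])), 1e-9)
  expect_error(dft_epoch(c(1, NA, 2)), "non-finite")
  expect_error(dft_epoch(1), "at least 2")
})

test_that("the FFT equals the direct quadratic-time transform", {
  direct_dft <- function(x) {
    N <- length(x)
    vapply(0:(N - 1), function(k)
      sum(x * exp(-1i * 2 * pi * k * (0:(N - 1)) / N)), complex(1))
  }
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(16)
    expect_lt(max(Mod(dft_epoch(x) - direct_dft(x))), 1e-9)
  }
})

test_that("Parseval's identity holds for random epochs", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(256)
    X <- dft_epoch(x)
    expect_lt(abs(sum(x^2) - sum(Mod(X)^2) / 256) / sum(x^2), 1e-9)
  }
})

test_that("band amplitudes average |X_k| over half-open positive-frequency bins", {
  bands <- default_bands()
  x <- cos(2 * pi * 10 * (0:255) / 256)
  X <- dft_epoch(x, rate = 256)
  expect_equal(band_amplitude(X, bands$alpha), 128 / 6, tolerance = 1e-9)
  expect_equal(band_amplitude(X, bands$theta), 0, tolerance = 1e-9)
  expect_equal(band_amplitude(dft_epoch(rep(0, 256), rate = 256),
                              bands$beta), 0)
  # an 8 Hz tone belongs to alpha (half-open boundary), not theta
  x8 <- cos(2 * pi * 8 * (0:255) / 256)
  X8 <- dft_epoch(x8, rate = 256)
  expect_equal(band_amplitude(X8, bands$theta), 0, tolerance = 1e-9)
  expect_gt(band_amplitude(X8, bands$alpha), 0)
  expect_error(band_amplitude(X, band_definition("high", 100, 200), 256),
               "Nyquist")
})

test_that("the montage triangulation tiles the convex hull exactly", {
  xy <- project_to_2d(default_montage())
  tri <- delaunay_triangulation(xy)
  area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  tri_area <- sum(apply(tri, 1, function(t)
    area(xy[t[1], ], xy[t[2], ], xy[t[3], ])))
  h <- chull(xy); hxy <- xy[h, ]; n <- nrow(hxy); hull_area <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    hull_area <- hull_area + hxy[i, 1] * hxy[j, 2] - hxy[j, 1] * hxy[i, 2]
  }
  expect_equal(tri_area, abs(hull_area) / 2, tolerance = 1e-9)
  expect_error(delaunay_triangulation(cbind(1:5, 2 * (1:5) + 1)), "collinear")
})

test_that("interpolation is exact for constants and at triangle centroids", {
  xy <- project_to_2d(default_montage())
  img <- interpolate_topomap(rep(4, 64), xy)
  mask <- attr(img, "mask")
  expect_true(all(abs(img[mask] - 4) < 1e-9))
  expect_true(all(img[!mask] == 0))

  # single triangle with values (0, 0, 3): centroid interpolates to 1
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  op <- topomap_operator(coords, grid_size = 64, margin = 0)
  centroid <- colMeans(coords)
  ix <- which.min(abs(op$grid_x - centroid[1]))
  iy <- which.min(abs(op$grid_y - centroid[2]))
  # use the operator weights at the nearest grid node to the centroid
  w <- op$weights[(iy - 1) * 64 + ix, ]
  pt <- c(op$grid_x[ix], op$grid_y[iy])
  expect_equal(sum(w * c(0, 0, 3)),
               3 * (1 - pt[1] - pt[2]) * 0 + 0 * pt[1] + 3 * pt[2],
               tolerance = 1e-9)
  expect_error(interpolate_topomap(rep(1, 3), coords[1:2, ]))
  expect_error(interpolate_topomap(c(1, NA, 2), coords), "non-finite")
})

test_that("interpolated pixels match an independent plane-equation oracle", {
  xy <- project_to_2d(default_montage())
  op <- topomap_operator(xy, grid_size = 32)
  set.seed(99)
  v <- runif(64, 0, 10)
  img <- interpolate_topomap(v, xy, op = op)
  # oracle: for each in-hull pixel, solve the plane through its triangle's
  # vertices and evaluate it at the pixel centre
  for (px in seq(1, 32, by = 3)) for (py in seq(1, 32, by = 3)) {
    k <- op$pixel_triangle[px, py]
    if (is.na(k)) next
    tr <- op$triangles[k, ]
    A <- cbind(1, xy[tr, 1], xy[tr, 2])
    coef <- solve(A, v[tr])
    want <- coef[1] + coef[2] * op$grid_x[px] + coef[3] * op$grid_y[py]
    expect_lt(abs(img[px, py] - want), 1e-9)
  }
})

test_that("band images merge by pixel-wise mean", {
  xy <- project_to_2d(default_montage())
  op <- topomap_operator(xy, 32)
  A <- interpolate_topomap(runif(64), xy, op = op, tag = "theta")
  B <- interpolate_topomap(runif(64), xy, op = op, tag = "beta")
  same <- merge_band_images(A, A, A)
  expect_equal(as.numeric(same), as.numeric(A), tolerance = 1e-12)
  expect_identical(attr(same, "band"), "merged")
  m <- merge_band_images(A, A, B)
  expect_equal(as.numeric(m), as.numeric((2 * unclass(A) + unclass(B)) / 3),
               tolerance = 1e-12)
  c0 <- interpolate_topomap(rep(0, 64), xy, op = op)
  c2 <- interpolate_topomap(rep(2, 64), xy, op = op)
  c4 <- interpolate_topomap(rep(4, 64), xy, op = op)
  mm <- merge_band_images(c0, c2, c4)
  expect_true(all(abs(mm[attr(mm, "mask")] - 2) < 1e-12))
  A16 <- interpolate_topomap(runif(64), xy, grid_size = 16)
  expect_error(merge_band_images(A, A, A16), "different sizes")
})

test_that("the image pipeline preserves epoch count and responds to signal", {
  fx <- tiny_cohort()
  m <- fx$cfg$montage
  eps <- segment_epochs(fx$cohort$recordings[["p01"]]$pre)
  imgs <- epochs_to_images(eps, m)
  expect_equal(dim(imgs), c(10, 32, 32))
  # zero signal gives all-zero images
  zero <- epoch_set(array(0, c(2, 64, 256)), 256, m$name)
  expect_true(all(epochs_to_images(zero, m) == 0))
  # scaling the samples by c > 0 scales every pixel by c
  eps2 <- eps; eps2$epochs <- eps$epochs * 2.5
  expect_equal(epochs_to_images(eps2, m), imgs * 2.5, tolerance = 1e-9)
})

test_that("the image pipeline is channel-permutation safe", {
  fx <- tiny_cohort()
  m <- fx$cfg$montage
  eps <- segment_epochs(fx$cohort$recordings[["p01"]]$pre)
  imgs <- epochs_to_images(eps, m)
  perm <- sample(64)
  eps_p <- epoch_set(eps$epochs[, perm, , drop = FALSE], 256,
                     eps$channel_names[perm])
  expect_equal(epochs_to_images(eps_p, m), imgs, tolerance = 0)
  bad <- epoch_set(eps$epochs[, 1:63, , drop = FALSE], 256,
                   eps$channel_names[1:63])
  expect_error(epochs_to_images(bad, m), "montage")
})

test_that("group-dependent alpha power shows up in the group-mean images", {
  fx <- tiny_cohort()
  m <- fx$cfg$montage
  coh <- fx$cohort
  mean_img <- function(ids) {
    imgs <- lapply(ids, function(id)
      epochs_to_images(segment_epochs(coh$recordings[[id]]$pre), m))
    Reduce(`+`, lapply(imgs, function(x) apply(x, c(2, 3), mean))) / length(ids)
  }
  resp <- mean_img(coh$outcomes$patient_id[coh$outcomes$group == "responder"])
  nonr <- mean_img(coh$outcomes$patient_id[coh$outcomes$group == "non_responder"])
  expect_gt(mean(resp), mean(nonr) * 1.5)
})

test_that("min-max normalization is fitted on the designated subset", {
  fx <- tiny_cohort()
  eps <- segment_epochs(fx$cohort$recordings[["p01"]]$pre)
  imgs <- epochs_to_images(eps, fx$cfg$montage, normalize = TRUE,
                           fit_idx = 1:5)
  rng <- attr(imgs, "norm_range")
  expect_equal(range(imgs[1:5, , ]), c(0, 1), tolerance = 1e-12)
  raw <- epochs_to_images(eps, fx$cfg$montage)
  expect_equal(rng, range(raw[1:5, , ]))
})
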