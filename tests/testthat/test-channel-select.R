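make_amp <- function(values, channels, session = "pre") {
  m <- matrix(values, nrow = length(channels),
              dimnames = list(channels, NULL))
  structure(m, session = session,
            class = c("amplitude_matrix", "matrix", "array"))
}

test_that("amplitude summaries are the time-mean absolute voltage", {
  ch <- c("Fz", "Cz", "Pz")
  t1 <- (0:25599) / 256                      # 100 s, whole cycles of 10 Hz
  recs <- list(p1 = list(
    pre = recording(rbind(rep(2, 25600), sin(2 * pi * 10 * t1),
                          rep(0, 25600)), 256, ch, "p1", "pre"),
    post = recording(matrix(1, 3, 25600), 256, ch, "p1", "post")))
  amp <- amplitude_summary(recs, "pre")
  expect_equal(amp["Fz", 1], 2)
  expect_equal(amp["Cz", 1], 2 / pi, tolerance = 1e-3)
  expect_equal(amp["Pz", 1], 0)
  expect_equal(attr(amp, "session"), "pre")
  # mismatching channels across patients
  recs$p2 <- list(pre = recording(matrix(1, 3, 256), 256,
                                  c("Fz", "Cz", "Oz"), "p2", "pre"))
  expect_error(amplitude_summary(recs, "pre"), "mismatch")
})

test_that("the greatest-change statistic matches its hand-computed example", {
  # rows: ch1 = (1,3), ch2 = (5,5), ch3 = (2,0)
  pre <- make_amp(rbind(c(1, 3), c(5, 5), c(2, 0)), c("ch1", "ch2", "ch3"))
  post <- make_amp(rbind(c(2, 4), c(5, 5), c(6, 8)), c("ch1", "ch2", "ch3"),
                   "post")
  r <- gccs_scores(pre, post)
  expect_equal(r$channel, c("ch3", "ch1", "ch2"))
  expect_equal(r$score, c(6, 1, 0))
  expect_identical(attr(r, "method"), "GCCS")
})

test_that("greatest-change scores match a loop-based evaluation exactly", {
  oracle <- function(pre, post, signed = FALSE) {
    M <- ncol(pre)
    e <- numeric(nrow(pre))
    for (i in seq_len(nrow(pre))) {
      acc <- 0
      for (j in seq_len(M)) {
        d <- pre[i, j] - post[i, j]
        acc <- acc + if (signed) d else abs(d)
      }
      e[i] <- acc / M
    }
    e
  }
  set.seed(13)
  for (rep in 1:10) {
    nch <- sample(3:8, 1); M <- sample(1:4, 1)
    ch <- paste0("c", seq_len(nch))
    pre <- make_amp(matrix(runif(nch * M, 0, 5), nch), ch)
    post <- make_amp(matrix(runif(nch * M, 0, 5), nch), ch, "post")
    for (signed in c(FALSE, TRUE)) {
      r <- gccs_scores(pre, post, signed = signed)
      e <- oracle(unclass(pre), unclass(post), signed)
      expect_identical(r$score, e[match(r$channel, ch)])
      expect_setequal(r$channel, ch)
    }
  }
})

test_that("greatest-change scores are homogeneous, tie-stable, and patient-order invariant", {
  set.seed(14)
  ch <- paste0("c", 1:6)
  pre <- make_amp(matrix(runif(24), 6), ch)
  post <- make_amp(matrix(runif(24), 6), ch, "post")
  r1 <- gccs_scores(pre, post)
  # scaling all amplitudes scales scores, leaves order unchanged
  r2 <- gccs_scores(make_amp(unclass(pre) * 3, ch),
                    make_amp(unclass(post) * 3, ch, "post"))
  expect_equal(r2$score, r1$score * 3)
  expect_identical(r2$channel, r1$channel)
  # permuting patients (columns) leaves every score unchanged
  perm <- c(3, 1, 4, 2)
  r3 <- gccs_scores(make_amp(unclass(pre)[, perm], ch),
                    make_amp(unclass(post)[, perm], ch, "post"))
  expect_identical(r3$score, r1$score)
  # pre == post: all-zero scores, montage order
  r0 <- gccs_scores(pre, pre)
  expect_identical(r0$channel, ch)
  expect_true(all(r0$score == 0))
  expect_error(gccs_scores(pre, make_amp(matrix(1, 5, 4), paste0("d", 1:5))),
               "shapes")
})

test_that("F-regression ranks uncorrelated channels above change-free ones", {
  set.seed(15)
  M <- 50
  ch <- c("stable", "noisy", "flat")
  pre_v <- runif(M, 1, 2)
  pre <- make_amp(rbind(pre_v, runif(M, 1, 2), rep(1, M)), ch)
  post <- make_amp(rbind(pre_v, runif(M, 1, 2), rep(1, M)), ch, "post")
  expect_message(r <- fr_scores(pre, post), "flat")
  expect_equal(r$channel[1], "noisy")     # independent pre/post: large p
  expect_equal(r$channel[3], "flat")      # zero variance: ranked last
  expect_lt(r$score[match("stable", r$channel)], 1e-10)
  expect_error(fr_scores(pre[, 1:2], post[, 1:2]), "at least 3")
})

test_that("tree-ensemble importance finds a planted predictive channel", {
  set.seed(16)
  M <- 100
  ch <- paste0("c", 1:6)
  pre <- matrix(runif(6 * M, 1, 2), 6, dimnames = list(ch, NULL))
  # the response is each patient's mean |pre - post|; make channel c4's pre
  # amplitude drive it
  delta <- 3 * (pre["c4", ] - 1)
  post <- pre + matrix(rep(delta, each = 6), 6) / 6 +
    matrix(rnorm(6 * M, 0, 0.01), 6)
  pre_a <- make_amp(pre, ch); post_a <- make_amp(post, ch, "post")
  for (method in c("RF", "ET")) {
    r <- tree_scores(pre_a, post_a, method, seed = 21)
    expect_equal(r$channel[1], "c4")
    r2 <- tree_scores(pre_a, post_a, method, seed = 21)
    expect_identical(r, r2)                 # seeded determinism
  }
  # all-constant input: uniform zero importance, montage order
  const <- make_amp(matrix(1, 6, 10), ch)
  rc <- tree_scores(const, const, "RF", seed = 1)
  expect_identical(rc$channel, ch)
  expect_true(all(rc$score == 0))
  expect_error(tree_scores(pre_a[, 1, drop = FALSE],
                           post_a[, 1, drop = FALSE], "RF"), "at least 2")
})

test_that("recursive elimination keeps the informative channel to the end", {
  set.seed(17)
  M <- 100
  ch <- paste0("c", 1:6)
  pre <- matrix(runif(6 * M, 1, 2), 6, dimnames = list(ch, NULL))
  delta <- 3 * (pre["c2", ] - 1)
  post <- pre + matrix(rep(delta, each = 6), 6) / 6 +
    matrix(rnorm(6 * M, 0, 0.01), 6)
  pre_a <- make_amp(pre, ch); post_a <- make_amp(post, ch, "post")
  r <- rfe_scores(pre_a, post_a, "RF", n_keep = 1, seed = 31)
  expect_equal(r$channel[1], "c2")          # sole survivor
  expect_setequal(r$channel, ch)
  expect_identical(r, rfe_scores(pre_a, post_a, "RF", n_keep = 1, seed = 31))
  # no elimination: a permutation with all-zero elimination scores
  r6 <- rfe_scores(pre_a, post_a, "RF", n_keep = 6, seed = 31)
  expect_setequal(r6$channel, ch)
  expect_true(all(r6$score == 0))
  expect_error(rfe_scores(pre_a, post_a, "RF", n_keep = 0), "n_keep")
})

test_that("rankings are always montage permutations on simulated cohorts", {
  fx <- tiny_cohort()
  pre <- amplitude_summary(fx$cohort$recordings, "pre")
  post <- amplitude_summary(fx$cohort$recordings, "post")
  for (r in list(gccs_scores(pre, post),
                 fr_scores(pre, post),
                 tree_scores(pre, post, "RF", seed = 2, num_trees = 100))) {
    expect_setequal(r$channel, fx$cfg$montage$name)
    expect_equal(nrow(r), 64)
    expect_equal(r$rank, 1:64)
  }
})

test_that("channel subsetting restricts, reorders, and validates", {
  fx <- tiny_cohort()
  rec <- fx$cohort$recordings[["p01"]]$pre
  keep <- c("Cz", "Fz", "P8")
  sub <- subset_channels(rec, keep, m = fx$cfg$montage)
  expect_identical(sub$channel_names, keep)
  expect_equal(sub$data, rec$data[keep, ])
  expect_identical(attr(sub, "montage")$name, keep)
  all64 <- subset_channels(rec, rec$channel_names)
  expect_equal(all64$data, rec$data)
  eps <- segment_epochs(rec)
  sub_e <- subset_channels(eps, keep)
  expect_equal(dim(sub_e$epochs), c(10, 3, 256))
  expect_equal(sub_e$epochs[3, 2, ], eps$epochs[3, match("Fz", eps$channel_names), ])
  expect_error(subset_channels(rec, c("Cz", "XX9")), "XX9")
  expect_error(subset_channels(rec, character(0)), "non-empty")
})

test_that("rankings export with their method tag", {
  pre <- make_amp(rbind(c(1, 2), c(3, 4)), c("a", "b"))
  post <- make_amp(rbind(c(2, 2), c(3, 4)), c("a", "b"), "post")
  f <- tempfile(fileext = ".csv")
  write_ranking(gccs_scores(pre, post), f)
  df <- read.csv(f)
  expect_identical(names(df), c("rank", "channel", "score", "method"))
  expect_true(all(df$method == "GCCS"))
})
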