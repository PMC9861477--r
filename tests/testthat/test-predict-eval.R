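# quick separable toy features: two Gaussian blobs in 16 dimensions
toy_features <- function(n_per_class = 30, width = 16, shift = 3, seed = 1) {
  with_seed <- get("with_seed", asNamespace("eegoutcome"))
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * width), n_per_class),
               matrix(rnorm(n_per_class * width, mean = shift), n_per_class))
    list(x = x, labels = rep(c("non_responder", "responder"),
                             each = n_per_class))
  })
}

test_that("the 8:2 split reproduces the documented sample counts", {
  labels <- rep(c("non_responder", "responder"), c(3000, 3642))
  sp <- split_data(labels, split_plan(seed = 1))
  expect_length(sp$train, 5314)
  expect_length(sp$test, 1328)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # stratification: class ratio in train within one sample of global
  for (cl in unique(labels)) {
    want <- sum(labels == cl) * 0.8
    expect_lt(abs(sum(labels[sp$train] == cl) - want), 1)
  }
  sp10 <- split_data(rep(c("responder", "non_responder"), 5),
                     split_plan(seed = 2))
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)
})

test_that("splits are seed-deterministic and validate inputs", {
  labels <- rep(c("responder", "non_responder"), 50)
  s1 <- split_data(labels, split_plan(seed = 7))
  s2 <- split_data(labels, split_plan(seed = 7))
  expect_identical(s1, s2)
  s3 <- split_data(labels, split_plan(seed = 8))
  expect_false(identical(s1$train, s3$train))
  expect_error(split_data(c("responder", "responder", "non_responder")),
               "2 samples per class")
  expect_error(split_plan(ratio = 1), "\\(0, 1\\)")
})

test_that("patient-unit splits keep all epochs of a patient on one side", {
  patients <- rep(sprintf("p%02d", 1:10), each = 20)
  labels <- rep(rep(c("responder", "non_responder"), each = 5), each = 20)
  sp <- split_data(labels, split_plan(unit = "patient", seed = 3), patients)
  train_p <- unique(patients[sp$train])
  test_p <- unique(patients[sp$test])
  expect_length(intersect(train_p, test_p), 0)
  expect_setequal(unique(labels[sp$train]), c("responder", "non_responder"))
  expect_setequal(unique(labels[sp$test]), c("responder", "non_responder"))
  # 1 patient per class cannot be split
  p2 <- rep(c("a", "b"), each = 10)
  l2 <- rep(c("responder", "non_responder"), each = 10)
  expect_error(split_data(l2, split_plan(unit = "patient", seed = 1), p2),
               "absent")
})

test_that("confusion metrics reproduce the published worked examples", {
  m <- confusion_metrics(matrix(c(533, 5, 9, 782), 2))
  expect_equal(unname(m$per_class_accuracy[1]), 99.07)
  expect_equal(unname(m$per_class_accuracy[2]), 98.86)
  expect_equal(m$overall_accuracy, 98.95)   # 1315/1329
  expect_equal(m$specificity, 99.07)
  expect_equal(m$sensitivity, 98.86)
  # row-wise (precision) ratios exposed alongside
  expect_equal(unname(m$row_wise[1]), round(533 / 542 * 100, 2))

  m2 <- confusion_metrics(matrix(c(138, 1, 1, 202), 2))
  expect_equal(unname(m2$per_class_accuracy[1]), 99.28)
  expect_equal(unname(m2$per_class_accuracy[2]), 99.51)
  expect_equal(m2$overall_accuracy, 99.42)

  perfect <- confusion_metrics(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(perfect$sensitivity, 100)

  # a class absent from the truth: its recall is NA, not 0
  m3 <- confusion_metrics(matrix(c(10, 2, 0, 0), 2))
  expect_true(is.na(m3$sensitivity))
  expect_false(is.na(m3$specificity))
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
  expect_error(confusion_metrics(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("an untrained network predicts the uniform distribution", {
  tf <- toy_features()
  spec <- mlp_spec(input_width = 16, hidden_units = c(8), epochs = 0, seed = 5)
  model <- train_mlp(tf$x, tf$labels, spec)
  p <- predict(model, tf$x)
  expect_true(all(abs(p - 0.5) < 1e-12))
  ev <- evaluate(model, tf$x, tf$labels)
  expect_equal(sum(ev$counts), 60)
  expect_equal(ev$overall_accuracy, 50)     # argmax ties resolve to one class
})

test_that("a small MLP separates toy blobs and is seed-reproducible", {
  tf <- toy_features()
  spec <- mlp_spec(input_width = 16, hidden_units = c(8),
                   learning_rate = 1e-2, epochs = 30, batch_size = 10,
                   seed = 5)
  m1 <- train_mlp(tf$x, tf$labels, spec)
  ev <- evaluate(m1, tf$x, tf$labels)
  expect_gte(ev$overall_accuracy, 95)
  expect_equal(nrow(m1$curves), 30)
  m2 <- train_mlp(tf$x, tf$labels, spec)
  expect_identical(predict(m1, tf$x), predict(m2, tf$x))
  expect_error(train_mlp(tf$x, tf$labels[-1], spec), "mismatch")
})

test_that("the CNN wrapper validates shapes and trains on tiny images", {
  with_seed <- get("with_seed", asNamespace("eegoutcome"))
  imgs <- with_seed(9, {
    a <- array(rnorm(40 * 8 * 8, mean = 0), c(40, 8, 8))
    a[21:40, , ] <- a[21:40, , ] + 2
    a
  })
  labels <- rep(c("non_responder", "responder"), each = 20)
  spec <- cnn_spec(input_size = 8, conv_filters = 4, dense_units = 8,
                   learning_rate = 1e-2, epochs = 15, batch_size = 10,
                   seed = 2)
  m <- train_cnn(imgs, labels, spec)
  ev <- evaluate(m, imgs, labels)
  expect_gte(ev$overall_accuracy, 95)
  expect_error(train_cnn(imgs, labels, cnn_spec(input_size = 16)), "16 x 16")
  expect_error(train_cnn(imgs, rep("x", 40), spec), "labels must be")
})

test_that("evaluation reports internally consistent counts and metrics", {
  tf <- toy_features(seed = 3)
  spec <- mlp_spec(input_width = 16, hidden_units = c(8),
                   learning_rate = 1e-2, epochs = 20, batch_size = 10, seed = 1)
  model <- train_mlp(tf$x, tf$labels, spec)
  ev <- evaluate(model, tf$x, tf$labels)
  expect_equal(sum(ev$counts), length(tf$labels))
  expect_equal(ev$overall_accuracy,
               round(sum(diag(ev$counts)) / sum(ev$counts) * 100, 2))
  expect_equal(colSums(ev$counts),
               c(non_responder = 30, responder = 30))
  expect_error(evaluate(model, tf$x[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("stratified k-fold partitions are disjoint, exhaustive, and balanced", {
  tf <- toy_features(n_per_class = 40)
  spec <- mlp_spec(input_width = 16, hidden_units = c(4), epochs = 0, seed = 1)
  for (k in c(5, 6, 7, 8)) {
    kf <- kfold_evaluate(tf$x, tf$labels, spec, k = k, seed = 4)
    expect_length(kf$folds, 80)
    expect_setequal(unique(kf$folds), seq_len(k))
    expect_length(kf$accuracies, k)
    # per-fold class ratio within 1 sample of the global 50:50
    for (fi in seq_len(k)) {
      tab <- table(factor(tf$labels[kf$folds == fi],
                          c("non_responder", "responder")))
      expect_lte(abs(tab[1] - tab[2]), 1)
    }
  }
  expect_error(kfold_evaluate(tf$x, tf$labels, spec, k = 1), ">= 2")
  expect_error(kfold_evaluate(tf$x, tf$labels, spec, k = 50),
               "class count")
})

test_that("k-fold accuracy is high on separable toy data", {
  tf <- toy_features(n_per_class = 40)
  spec <- mlp_spec(input_width = 16, hidden_units = c(8),
                   learning_rate = 1e-2, epochs = 20, batch_size = 10, seed = 1)
  kf <- kfold_evaluate(tf$x, tf$labels, spec, k = 4, seed = 4)
  expect_true(all(kf$accuracies >= 0.9))
  expect_equal(kf$mean_accuracy, mean(kf$accuracies))
})

test_that("patient-level prediction aggregates epochs by majority vote", {
  tf <- toy_features()
  spec <- mlp_spec(input_width = 16, hidden_units = c(8),
                   learning_rate = 1e-2, epochs = 25, batch_size = 10, seed = 5)
  model <- train_mlp(tf$x, tf$labels, spec)
  resp <- predict_patient(model, tf$x[31:40, ])
  expect_equal(resp$label, "responder")
  expect_false(resp$tie)
  expect_equal(dim(resp$probabilities), c(10, 2))
  # mixed epochs: 3 responder-like vs 2 non-responder-like
  mix <- predict_patient(model, tf$x[c(31:33, 1:2), ])
  expect_equal(mix$label, "responder")
  # an even vote exercises the tie path: decided by mean responder probability
  tie <- predict_patient(model, tf$x[c(31:32, 1:2), ])
  expect_true(tie$tie)
  expect_equal(tie$label,
               if (mean(tie$probabilities[, 2]) >= 0.5) "responder"
               else "non_responder")
})
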