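#' Classifier specifications
#'
#' Configuration of the two compact classifiers.  The training protocol
#' defaults mirror the study settings: 80 training epochs at learning rate
#' 1e-5 with a softmax output over the two outcome classes; ReLU activations
#' throughout.  The architecture itself (unstated in the source protocol) is
#' the smallest standard stack consistent with a
#' conv-pool-dense-softmax sketch: two 3x3 convolution blocks of 32 and 64
#' filters, each followed by 2x2 max pooling, then a dense layer of 128
#' units.
#'
#' @param input_size image side in pixels (default 32).
#' @param conv_filters filters per convolution block.
#' @param kernel convolution kernel side (default 3).
#' @param dense_units width of the dense layer before the output.
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param epochs training epochs (default 80).
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed for initialisation and shuffling.
#' @return A `cnn_spec` / `mlp_spec` list.
#' @export
cnn_spec <- function(input_size = 32, conv_filters = c(32, 64), kernel = 3,
                     dense_units = 128, learning_rate = 1e-5, epochs = 80,
                     batch_size = 32, seed = 42L) {
  if (length(conv_filters) < 1) stop("need at least one convolution block")
  structure(list(input_size = input_size, conv_filters = conv_filters,
                 kernel = kernel, dense_units = dense_units,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, optimizer = "adam",
                 seed = as.integer(seed), classes = outcome_classes()),
            class = "cnn_spec")
}

#' @param input_width flattened input width for the MLP (default 4096, a
#'   64 x 64 connectivity matrix).
#' @param hidden_units hidden ReLU layer widths (default 256, 64).
#' @rdname cnn_spec
#' @export
mlp_spec <- function(input_width = 64 * 64, hidden_units = c(256, 64),
                     learning_rate = 1e-5, epochs = 80, batch_size = 32,
                     seed = 42L) {
  structure(list(input_width = input_width, hidden_units = hidden_units,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, optimizer = "adam",
                 seed = as.integer(seed), classes = outcome_classes()),
            class = "mlp_spec")
}

outcome_classes <- function() c("non_responder", "responder")

as_class_index <- function(labels) {
  cls <- outcome_classes()
  y <- match(as.character(labels), cls)
  if (anyNA(y))
    stop("labels must be among: ", paste(cls, collapse = ", "))
  y
}

#' Train/test splitting
#'
#' @param ratio training fraction in (0, 1); default 0.8 (the 8:2 split).
#' @param unit `"epoch"` (each 1-s sample assigned independently, the
#'   protocol default) or `"patient"` (all epochs of a patient stay on one
#'   side, avoiding within-patient leakage).
#' @param stratified preserve class proportions (default TRUE).
#' @param seed seed for the shuffle.
#' @return `split_plan()` returns a `split_plan` list.
#' @export
split_plan <- function(ratio = 0.8, unit = c("epoch", "patient"),
                       stratified = TRUE, seed = 42L) {
  unit <- match.arg(unit)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)")
  structure(list(ratio = ratio, unit = unit, stratified = stratified,
                 seed = as.integer(seed)), class = "split_plan")
}

# largest-remainder apportionment of `target` across class counts
apportion <- function(counts, target) {
  quota <- counts * target / sum(counts)
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(counts))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Split labelled samples into train and test sets
#'
#' The training set holds `round(n * ratio)` samples (6642 samples at 8:2
#' give exactly 5314 train / 1328 test); stratification keeps per-class
#' training fractions within one sample of the global ratio.  With
#' `unit = "patient"`, whole patients are assigned to a side and both
#' classes must remain represented on both sides.
#'
#' @param labels class label per sample.
#' @param plan a [split_plan()].
#' @param patients patient id per sample (required for patient-unit
#'   splits).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_data <- function(labels, plan = split_plan(), patients = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  n <- length(labels)
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  with_seed(plan$seed, {
    if (plan$unit == "patient") {
      if (is.null(patients)) stop("patient-unit split needs patient ids")
      pt <- unique(patients)
      plab <- labels[match(pt, patients)]
      train_p <- character(0)
      for (cl in unique(plab)) {
        p_cl <- sample(pt[plab == cl])
        k <- round(length(p_cl) * plan$ratio)
        if (k == 0 || k == length(p_cl))
          stop("class ", cl, " would be absent from one side of the ",
               "patient-unit split")
        train_p <- c(train_p, p_cl[seq_len(k)])
      }
      train <- which(patients %in% train_p)
    } else if (plan$stratified) {
      target <- round(n * plan$ratio)
      cls <- sort(unique(labels))
      counts <- vapply(cls, function(cl) sum(labels == cl), integer(1))
      k_per <- apportion(counts, target)
      train <- integer(0)
      for (i in seq_along(cls)) {
        idx <- sample(which(labels == cls[i]))
        train <- c(train, idx[seq_len(k_per[i])])
      }
      train <- sort(train)
    } else {
      train <- sort(sample.int(n, round(n * plan$ratio)))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

build_cnn_net <- function(spec) {
  g <- spec$input_size
  layers <- list()
  cin <- 1L
  side <- g
  for (f in spec$conv_filters) {
    layers <- c(layers, list(nn_layer_conv(f, spec$kernel, cin)),
                list(list(type = "relu")), list(list(type = "pool")))
    side <- (side - spec$kernel + 1) %/% 2
    cin <- f
  }
  flat <- side * side * cin
  layers <- c(layers, list(list(type = "flatten")),
              list(nn_layer_dense(spec$dense_units, flat)),
              list(list(type = "relu")),
              list(nn_layer_dense(2L, spec$dense_units, init = "zero")))
  list(layers = layers)
}

build_mlp_net <- function(spec) {
  widths <- c(spec$input_width, spec$hidden_units)
  layers <- list()
  for (i in seq_along(spec$hidden_units))
    layers <- c(layers, list(nn_layer_dense(widths[i + 1], widths[i])),
                list(list(type = "relu")))
  layers <- c(layers, list(nn_layer_dense(2L, utils::tail(widths, 1), init = "zero")))
  list(layers = layers)
}

#' Train the topographic-image CNN
#'
#' @param images numeric array n x side x side (e.g. from
#'   [epochs_to_images()]).
#' @param labels class label per image (`"responder"` /
#'   `"non_responder"`).
#' @param spec a [cnn_spec()].
#' @return An `eeg_classifier` with the fitted network, the spec, and
#'   per-epoch training `curves` (loss, accuracy).
#' @export
train_cnn <- function(images, labels, spec = cnn_spec()) {
  stopifnot(inherits(spec, "cnn_spec"))
  d <- dim(images)
  if (length(d) != 3 || d[2] != spec$input_size || d[3] != spec$input_size)
    stop("images must be n x ", spec$input_size, " x ", spec$input_size)
  y <- as_class_index(labels)
  if (d[1] != length(y)) stop("image / label count mismatch")
  if (length(unique(y)) < 2 && spec$epochs > 0)
    stop("need at least one sample of each class")
  x <- aperm(array(images, c(d[1], d[2], d[3], 1)), c(2, 3, 4, 1))
  norm <- fit_standardizer(x)
  x <- (x - norm[1]) / norm[2]
  with_seed(spec$seed, {
    net <- build_cnn_net(spec)
    fit <- nn_train(net, x, y, spec$epochs, spec$learning_rate,
                    spec$batch_size)
    structure(list(kind = "cnn", net = fit$net, spec = spec, norm = norm,
                   classes = spec$classes, curves = fit$curves),
              class = "eeg_classifier")
  })
}

# scalar centre/scale fitted on the training inputs; applied to every
# input the model sees so the softmax can separate classes through the
# origin from the first update
fit_standardizer <- function(x) {
  mu <- mean(x)
  sdv <- sd(as.numeric(x))
  c(mu = mu, sd = if (is.finite(sdv) && sdv > 0) sdv else 1)
}

#' Train the connectivity MLP
#'
#' @param matrices numeric array n x ch x ch of coherence matrices (or a
#'   pre-flattened n x ch^2 matrix).
#' @param labels class label per matrix.
#' @param spec an [mlp_spec()].
#' @return An `eeg_classifier`.
#' @export
train_mlp <- function(matrices, labels, spec = mlp_spec()) {
  stopifnot(inherits(spec, "mlp_spec"))
  x <- flatten_features(matrices, spec$input_width)
  y <- as_class_index(labels)
  if (ncol(x) != length(y)) stop("matrix / label count mismatch")
  norm <- fit_standardizer(x)
  x <- (x - norm[1]) / norm[2]
  with_seed(spec$seed, {
    net <- build_mlp_net(spec)
    fit <- nn_train(net, x, y, spec$epochs, spec$learning_rate,
                    spec$batch_size)
    structure(list(kind = "mlp", net = fit$net, spec = spec, norm = norm,
                   classes = spec$classes, curves = fit$curves),
              class = "eeg_classifier")
  })
}

flatten_features <- function(m, width) {
  if (is.matrix(m)) {
    if (ncol(m) != width) stop("expected ", width, " features per sample")
    return(t(m))
  }
  d <- dim(m)
  if (length(d) == 3) {
    if (d[2] * d[3] != width) stop("expected ", width, " features per sample")
    return(t(matrix(m, d[1], d[2] * d[3])))
  }
  stop("matrices must be an n x ch x ch array or n x ch^2 matrix")
}

#' Predict class probabilities
#'
#' @param object an `eeg_classifier`.
#' @param features images (n x side x side) for the CNN or matrices for the
#'   MLP.
#' @param ... unused.
#' @return numeric matrix n x 2 of softmax probabilities, columns named by
#'   class.
#' @export
predict.eeg_classifier <- function(object, features, ...) {
  x <- if (object$kind == "cnn") {
    d <- dim(features)
    aperm(array(features, c(d[1], d[2], d[3], 1)), c(2, 3, 4, 1))
  } else flatten_features(features, object$spec$input_width)
  x <- (x - object$norm[1]) / object$norm[2]
  p <- nn_predict_probs(object$net, x)
  colnames(p) <- object$classes
  p
}

round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Confusion-matrix metrics
#'
#' Counts are arranged rows = predicted, columns = true, in class order
#' (non-responder, responder).  Overall accuracy is the trace over the
#' total; per-class accuracy is the column recall; sensitivity is the
#' responder recall and specificity the non-responder recall.  Because
#' published reports sometimes quote row-wise (precision) ratios under
#' these names, the row-wise values are exposed too.  Percentages are
#' rounded half-up to 2 decimals; a metric whose denominator is zero is
#' `NA`.
#'
#' @param counts 2 x 2 numeric matrix of confusion counts.
#' @return list with `counts`, `overall_accuracy`, `per_class_accuracy`,
#'   `sensitivity`, `specificity`, `row_wise` (precision per class) - all
#'   percentages.
#' @export
confusion_metrics <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts)
  if (total == 0) stop("empty confusion table")
  cls <- outcome_classes()
  dimnames(counts) <- list(predicted = cls, true = cls)
  colt <- colSums(counts); rowt <- rowSums(counts)
  recall <- ifelse(colt > 0, diag(counts) / colt * 100, NA_real_)
  precision <- ifelse(rowt > 0, diag(counts) / rowt * 100, NA_real_)
  list(counts = counts,
       overall_accuracy = round_half_up(sum(diag(counts)) / total * 100),
       per_class_accuracy = stats::setNames(round_half_up(recall), cls),
       sensitivity = unname(round_half_up(recall[2])),
       specificity = unname(round_half_up(recall[1])),
       row_wise = stats::setNames(round_half_up(precision), cls))
}

#' Evaluate a classifier on a test set
#'
#' @param model an `eeg_classifier`.
#' @param features,labels test samples.
#' @return An `eval_report`: confusion counts (rows = predicted,
#'   cols = true), the [confusion_metrics()] list, and the training curves.
#' @export
evaluate <- function(model, features, labels) {
  y <- as_class_index(labels)
  if (length(y) == 0) stop("empty test set")
  p <- predict(model, features)
  pred <- max.col(p, ties.method = "first")
  counts <- matrix(0, 2, 2)
  for (i in seq_along(y)) counts[pred[i], y[i]] <- counts[pred[i], y[i]] + 1
  m <- confusion_metrics(counts)
  structure(c(m, list(n = length(y), curves = model$curves)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  print(x$counts)
  cat(sprintf("overall %.2f%% | specificity %.2f%% | sensitivity %.2f%%\n",
              x$overall_accuracy, x$specificity, x$sensitivity))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified folds (disjoint, exhaustive, per-fold class ratios
#' within one sample of the global ratio); each fold is held out once while
#' the classifier trains on the rest.
#'
#' @param features images or matrices, first dimension = samples.
#' @param labels class labels.
#' @param spec a [cnn_spec()] or [mlp_spec()] (decides which classifier is
#'   trained).
#' @param k number of folds (>= 2, at most the smaller class count).
#' @param seed fold-assignment seed.
#' @return list with `folds` (fold index per sample), `accuracies`
#'   (fraction correct per fold) and `mean_accuracy`.
#' @export
kfold_evaluate <- function(features, labels, spec, k, seed = 42L) {
  y <- as_class_index(labels)
  if (k < 2) stop("k must be >= 2")
  if (k > min(table(y))) stop("k exceeds the smaller class count")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  take <- function(idx) {
    if (length(dim(features)) == 3) features[idx, , , drop = FALSE]
    else features[idx, , drop = FALSE]
  }
  lab <- outcome_classes()[y]
  acc <- vapply(seq_len(k), function(fi) {
    tr <- folds != fi
    model <- if (inherits(spec, "cnn_spec"))
      train_cnn(take(which(tr)), lab[tr], spec)
    else train_mlp(take(which(tr)), lab[tr], spec)
    p <- predict(model, take(which(!tr)))
    mean(max.col(p, ties.method = "first") == y[!tr])
  }, numeric(1))
  list(folds = folds, accuracies = acc, mean_accuracy = mean(acc))
}

#' Patient-level prediction from baseline epochs
#'
#' Applies the classifier to every baseline epoch of one patient and
#' aggregates by majority vote; an exact tie is resolved by the mean
#' responder probability (responder when >= 0.5), and the tie is noted in
#' the result.
#'
#' @param model an `eeg_classifier`.
#' @param features the patient's epoch features (images or matrices).
#' @return list with `probabilities` (per-epoch softmax outputs), `votes`,
#'   `label`, and `tie` flag.
#' @export
predict_patient <- function(model, features) {
  p <- predict(model, features)
  if (nrow(p) < 1) stop("need at least one epoch")
  pred <- max.col(p, ties.method = "first")
  votes <- tabulate(pred, nbins = 2)
  tie <- votes[1] == votes[2]
  label <- if (tie) {
    if (mean(p[, 2]) >= 0.5) "responder" else "non_responder"
  } else outcome_classes()[which.max(votes)]
  list(probabilities = p,
       votes = stats::setNames(votes, outcome_classes()),
       label = label, tie = tie)
}
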