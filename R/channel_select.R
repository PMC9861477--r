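#' Per-channel amplitude summary across patients
#'
#' Entry (i, j) is the time-mean absolute voltage of channel i for patient
#' j in the requested session, the "average amplitude" entering the
#' channel-importance statistics.
#'
#' @param recs named list of per-patient recording pairs
#'   (`list(pre =, post =)`, as produced by [simulate_cohort()]), or a flat
#'   list of `eeg_recording`s all from one session.
#' @param session `"pre"` or `"post"` (used with the paired form).
#' @return An `amplitude_matrix`: channels x patients matrix with dimnames
#'   and attribute `session`.
#' @export
amplitude_summary <- function(recs, session = c("pre", "post")) {
  session <- match.arg(session)
  if (length(recs) == 0) stop("no recordings")
  flat <- lapply(recs, function(r) {
    if (inherits(r, "eeg_recording")) r
    else r[[session]] %||% stop("missing ", session, " recording")
  })
  ch <- flat[[1]]$channel_names
  for (r in flat) {
    stopifnot(inherits(r, "eeg_recording"))
    if (!identical(r$channel_names, ch))
      stop("recordings have mismatching channels")
  }
  m <- vapply(flat, function(r) rowMeans(abs(r$data)), numeric(length(ch)))
  dimnames(m) <- list(ch, vapply(flat, `[[`, character(1), "patient_id"))
  structure(m, session = session,
            class = c("amplitude_matrix", "matrix", "array"))
}

rank_channels <- function(scores, channels, method, decreasing = TRUE) {
  # ties (and NAs, placed last) break by montage order
  key <- if (decreasing) -scores else scores
  key[is.na(key)] <- Inf
  ord <- order(key, seq_along(key))
  structure(data.frame(rank = seq_along(ord), channel = channels[ord],
                       score = scores[ord], stringsAsFactors = FALSE),
            method = method, class = c("channel_ranking", "data.frame"))
}

#' Greatest-change channel selection (GCCS)
#'
#' Scores each channel by the mean over patients of its pre-to-post
#' amplitude change, `E_ci = (1/M) * sum_j |AC_ij - AC'_ij|`, and ranks
#' channels by the score, largest first.  The absolute difference is the
#' default so that positive and negative treatment effects cannot cancel
#' across patients; `signed = TRUE` evaluates the literal signed mean
#' difference instead.  Ties break by montage (row) order.
#'
#' @param pre,post `amplitude_matrix` objects (channels x patients) with
#'   matching shape and channel order.
#' @param signed use the signed mean difference instead of the mean
#'   absolute difference.
#' @return A `channel_ranking`: data frame `rank,channel,score` with
#'   attribute `method = "GCCS"`.
#' @export
gccs_scores <- function(pre, post, signed = FALSE) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post)))
    stop("pre and post matrices have different shapes")
  if (ncol(pre) < 1) stop("need at least one patient")
  d <- pre - post
  e <- if (signed) rowMeans(d) else rowMeans(abs(d))
  ch <- rownames(pre) %||% paste0("ch", seq_len(nrow(pre)))
  rank_channels(e, ch, "GCCS")
}

#' F-regression channel ranking
#'
#' For each channel, the correlation between its pre- and post-treatment
#' amplitudes across patients is converted to an F statistic and p-value;
#' channels are ranked by p-value, largest first (a channel whose post
#' values are fully predicted by its pre values carries no change signal).
#' Channels with zero variance (undefined correlation) are ranked last.
#'
#' @inheritParams gccs_scores
#' @return A `channel_ranking` with attribute `method = "FR"`; the score is
#'   the p-value.
#' @export
fr_scores <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post))) stop("shape mismatch")
  M <- ncol(pre)
  if (M < 3) stop("F-regression needs at least 3 patients")
  ch <- rownames(pre) %||% paste0("ch", seq_len(nrow(pre)))
  p <- vapply(seq_len(nrow(pre)), function(i) {
    if (sd(pre[i, ]) == 0 || sd(post[i, ]) == 0) return(NA_real_)
    cor.test(pre[i, ], post[i, ])$p.value
  }, numeric(1))
  if (anyNA(p))
    message("zero-variance channel(s) ranked last: ",
            paste(ch[is.na(p)], collapse = ", "))
  rank_channels(p, ch, "FR")
}

# shared regression design of the model-based rankers: features are the
# per-patient pre-treatment amplitudes, the response is each patient's mean
# absolute amplitude change across channels
importance_design <- function(pre, post) {
  X <- t(as.matrix(pre))                       # patients x channels
  y <- colMeans(abs(as.matrix(pre) - as.matrix(post)))
  colnames(X) <- rownames(pre) %||% paste0("ch", seq_len(nrow(pre)))
  list(X = as.data.frame(X), y = y)
}

fit_forest <- function(X, y, method, seed, num_trees = 500) {
  ranger::ranger(x = X, y = y, num.trees = num_trees,
                 importance = "impurity",
                 splitrule = if (method == "ET") "extratrees" else "variance",
                 replace = method != "ET",
                 sample.fraction = if (method == "ET") 1 else 0.632,
                 num.threads = 1, seed = seed)
}

#' Tree-ensemble channel importance (RF / ET)
#'
#' Random-forest or extremely-randomised-trees impurity importance over a
#' fixed regression design: per-patient pre-treatment channel amplitudes
#' predict the patient's mean absolute amplitude change.  Seeded and
#' single-threaded, so rankings are reproducible.
#'
#' @inheritParams gccs_scores
#' @param method `"RF"` (random forest) or `"ET"` (extra trees).
#' @param seed integer seed for the ensemble.
#' @param num_trees trees in the ensemble (default 500).
#' @return A `channel_ranking` scored by impurity importance (descending).
#' @export
tree_scores <- function(pre, post, method = c("RF", "ET"), seed = 1L,
                        num_trees = 500) {
  method <- match.arg(method)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post))) stop("shape mismatch")
  if (ncol(pre) < 2) stop("tree importance needs at least 2 patients")
  dsg <- importance_design(pre, post)
  ch <- colnames(dsg$X)
  if (sd(dsg$y) == 0 || all(vapply(dsg$X, sd, numeric(1)) == 0)) {
    imp <- stats::setNames(rep(0, length(ch)), ch)   # no signal: montage order
  } else {
    fit <- fit_forest(dsg$X, dsg$y, method, seed, num_trees)
    imp <- fit$variable.importance[ch]
  }
  rank_channels(as.numeric(imp), ch, method)
}

#' Recursive feature elimination over channels
#'
#' Repeatedly fits the tree ensemble on the surviving channels and removes
#' the least-important one (`step` at a time), until `n_keep` remain.  The
#' ranking is the reverse elimination order; the final survivors are
#' ordered by the last model's importance.
#'
#' @inheritParams tree_scores
#' @param n_keep number of channels to retain (in `[1, channels]`).
#' @param step channels removed per round (default 1).
#' @return A `channel_ranking` with attribute `method = "RFE"`; the score
#'   is the elimination round (0 for survivors, higher = removed earlier).
#' @export
rfe_scores <- function(pre, post, method = c("RF", "ET"), n_keep = 1L,
                       seed = 1L, num_trees = 200, step = 1L) {
  method <- match.arg(method)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post))) stop("shape mismatch")
  nch <- nrow(pre)
  if (n_keep < 1 || n_keep > nch) stop("n_keep must lie in [1, ", nch, "]")
  dsg <- importance_design(pre, post)
  ch <- colnames(dsg$X)
  alive <- ch
  eliminated <- character(0)
  round <- 0L
  last_imp <- NULL
  repeat {
    round <- round + 1L
    fit <- fit_forest(dsg$X[, alive, drop = FALSE], dsg$y, method,
                      seed + round, num_trees)
    imp <- fit$variable.importance[alive]
    last_imp <- imp
    if (length(alive) <= n_keep) break
    ord <- order(imp, match(alive, ch))        # least important first
    drop_n <- min(step, length(alive) - n_keep)
    eliminated <- c(alive[ord[seq_len(drop_n)]], eliminated)
    alive <- setdiff(alive, alive[ord[seq_len(drop_n)]])
  }
  survivors <- alive[order(-last_imp, match(alive, ch))]
  ordered <- c(survivors, eliminated)
  score <- stats::setNames(c(rep(0, length(survivors)),
                             rev(seq_along(eliminated))), ordered)
  out <- data.frame(rank = seq_along(ordered), channel = ordered,
                    score = as.numeric(score), stringsAsFactors = FALSE)
  structure(out, method = "RFE", class = c("channel_ranking", "data.frame"))
}

#' Restrict a recording or epoch set to selected channels
#'
#' Rows are restricted and reordered to `keep`; when a montage is supplied
#' the matching reduced montage is attached as attribute `montage`, so
#' topographic images can be rebuilt from the reduced electrode set.
#'
#' @param x an `eeg_recording` or `eeg_epochs`.
#' @param keep non-empty character vector of channel names to retain.
#' @param m optional `eeg_montage` to subset alongside.
#' @return Object of the same class as `x`, reduced to `keep`.
#' @export
subset_channels <- function(x, keep, m = NULL) {
  keep <- as.character(keep)
  if (length(keep) == 0) stop("keep must be non-empty")
  bad <- setdiff(keep, x$channel_names)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  idx <- match(keep, x$channel_names)
  out <- if (inherits(x, "eeg_recording")) {
    recording(x$data[idx, , drop = FALSE], x$rate, keep, x$patient_id, x$session)
  } else if (inherits(x, "eeg_epochs")) {
    epoch_set(x$epochs[, idx, , drop = FALSE], x$rate, keep, x$patient_id,
              x$session)
  } else stop("x must be an eeg_recording or eeg_epochs")
  if (!is.null(m)) {
    stopifnot(inherits(m, "eeg_montage"))
    sub <- m[match(keep, m$name), , drop = FALSE]
    class(sub) <- class(m)
    attr(out, "montage") <- sub
  }
  out
}

#' Write a channel ranking to CSV
#'
#' @param ranking a `channel_ranking`.
#' @param path output path; columns `rank,channel,score,method`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$method <- attr(ranking, "method")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
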