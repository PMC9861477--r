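#' Synthetic two-group EEG cohort configuration
#'
#' The generator emulates the structure the analysis pipeline is designed to
#' detect: two patient groups (responders / non-responders) with
#' group-dependent theta/alpha/beta oscillation amplitudes, coherent channel
#' clusters driven by shared latent oscillatory sources, planted pre-to-post
#' per-channel amplitude changes, white background noise, and paired TFI
#' scores consistent with the group labels.  Oscillations are sinusoids with
#' slowly drifting (random-walk) phase, so band powers stay analytically
#' predictable; coherence between channels arises only through the additive
#' shared latent sources, so it is monotone in the mixing weight.
#'
#' @param montage electrode montage; default the packaged 64-channel layout.
#' @param n_per_group patients per group (default 4, i.e. an 8-patient
#'   cohort of 4 responders and 4 non-responders).
#' @param duration recording length in seconds (default 100, giving 100
#'   one-second epochs per recording at 256 Hz).
#' @param rate sampling rate in Hz; 256 (direct) or 8192 (native, to be
#'   down-sampled).
#' @param band_amplitudes 2 x 3 matrix (rows `responder`, `non_responder`;
#'   columns `theta`, `alpha`, `beta`) of sinusoid amplitudes in microvolts.
#'   The default plants a 3x alpha-amplitude separation between groups.
#' @param band_freqs oscillator frequency per band in Hz (defaults 6, 10,
#'   20 Hz, one representative tone inside each band).
#' @param coherent_clusters list of clusters; each is a list with fields
#'   `channels` (channel names), `weight` (named mixing weights in \[0,1\]
#'   per group), `freq` (Hz) and `amplitude` (microvolts of the latent
#'   source).  The default plants a frontal-central cluster
#'   (F1,Fz,F2,FC1,FCz,FC2,C1,Cz,C2) with strong coupling in responders and
#'   weak in non-responders, plus a parietal cluster coupled equally.
#' @param post_delta named per-channel alpha-amplitude change (microvolts)
#'   added in post-treatment sessions; channels not named get the
#'   `background_delta` default.
#' @param planted_channels channels carrying the largest absolute
#'   `post_delta`; default FC3, P8, P4, T8, CP5 with +3 microvolts.
#' @param background_delta amplitude change for non-planted channels;
#'   default an even spread over \[0, 1\] microvolts in montage order, so
#'   channel ranking has a non-trivial background to beat.
#' @param phase_walk_sd per-sample standard deviation (radians) of the
#'   random-walk phase drift (default 0.05).
#' @param noise_sd white-noise standard deviation in microvolts (default 1;
#'   the planted 3 microvolt change is then a 3x effect).
#' @param tfi_params per-group list with `baseline_mean`, `baseline_sd`,
#'   `change_mean`, `change_sd` (TFI points); defaults give responders a
#'   mean change of +15 and non-responders 0, consistent with the labelling
#'   rule (change = post - baseline, responder >= 4.8).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(montage = default_montage(),
                       n_per_group = 4,
                       duration = 100,
                       rate = 256,
                       band_amplitudes = rbind(
                         responder     = c(theta = 2, alpha = 6, beta = 1.5),
                         non_responder = c(theta = 2, alpha = 2, beta = 1.5)),
                       band_freqs = c(theta = 6, alpha = 10, beta = 20),
                       coherent_clusters = list(
                         list(channels = c("F1", "Fz", "F2", "FC1", "FCz",
                                           "FC2", "C1", "Cz", "C2"),
                              weight = c(responder = 0.9, non_responder = 0.3),
                              freq = 10,
                              amplitude = c(responder = 12, non_responder = 4)),
                         list(channels = c("P1", "Pz", "P2", "PO3", "POz", "PO4"),
                              weight = c(responder = 0.5, non_responder = 0.5),
                              freq = 10,
                              amplitude = c(responder = 12, non_responder = 4))),
                       post_delta = NULL,
                       planted_channels = c("FC3", "P8", "P4", "T8", "CP5"),
                       background_delta = NULL,
                       phase_walk_sd = 0.05,
                       noise_sd = 1,
                       tfi_params = list(
                         responder = list(baseline_mean = 45, baseline_sd = 10,
                                          change_mean = 15, change_sd = 4),
                         non_responder = list(baseline_mean = 45, baseline_sd = 10,
                                              change_mean = 0, change_sd = 2)),
                       seed = 1L) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (duration * rate < rate) stop("duration must cover at least one epoch")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ch <- montage$name
  for (cl in coherent_clusters) {
    bad <- setdiff(cl$channels, ch)
    if (length(bad)) stop("unknown cluster channels: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(planted_channels, ch)
  if (length(bad)) stop("planted_channels not in montage: ", paste(bad, collapse = ", "))
  if (is.null(post_delta)) {
    post_delta <- stats::setNames(numeric(length(ch)), ch)
    others <- setdiff(ch, planted_channels)
    if (is.null(background_delta))
      background_delta <- stats::setNames(seq(0, 1, length.out = length(others)), others)
    post_delta[names(background_delta)] <- background_delta
    post_delta[planted_channels] <- 3
  } else {
    bad <- setdiff(names(post_delta), ch)
    if (length(bad)) stop("post_delta names not in montage: ", paste(bad, collapse = ", "))
    full <- stats::setNames(numeric(length(ch)), ch)
    full[names(post_delta)] <- post_delta
    post_delta <- full
  }
  structure(list(montage = montage, n_per_group = n_per_group,
                 duration = duration, rate = rate,
                 band_amplitudes = band_amplitudes, band_freqs = band_freqs,
                 coherent_clusters = coherent_clusters,
                 post_delta = post_delta, planted_channels = planted_channels,
                 phase_walk_sd = phase_walk_sd, noise_sd = noise_sd,
                 tfi_params = tfi_params, seed = as.integer(seed)),
            class = "sim_config")
}

# run code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# deterministic per-patient/session sub-seed below 2^31
sub_seed <- function(seed, patient_index, session) {
  (as.integer(seed) %% 100000L) * 20011L + patient_index * 7L +
    (if (session == "post") 3L else 0L)
}

#' Simulate one recording
#'
#' @param config a [sim_config()].
#' @param patient_id identifier stored in the recording.
#' @param session `"pre"` or `"post"`; post sessions add the configured
#'   per-channel alpha-amplitude change.
#' @param group `"responder"` or `"non_responder"`; selects band amplitudes
#'   and cluster mixing weights.
#' @param seed optional seed making this single recording reproducible on
#'   its own; when `NULL` the current RNG stream is used.
#' @return An `eeg_recording` of size channels x (duration * rate).
#' @export
simulate_recording <- function(config, patient_id = "p1",
                               session = c("pre", "post"),
                               group = c("responder", "non_responder"),
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  session <- match.arg(session)
  group <- match.arg(group)
  if (!is.null(seed))
    return(with_seed(seed, simulate_recording(config, patient_id, session, group)))

  ch <- config$montage$name
  n <- round(config$duration * config$rate)
  t <- (seq_len(n) - 1) / config$rate
  x <- matrix(0, nrow = length(ch), ncol = n, dimnames = list(ch, NULL))

  bands <- colnames(config$band_amplitudes)
  for (b in bands) {
    f <- config$band_freqs[[b]]
    amp <- rep(config$band_amplitudes[group, b], length(ch))
    if (session == "post" && b == "alpha")
      amp <- amp + config$post_delta[ch]
    for (i in seq_along(ch)) {
      phase <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n, 0, config$phase_walk_sd))
      x[i, ] <- x[i, ] + amp[i] * sin(2 * pi * f * t + phase)
    }
  }
  for (cl in config$coherent_clusters) {
    w <- cl$weight[[group]]
    if (w <= 0) next
    amp_l <- if (length(cl$amplitude) > 1) cl$amplitude[[group]] else cl$amplitude
    phase <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(n, 0, config$phase_walk_sd))
    latent <- amp_l * sin(2 * pi * cl$freq * t + phase)
    idx <- match(cl$channels, ch)
    x[idx, ] <- x[idx, ] + rep(w, length(idx)) %o% latent
  }
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, config$noise_sd), nrow = nrow(x))
  recording(x, config$rate, ch, patient_id, session)
}

# one TFI pair consistent with the target label (rejection sampling)
draw_tfi_pair <- function(params, target_label, spec = label_spec()) {
  if (params$baseline_sd == 0 && params$change_sd == 0) {
    base <- round(params$baseline_mean, 1)
    post <- round(base + params$change_mean, 1)
    lab <- label_outcome(base, post, spec)$label
    if (lab != target_label)
      stop("tfi_params cannot satisfy the ", target_label,
           " label with zero variance")
    return(c(base, post))
  }
  for (i in 1:1000) {
    base <- round(min(100, max(0, stats::rnorm(1, params$baseline_mean,
                                               params$baseline_sd))), 1)
    post <- round(base + stats::rnorm(1, params$change_mean, params$change_sd), 1)
    if (post < 0 || post > 100) next
    if (label_outcome(base, post, spec)$label == target_label)
      return(c(base, post))
  }
  stop("could not draw a TFI pair labelled ", target_label,
       " from the given tfi_params")
}

#' Simulate a full pre/post cohort
#'
#' Generates `2 * n_per_group` patients (first group responders, second
#' non-responders), each with a pre- and post-treatment recording, paired
#' TFI scores whose labels match the group by construction, and a ground
#' truth record.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{recordings}{named list per patient, each `list(pre =, post =)`.}
#'     \item{outcomes}{data frame: `patient_id`, `group`, `tfi_baseline`,
#'       `tfi_post`, `tfi_change`, `label`.}
#'     \item{truth}{`sim_truth` list: `group`, `planted_channels`,
#'       `post_delta`, `tfi`, and the generating `config`.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- rep(c("responder", "non_responder"), each = config$n_per_group)
  ids <- sprintf("p%02d", seq_along(groups))
  spec <- label_spec()

  tfi <- with_seed(config$seed, {
    t(vapply(seq_along(ids), function(i)
      draw_tfi_pair(config$tfi_params[[groups[i]]], groups[i], spec),
      numeric(2)))
  })
  recs <- lapply(seq_along(ids), function(i) {
    list(pre = simulate_recording(config, ids[i], "pre", groups[i],
                                  seed = sub_seed(config$seed, i, "pre")),
         post = simulate_recording(config, ids[i], "post", groups[i],
                                   seed = sub_seed(config$seed, i, "post")))
  })
  names(recs) <- ids
  beh <- data.frame(patient_id = ids, tfi_baseline = tfi[, 1],
                    tfi_post = tfi[, 2], stringsAsFactors = FALSE)
  outcomes <- label_cohort(beh, spec)
  outcomes$group <- groups
  outcomes <- outcomes[, c("patient_id", "group", "tfi_baseline", "tfi_post",
                           "tfi_change", "label")]
  stopifnot(all(outcomes$label == outcomes$group))
  truth <- structure(list(group = stats::setNames(groups, ids),
                          planted_channels = config$planted_channels,
                          post_delta = config$post_delta,
                          tfi = beh, config = config),
                     class = "sim_truth")
  list(recordings = recs, outcomes = outcomes, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits one RDS recording per patient/session plus `behavioural.csv` and a
#' `truth.json` summary into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    for (ses in c("pre", "post")) {
      write_recording(cohort$recordings[[id]][[ses]],
                      file.path(dir, sprintf("%s_%s.rds", id, ses)))
    }
  }
  write.csv(cohort$outcomes[, c("patient_id", "tfi_baseline", "tfi_post")],
            file.path(dir, "behavioural.csv"), row.names = FALSE)
  jsonlite::write_json(list(group = as.list(cohort$truth$group),
                            planted_channels = cohort$truth$planted_channels,
                            post_delta = as.list(cohort$truth$post_delta)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
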