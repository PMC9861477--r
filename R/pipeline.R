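#' Pipeline configuration
#'
#' One document driving the full chain from (synthetic or stored)
#' recordings to an evaluated classifier and a channel-importance report.
#' A single global seed fans out to per-stage seeds (stage name hashed), so
#' each stage is independently reproducible.
#'
#' @param feature `"topomap"` (CNN on merged band images) or
#'   `"connectivity"` (MLP on merged coherence matrices).
#' @param sim a [sim_config()] describing the cohort to simulate, or `NULL`
#'   to read recordings from `data_dir` (the layout written by
#'   [write_cohort()]).
#' @param data_dir directory of stored recordings + `behavioural.csv`
#'   (used when `sim` is `NULL`).
#' @param target_rate analysis rate in Hz (default 256).
#' @param epoch_seconds epoch length (default 1).
#' @param grid_size topomap side in pixels (default 32).
#' @param model_spec a [cnn_spec()] / [mlp_spec()]; defaults chosen to
#'   match `feature`.
#' @param plan a [split_plan()].
#' @param rank_method channel ranking method (`"gccs"`, `"fr"`, `"rf"`,
#'   `"et"`, `"rfe"`).
#' @param top_k channels reported from the ranking (default 30).
#' @param seed global pipeline seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(feature = c("topomap", "connectivity"),
                            sim = sim_config(), data_dir = NULL,
                            target_rate = 256, epoch_seconds = 1,
                            grid_size = 32, model_spec = NULL,
                            plan = split_plan(),
                            rank_method = c("gccs", "fr", "rf", "et", "rfe"),
                            top_k = 30, seed = 1L) {
  feature <- match.arg(feature)
  rank_method <- match.arg(rank_method)
  if (is.null(model_spec))
    model_spec <- if (feature == "topomap") cnn_spec(input_size = grid_size)
                  else mlp_spec()
  structure(list(feature = feature, sim = sim, data_dir = data_dir,
                 target_rate = target_rate, epoch_seconds = epoch_seconds,
                 grid_size = grid_size, model_spec = model_spec, plan = plan,
                 rank_method = rank_method, top_k = top_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L +
    sum(utf8ToInt(stage)) %% 10007L
}

#' Run the full pipeline
#'
#' simulate/load -> resample -> epoch -> features (topomap images or
#' coherence matrices) -> stratified split -> train -> evaluate -> channel
#' ranking.  All artefacts (features metadata, evaluation report, ranking,
#' manifest) are written under `out_dir`; nothing is written elsewhere, and
#' the manifest records the seed, configuration hash and every emitted
#' file, so a run is reproducible from the manifest alone.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created; default a fresh temporary
#'   directory).
#' @param verbose print stage progress.
#' @return Invisibly, a list with `report` (the [evaluate()] result),
#'   `ranking`, `outcomes`, `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("eegrun"), verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[eegoutcome] ", ...)
  files <- character(0)
  emit <- function(path) files <<- c(files, basename(path))

  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(cfg$sim)) {
      say("simulating cohort (seed ", cfg$seed, ")")
      sim <- cfg$sim; sim$seed <- stage_seed(cfg$seed, "simulate")
      cohort <- simulate_cohort(sim)
    } else {
      say("loading cohort from ", cfg$data_dir)
      cohort <- load_cohort(cfg$data_dir)
    }
    outcomes <- cohort$outcomes

    stage <- "preprocess"
    montage <- if (!is.null(cfg$sim)) cfg$sim$montage else default_montage()
    eps <- list()
    for (id in names(cohort$recordings)) {
      rec <- cohort$recordings[[id]]$pre
      if (rec$rate != cfg$target_rate)
        rec <- resample_recording(rec, cfg$target_rate)
      eps[[id]] <- segment_epochs(rec, cfg$epoch_seconds)
    }

    stage <- "features"
    say("extracting ", cfg$feature, " features")
    feats_by_patient <- lapply(eps, function(e) {
      if (cfg$feature == "topomap")
        epochs_to_images(e, montage, grid_size = cfg$grid_size)
      else epoch_coherence_matrices(e)
    })
    n_by_patient <- vapply(feats_by_patient, function(f) dim(f)[1], integer(1))
    features <- abind_first(feats_by_patient)
    patients <- rep(names(n_by_patient), n_by_patient)
    labels <- outcomes$label[match(patients, outcomes$patient_id)]
    stage <- "split"
    plan <- cfg$plan; plan$seed <- stage_seed(cfg$seed, "split")
    sp <- split_data(labels, plan, patients)
    if (cfg$feature == "topomap") {
      # global min-max fitted on the training side only
      rng <- range(if (length(dim(features)) == 3)
        features[sp$train, , , drop = FALSE] else features[sp$train, ])
      if (diff(rng) == 0) rng[2] <- rng[1] + 1
      features <- (features - rng[1]) / diff(rng)
    }

    stage <- "train"
    say("training ", if (cfg$feature == "topomap") "CNN" else "MLP",
        " on ", length(sp$train), " samples")
    spec <- cfg$model_spec; spec$seed <- stage_seed(cfg$seed, "train")
    take <- function(i) if (length(dim(features)) == 3)
      features[i, , , drop = FALSE] else features[i, , drop = FALSE]
    model <- if (cfg$feature == "topomap")
      train_cnn(take(sp$train), labels[sp$train], spec)
    else train_mlp(take(sp$train), labels[sp$train], spec)

    stage <- "evaluate"
    report <- evaluate(model, take(sp$test), labels[sp$test])

    stage <- "rank"
    pre <- amplitude_summary(cohort$recordings, "pre")
    post <- amplitude_summary(cohort$recordings, "post")
    rseed <- stage_seed(cfg$seed, "rank")
    ranking <- switch(cfg$rank_method,
                      gccs = gccs_scores(pre, post),
                      fr = fr_scores(pre, post),
                      rf = tree_scores(pre, post, "RF", seed = rseed),
                      et = tree_scores(pre, post, "ET", seed = rseed),
                      rfe = rfe_scores(pre, post, "RF", n_keep = cfg$top_k,
                                       seed = rseed))

    stage <- "write"
    jsonlite::write_json(
      list(counts = unclass(report$counts),
           overall_accuracy = report$overall_accuracy,
           per_class_accuracy = as.list(report$per_class_accuracy),
           sensitivity = report$sensitivity,
           specificity = report$specificity, n = report$n),
      file.path(out_dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
    emit("eval_report.json")
    write.csv(report$curves, file.path(out_dir, "curves.csv"),
              row.names = FALSE); emit("curves.csv")
    write_ranking(ranking, file.path(out_dir, "ranking.csv")); emit("ranking.csv")
    write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
              row.names = FALSE); emit("outcomes.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("eegoutcome")),
      r_version = R.version.string,
      seed = cfg$seed,
      feature = cfg$feature,
      config_hash = config_hash(cfg),
      n_train = length(sp$train), n_test = length(sp$test),
      files = files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(report = report, ranking = ranking, outcomes = outcomes,
         manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("done: ", out_dir)
  invisible(res)
}

# stack per-patient feature arrays along the first dimension
abind_first <- function(lst) {
  d <- dim(lst[[1]])
  n <- sum(vapply(lst, function(x) dim(x)[1], integer(1)))
  out <- array(0, dim = c(n, d[-1]))
  at <- 0
  for (x in lst) {
    k <- dim(x)[1]
    if (length(d) == 3) out[at + seq_len(k), , ] <- x
    else out[at + seq_len(k), ] <- x
    at <- at + k
  }
  out
}

config_hash <- function(cfg) {
  # cheap stable fingerprint of the serialised config (no digest dependency)
  raw <- serialize(cfg, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 97)) %% .Machine$integer.max)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir directory holding `pXX_pre.rds` / `pXX_post.rds` recordings
#'   and `behavioural.csv`.
#' @return list with `recordings` (per-patient pre/post pairs) and
#'   `outcomes` (labelled behavioural table).
#' @export
load_cohort <- function(dir) {
  beh <- read_behavioural(file.path(dir, "behavioural.csv"))
  recs <- lapply(beh$patient_id, function(id)
    list(pre = read_recording(file.path(dir, paste0(id, "_pre.rds"))),
         post = read_recording(file.path(dir, paste0(id, "_post.rds")))))
  names(recs) <- beh$patient_id
  list(recordings = recs, outcomes = label_cohort(beh))
}
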