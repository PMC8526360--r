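# Configuration-driven orchestration of the full analysis: datasets ->
# models -> decoding -> representational analysis -> simulated experiments ->
# highlight cues, with manifests, seeds and per-stage logs.

#' Build a pipeline configuration
#'
#' @param stages Character vector of stages to run, a subset (in dependency
#'   order) of `"make_data"`, `"train_unsupervised"`, `"train_supervised"`,
#'   `"decode"`, `"rsa"`, `"experiment3"`, `"cues"`.
#' @param world A [world_config()] for the main (bimodal) dataset.
#' @param n_images Images in the main dataset.
#' @param model A [pixelvae_config()].
#' @param supervised A [supervised_config()].
#' @param instance_seeds Seeds of the model training instances (the full
#'   study uses ten; small runs use two or three).
#' @param n_sequences Candidate relief sequences for the simulated
#'   constancy experiment.
#' @param n_cue_scenes Base scenes for the cue-manipulation analysis.
#' @param seed Global seed.
#' @param out_dir Output directory for artifacts (`NULL`: keep in memory
#'   only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("make_data", "train_unsupervised",
                                       "train_supervised", "decode", "rsa",
                                       "experiment3", "cues"),
                            world = world_config(image_size = 32L),
                            n_images = 1500L,
                            model = pixelvae_config("desk"),
                            supervised = supervised_config("desk"),
                            instance_seeds = c(1L, 2L),
                            n_sequences = 20L,
                            n_cue_scenes = 5L,
                            seed = 1L,
                            out_dir = NULL) {
  all_stages <- c("make_data", "train_unsupervised", "train_supervised",
                  "decode", "rsa", "experiment3", "cues")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(train_unsupervised = "make_data",
               train_supervised = "make_data",
               decode = c("train_unsupervised", "train_supervised"),
               rsa = c("train_unsupervised", "train_supervised"),
               experiment3 = c("train_unsupervised", "train_supervised",
                               "decode"),
               cues = c("train_unsupervised", "decode"))
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage(s): ", paste(miss, collapse = ", "))
  }
  structure(list(stages = stages, world = world, n_images = n_images,
                 model = model, supervised = supervised,
                 instance_seeds = instance_seeds,
                 n_sequences = n_sequences, n_cue_scenes = n_cue_scenes,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order. Every produced artifact carries
#' the configuration hash and the seeds used; rerunning with the same
#' configuration reproduces identical manifests and results.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_run` list of stage artifacts plus a `log` tibble.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  run <- list(config = config, hash = cfg_hash)
  log_rows <- list()
  note <- function(stage, t0) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, seconds = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
      hash = cfg_hash, seed = config$seed)
    if (verbose) message("stage ", stage, " done")
  }
  for (stage in config$stages) {
    t0 <- Sys.time()
    if (stage == "make_data") {
      run$dataset <- generate_dataset(config$world, config$n_images,
                                      seed = derive_seed(config$seed, 11))
    } else if (stage == "train_unsupervised") {
      run$unsupervised <- lapply(config$instance_seeds, function(s)
        train_pixelvae(run$dataset, config$model, seed = s))
      run$latents <- lapply(run$unsupervised, function(m)
        encode_latents(m, run$dataset$images))
    } else if (stage == "train_supervised") {
      run$supervised <- lapply(config$instance_seeds, function(s)
        train_supervised_classifier(run$dataset, config$supervised, seed = s))
      run$sup_features <- lapply(run$supervised, function(m)
        supervised_features(m, run$dataset$images))
    } else if (stage == "decode") {
      man <- run$dataset$manifest
      sseed <- derive_seed(config$seed, 21)
      run$axes <- lapply(run$latents, function(l)
        fit_gloss_classifier(l, man$gloss_label, sseed))
      run$decoding <- dplyr::bind_rows(
        purrr::imap_dfr(run$latents, function(l, i) dplyr::mutate(
          dplyr::bind_rows(
            dplyr::mutate(run$axes[[i]]$report, r_squared = NA_real_,
                          chance = 0.5),
            dplyr::mutate(decode_lightfield(l, man$lightfield_id, sseed),
                          r_squared = NA_real_),
            regress_relief(l, man$relief_depth, sseed)),
          model = "unsupervised", instance = i)),
        purrr::imap_dfr(run$sup_features, function(f, i) dplyr::mutate(
          dplyr::bind_rows(
            dplyr::mutate(
              fit_gloss_classifier(f, man$gloss_label, sseed)$report,
              r_squared = NA_real_, chance = 0.5),
            dplyr::mutate(decode_lightfield(f, man$lightfield_id, sseed),
                          r_squared = NA_real_),
            regress_relief(f, man$relief_depth, sseed)),
          model = "supervised", instance = i)))
    } else if (stage == "rsa") {
      sub <- utils::head(seq_len(nrow(run$dataset$manifest)), 400L)
      man <- run$dataset$manifest[sub, ]
      run$rsa <- purrr::map_dfr(
        list(unsupervised = run$latents, supervised = run$sup_features),
        function(featlist) {
          mats <- lapply(featlist, function(f)
            correlation_distance_matrix(f[sub, ]))
          purrr::map_dfr(list(gloss = man$gloss_label,
                              lightfield = man$lightfield_id),
                         function(lab) {
                           ct <- same_vs_different_contrast(mats, lab)
                           tibble::tibble(mean_contrast = mean(ct$contrasts))
                         }, .id = "factor")
        }, .id = "model")
    } else if (stage == "experiment3") {
      run$experiment3 <- simulate_experiment3(
        run$unsupervised, run$axes, run$supervised,
        config, n_sequences = config$n_sequences,
        seed = derive_seed(config$seed, 31))
    } else if (stage == "cues") {
      cue_cfg <- config$world
      scenes <- with_seed(derive_seed(config$seed, 41), {
        par <- sample_scene(cue_cfg, n = config$n_cue_scenes)
        par$spec_magnitude <- stats::runif(config$n_cue_scenes, 0.3, 0.5)
        par$spec_concentration <- stats::runif(config$n_cue_scenes, 0.75, 0.95)
        lapply(seq_len(config$n_cue_scenes), function(i)
          render_scene(par[i, ], cue_cfg, margin = 50L))
      })
      run$cue_curves <- cue_response_curves(run$unsupervised[[1]],
                                            run$axes[[1]], scenes)
    }
    note(stage, t0)
  }
  run$log <- dplyr::bind_rows(log_rows)
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  structure(run, class = "pipeline_run")
}

# Simulated relief-sequence experiment: render candidate sequences, obtain
# instance-level 2AFC profiles for both models, rank by interaction F,
# classify the unsupervised model's constancy patterns.
simulate_experiment3 <- function(unsup_models, axes, sup_models, config,
                                 n_sequences, seed) {
  wc <- config$world
  base <- sample_sequence_params(wc, n_sequences, "3b", seed)
  reliefs <- relief_schedule()
  prof_a <- vector("list", n_sequences)
  prof_b <- vector("list", n_sequences)
  patterns <- character(n_sequences)
  for (s in seq_len(n_sequences)) {
    seq_scenes <- render_relief_sequence(base[s, ], reliefs, wc)
    imgs <- array(0L, c(length(seq_scenes), wc$image_size, wc$image_size, 3))
    for (k in seq_along(seq_scenes))
      imgs[k, , , ] <- quantize8(seq_scenes[[k]]$composite)
    pa <- t(vapply(seq_along(unsup_models), function(i) {
      pred <- predict_gloss(axes[[i]],
                            encode_latents(unsup_models[[i]], imgs))
      simulate_2afc(pred)$prop_glossier
    }, numeric(length(reliefs))))
    pb <- t(vapply(seq_along(sup_models), function(i) {
      sc <- predict(sup_models[[i]], imgs)$score
      hi_col <- which(sup_models[[i]]$levels == "high")
      pred <- sc[, hi_col] - sc[, -hi_col]
      simulate_2afc(pred)$prop_glossier
    }, numeric(length(reliefs))))
    prof_a[[s]] <- pa
    prof_b[[s]] <- pb
    patterns[s] <- classify_constancy_pattern(colMeans(pa))
  }
  ranking <- rank_sequences_by_disagreement(prof_a, prof_b)
  list(profiles_unsupervised = prof_a, profiles_supervised = prof_b,
       ranking = ranking,
       patterns = tibble::tibble(sequence = seq_len(n_sequences),
                                 pattern = patterns))
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(run$decoding))
    utils::write.csv(run$decoding, file.path(dir, "decoding.csv"),
                     row.names = FALSE)
  if (!is.null(run$rsa))
    utils::write.csv(run$rsa, file.path(dir, "rsa.csv"), row.names = FALSE)
  if (!is.null(run$cue_curves))
    utils::write.csv(run$cue_curves, file.path(dir, "cue_curves.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(hash = run$hash, seed = run$config$seed,
                            stages = run$config$stages),
                       file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Summarize a pipeline run
#'
#' One tidy table per analysis (decoding report, representational contrasts,
#' constancy patterns, cue curves), plus an index of what is present;
#' stages that were not run are reported as gaps.
#'
#' @param run A [run_pipeline()] result.
#' @return A `pipeline_report` list of tibbles with an `index` tibble.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  parts <- list()
  if (!is.null(run$decoding)) parts$decoding <- run$decoding
  if (!is.null(run$rsa)) parts$rsa <- run$rsa
  if (!is.null(run$experiment3)) {
    parts$constancy_patterns <- run$experiment3$patterns
    parts$sequence_ranking <- run$experiment3$ranking
  }
  if (!is.null(run$cue_curves)) parts$cue_curves <- run$cue_curves
  all_parts <- c("decoding", "rsa", "constancy_patterns",
                 "sequence_ranking", "cue_curves")
  index <- tibble::tibble(part = all_parts,
                          present = all_parts %in% names(parts))
  structure(c(parts, list(index = index, hash = run$hash)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$index)
  invisible(x)
}
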