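# End-to-end orchestration: simulate -> preprocess -> split -> train ->
# baselines -> evaluate -> explain, with every artifact written to a run
# directory as CSV/JSON.

#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end pipeline with defaults mirroring the
#' study protocol (stratified 70/15/15 split, seeds 42/123, bootstrap 1000,
#' sigma grid 0-0.5, patience 20). Serialises losslessly to JSON; every run
#' writes its resolved configuration next to its outputs.
#'
#' @param n_per_class Subjects per class to simulate.
#' @param task `"pegboard"` or `"gait_imagery"`.
#' @param sim_hz Simulation sampling rate (Hz).
#' @param target_hz Model-input rate after decimation.
#' @param chromophore `"hbo"`, `"hbr"` or `"hbt"`.
#' @param d_model,n_heads,n_transformer_layers,epochs,batch_size,patience
#'   Deep-model settings (see [model_spec()]).
#' @param seed_shuffle,seed_weights The two pipeline seeds (42 / 123).
#' @param master_seed Seed for cohort simulation.
#' @param bootstrap_n Bootstrap resamples for evaluation CIs.
#' @param noise_sigmas Robustness sigma grid.
#' @param noise_reps Draws per sigma.
#' @param importance_repeats Permutation-importance repeats.
#' @param baselines Character vector of baseline names to run.
#' @param out_dir Output directory.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(n_per_class = 20, task = "pegboard", sim_hz = 10,
                       target_hz = 1, chromophore = "hbo",
                       d_model = 128, n_heads = 4, n_transformer_layers = 2,
                       epochs = 120, batch_size = 16, patience = 20,
                       seed_shuffle = 42, seed_weights = 123, master_seed = 1,
                       bootstrap_n = 1000,
                       noise_sigmas = seq(0, 0.5, by = 0.1), noise_reps = 20,
                       importance_repeats = 10,
                       baselines = c("svm", "rf", "knn", "bpnn"),
                       out_dir = tempfile("atlaspd_run_")) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, split, deep-model training (hybrid +
#' LSTM), classical baselines with cross-validation, evaluation (bootstrap
#' CIs, McNemar pairings, noise robustness) and interpretability
#' (permutation importance, region aggregation, t-SNE), writing every
#' artifact (JSON metrics, CSV curves/tables, the resolved config) into
#' `config$out_dir`. Stage failures abort with a stage-tagged error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the run directory and the in-memory
#'   results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  design <- block_design(sampling_hz = config$sim_hz)
  cohort <- .stage("simulate", simulate_cohort(
    config$n_per_class, task = config$task, design = design,
    seed = config$master_seed))
  dataset <- .stage("preprocess", build_dataset(
    cohort, chromophore = config$chromophore, target_hz = config$target_hz,
    seed = config$master_seed))
  utils::write.csv(data.frame(subject_id = dataset$subject_ids,
                              label = as.character(dataset$labels)),
                   file.path(config$out_dir, "labels.csv"), row.names = FALSE)

  sp <- .stage("split", split_dataset(dataset$labels, seed = config$seed_shuffle))
  xtr <- dataset$data[sp$train, , , drop = FALSE]; ytr <- dataset$labels[sp$train]
  xva <- dataset$data[sp$val, , , drop = FALSE];  yva <- dataset$labels[sp$val]
  xte <- dataset$data[sp$test, , , drop = FALSE]; yte <- dataset$labels[sp$test]

  spec_atlas <- model_spec("atlas", d_model = config$d_model,
                           n_heads = config$n_heads,
                           n_transformer_layers = config$n_transformer_layers,
                           epochs = config$epochs, batch_size = config$batch_size,
                           patience = config$patience,
                           input_channels = dim(dataset$data)[2])
  spec_lstm <- model_spec("lstm", epochs = config$epochs,
                          batch_size = config$batch_size,
                          patience = config$patience,
                          input_channels = dim(dataset$data)[2])
  fit_a <- .stage("train_atlas", atlas_pd(xtr, ytr, xva, yva, spec = spec_atlas,
                                          seed_shuffle = config$seed_shuffle,
                                          seed_weights = config$seed_weights))
  fit_l <- .stage("train_lstm", lstm_net(xtr, ytr, xva, yva, spec = spec_lstm,
                                         seed_shuffle = config$seed_shuffle,
                                         seed_weights = config$seed_weights))
  utils::write.csv(fit_a$history, file.path(config$out_dir, "history_atlas.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_l$history, file.path(config$out_dir, "history_lstm.csv"),
                   row.names = FALSE)

  feats <- .stage("featurize", featurize(dataset))
  ftr <- feats[c(sp$train, sp$val), , drop = FALSE]
  ytrv <- dataset$labels[c(sp$train, sp$val)]
  fte <- feats[sp$test, , drop = FALSE]
  base_fits <- list(); cv_scores <- list()
  folds_eff <- max(2L, min(5L, min(table(ytrv))))
  for (b in config$baselines) {
    cv <- .stage(paste0("cv_", b), cross_validate(b, ftr, ytrv,
                                                  folds = folds_eff,
                                                  seed = config$seed_shuffle))
    base_fits[[b]] <- cv$final_fit
    cv_scores[[b]] <- cv$mean_accuracy
  }

  models <- c(list(atlas = fit_a, lstm = fit_l), base_fits)
  test_inputs <- c(list(atlas = xte, lstm = xte),
                   stats::setNames(rep(list(fte), length(base_fits)),
                                   names(base_fits)))
  reports <- list(); preds <- list()
  for (m in names(models)) {
    reports[[m]] <- .stage(paste0("evaluate_", m), evaluate_classifier(
      models[[m]], test_inputs[[m]], yte, bootstrap_n = config$bootstrap_n,
      seed = config$master_seed))
    preds[[m]] <- predict(models[[m]], test_inputs[[m]], type = "class")
  }
  mcn <- list()
  for (m in setdiff(names(models), "atlas"))
    mcn[[m]] <- mcnemar_test(preds$atlas, preds[[m]], yte,
                             bootstrap_n = config$bootstrap_n,
                             seed = config$master_seed)

  rob <- .stage("robustness", noise_robustness(
    fit_a, xte, yte, sigmas = config$noise_sigmas, reps = config$noise_reps,
    seed = config$master_seed))
  utils::write.csv(rob$curve, file.path(config$out_dir, "robustness_atlas.csv"),
                   row.names = FALSE)

  imp <- .stage("importance", permutation_importance(
    fit_a, xte, yte, repeats = config$importance_repeats,
    seed = config$master_seed, channel_ids = dataset$channel_ids))
  reg <- aggregate_by_region(imp, dataset$layout)
  utils::write.csv(imp$channels, file.path(config$out_dir, "importance_channels.csv"),
                   row.names = FALSE)
  utils::write.csv(reg, file.path(config$out_dir, "importance_regions.csv"),
                   row.names = FALSE)

  emb <- NULL
  if (length(yte) > 3 * 5 + 1) {
    emb <- .stage("embed", embed_features(fit_a, xte, yte,
                                          perplexity = min(30, floor(length(yte) / 3) - 1),
                                          seed = config$master_seed))
    utils::write.csv(emb$coords, file.path(config$out_dir, "tsne.csv"),
                     row.names = FALSE)
  }

  metrics <- lapply(reports, function(r) list(
    accuracy = r$accuracy, macro_f1 = r$macro_f1, macro_auc = r$macro_auc,
    accuracy_ci = if (!is.null(r$ci)) as.numeric(r$ci["accuracy", ]) else NULL))
  metrics$mcnemar <- lapply(mcn, function(m)
    list(b = m$b, c = m$c, chi2 = m$statistic, p = m$p_value))
  metrics$auc_robustness_atlas <- rob$auc_robustness
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = config$out_dir, reports = reports, robustness = rob,
                 importance = imp, regions = reg, mcnemar = mcn,
                 fits = models, embedding = emb, split = sp))
}
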