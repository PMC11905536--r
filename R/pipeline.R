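# End-to-end orchestration: preprocess -> SMOTE -> RF selection -> MLP ->
# OpenMax -> open-set prediction -> 92-label evaluation, with a manifest
# recording configuration, seeds and input hashes for reproducibility.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with the published defaults
#' where stated (4000 trees, sqrt mtry, 1000-probe panel with a 767-probe
#' comparison mode, SMOTE equalisation to the majority class) and
#' desk-scale defaults elsewhere. A single global `seed` fans out to
#' per-stage derived seeds so stages can be rerun independently and the
#' whole run is reproducible.
#'
#' @param n_probes Panel size (default 1000; capped at the number of
#'   available probes with a message). Set 767 for the comparison mode,
#'   or `"auto"` to keep every probe whose importance is clearly above
#'   the uniform share (see [select_above_uniform()]).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param num_trees,mtry Random-forest parameters (defaults 4000, sqrt).
#' @param hidden_units,learning_rate,momentum,max_epochs,patience,validation_fraction
#'   MLP parameters (see [train_mlp()]).
#' @param tail_size,openmax_mode,distance OpenMax parameters (see
#'   [fit_openmax()]).
#' @param tail_method `"extreme"` (default; extreme-value tail
#'   construction) or `"mle"` (direct fit on the `tail_size` largest
#'   distances).
#' @param calibration_fraction Fraction of the training originals set
#'   aside (stratified) as a held-out calibration cohort for the OpenMax
#'   distance tails; 0 disables calibration and fits tails on
#'   resubstitution distances.
#' @param mode `"92"` (default, open-set OpenMax prediction) or `"91"`
#'   (closed-set SoftMax argmax over the known classes).
#' @param batch_correction Apply the per-probe linear-model correction.
#' @param test_fraction Stratified held-out fraction per class.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_probes = 1000, smote_k = 5, num_trees = 4000,
                            mtry = NULL, hidden_units = 128,
                            learning_rate = 0.01, momentum = 0.9,
                            max_epochs = 200, patience = 10,
                            validation_fraction = 0.1, tail_size = 20,
                            openmax_mode = c("weibull_cdf", "as_printed"),
                            distance = c("euclidean", "cosine"),
                            tail_method = c("extreme", "mle"),
                            calibration_fraction = 0.15,
                            mode = c("92", "91"), batch_correction = TRUE,
                            test_fraction = 0.25, seed = 1) {
  cfg <- list(n_probes = n_probes, smote_k = smote_k, num_trees = num_trees,
              mtry = mtry, hidden_units = hidden_units,
              learning_rate = learning_rate, momentum = momentum,
              max_epochs = max_epochs, patience = patience,
              validation_fraction = validation_fraction,
              tail_size = tail_size, openmax_mode = match.arg(openmax_mode),
              distance = match.arg(distance),
              tail_method = match.arg(tail_method),
              calibration_fraction = calibration_fraction,
              mode = match.arg(mode),
              batch_correction = batch_correction,
              test_fraction = test_fraction, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: the path, invisibly;
#'   `read_pipeline_config`: the config (round-trips without loss).
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the full classification pipeline
#'
#' Executes the workflow stages in order on a beta matrix: probe
#' filtering, log2(v + 1) transform, batch correction (estimated jointly
#' on all supplied samples, without class labels), stratified train/test
#' split of the labelled known-class samples (novel/unlabelled samples are
#' never trained on and enter the test set with truth `"unknown"`), SMOTE
#' equalisation of the training classes, random-forest probe ranking,
#' top-K panel selection, MLP training, OpenMax fitting, open-set
#' prediction on the test set and 92-label evaluation (plus the filtered
#' known-truth evaluation).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet data.frame with `sample_id`, `class_label`,
#'   `batch` and optionally `is_novel` (novel samples may equivalently
#'   carry class_label `"unknown"`).
#' @param annotation Optional probe annotation for filtering.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the panel, predictions,
#'   evaluation report and a run manifest are written there.
#' @return A list: `panel`, `model`, `openmax`, `predictions` (data.frame
#'   with sample_id, truth, predicted class, calibrated score, p_unknown),
#'   `evaluation` (92-label report), `evaluation_filtered` (known truths
#'   only, evaluated over the known-class label set), `split`, `config`.
#' @export
run_pipeline <- function(beta, samples, annotation = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  validate_beta_matrix(beta)
  if (!all(samples$sample_id %in% colnames(beta)))
    stop("sample sheet contains samples absent from the matrix")
  beta <- beta[, samples$sample_id, drop = FALSE]
  is_novel <- if ("is_novel" %in% names(samples)) samples$is_novel
              else samples$class_label %in% c("unknown", NA)

  # --- preprocessing ---------------------------------------------------
  if (!is.null(annotation)) beta <- filter_probes(beta, annotation)
  lg <- log_transform(beta)
  if (config$batch_correction && length(unique(samples$batch)) > 1)
    lg <- remove_batch_effect(lg, samples$batch)
  x_all <- t(lg)  # samples x probes for modelling

  # --- split: known-class samples only are train-eligible --------------
  known_idx <- which(!is_novel)
  y_known <- samples$class_label[known_idx]
  sp <- split_cohort(y_known, config$test_fraction,
                     seed = derive_seed(config$seed, "split"))
  tr_all <- known_idx[sp$train]
  te <- c(known_idx[sp$test], which(is_novel))
  truth <- ifelse(is_novel[te], "unknown", samples$class_label[te])

  # held-out calibration split (original samples, never trained on)
  if (config$calibration_fraction > 0) {
    spc <- split_cohort(samples$class_label[tr_all],
                        config$calibration_fraction,
                        seed = derive_seed(config$seed, "calibration"))
    tr <- tr_all[spc$train]
    cal <- tr_all[spc$test]
  } else {
    tr <- tr_all
    cal <- integer(0)
  }
  y_train <- factor(samples$class_label[tr])

  # --- SMOTE + feature selection ---------------------------------------
  sm <- smote_oversample(x_all[tr, , drop = FALSE], y_train,
                         k_neighbors = config$smote_k,
                         seed = derive_seed(config$seed, "smote"))
  panel_full <- rf_importance(sm$x, sm$y, num_trees = config$num_trees,
                              mtry = config$mtry,
                              seed = derive_seed(config$seed, "rf"))
  if (identical(config$n_probes, "auto")) {
    panel <- select_above_uniform(panel_full)
  } else {
    k <- config$n_probes
    if (k > nrow(panel_full)) {
      message(sprintf("n_probes = %d exceeds available probes; using %d",
                      k, nrow(panel_full)))
      k <- nrow(panel_full)
    }
    panel <- select_top(panel_full, k)
  }

  # --- MLP + OpenMax ----------------------------------------------------
  x_tr <- sm$x[, panel$probe_id, drop = FALSE]
  model <- train_mlp(x_tr, sm$y,
                     hidden_units = config$hidden_units,
                     learning_rate = config$learning_rate,
                     momentum = config$momentum,
                     max_epochs = config$max_epochs,
                     patience = config$patience,
                     validation_fraction = config$validation_fraction,
                     seed = derive_seed(config$seed, "mlp"))
  # calibration cohort: the held-out calibration split plus the original
  # (non-synthetic) samples of the MLP's early-stopping validation split,
  # none of which contributed gradient updates
  val_orig <- model$val_idx[!sm$synthetic[model$val_idx]]
  x_cal <- rbind(
    if (length(cal)) x_all[cal, panel$probe_id, drop = FALSE],
    x_tr[val_orig, , drop = FALSE])
  y_cal <- c(if (length(cal)) samples$class_label[cal],
             as.character(sm$y[val_orig]))
  openmax <- fit_openmax(
    model, x_tr, sm$y,
    tail_size = config$tail_size,
    mode = config$openmax_mode,
    distance = config$distance,
    x_cal = if (NROW(x_cal) > 0) x_cal,
    y_cal = if (NROW(x_cal) > 0) y_cal,
    tail_method = if (config$openmax_mode == "weibull_cdf")
      config$tail_method else "mle",
    # familiar-range control at the cohort level: with the hypothetical
    # fresh cohort as large as the training cohort, about ln(2) known
    # samples per cohort-sized test set are expected beyond the boundary
    n_extreme = nrow(x_tr))

  # --- prediction -------------------------------------------------------
  x_te <- x_all[te, panel$probe_id, drop = FALSE]
  if (config$mode == "92") {
    pr <- predict_open(model, openmax, x_te)
    predictions <- data.frame(sample_id = samples$sample_id[te],
                              truth = truth,
                              predicted = as.character(pr$class),
                              calibrated_score = pr$score,
                              p_unknown = pr$p_unknown,
                              stringsAsFactors = FALSE)
  } else {
    p <- rbind(predict(model, x_te, type = "prob"))
    p92 <- append_unknown_to_closed(p)
    predictions <- data.frame(sample_id = samples$sample_id[te],
                              truth = truth,
                              predicted = model$classes[max.col(p, ties.method = "first")],
                              calibrated_score = apply(p, 1, max),
                              p_unknown = p92[, "unknown"],
                              stringsAsFactors = FALSE)
  }

  # --- evaluation -------------------------------------------------------
  labels92 <- c(model$classes, "unknown")
  y_true <- harmonize_labels(predictions$truth, model$classes)
  y_pred <- harmonize_labels(predictions$predicted, model$classes)
  evaluation <- f1_scores(y_true, y_pred, labels = labels92)
  fk <- filter_known(y_true, y_pred)
  evaluation_filtered <- f1_scores(fk$y_true, fk$y_pred, labels = model$classes)

  result <- list(panel = panel, model = model, openmax = openmax,
                 predictions = predictions, evaluation = evaluation,
                 evaluation_filtered = evaluation_filtered,
                 split = list(train = tr, test = te), config = config,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_probe_panel(panel, file.path(out_dir, "panel.csv"))
    data.table::fwrite(predictions, file.path(out_dir, "predictions.csv"))
    save_mlp(model, file.path(out_dir, "model"))
    save_openmax(openmax, file.path(out_dir, "openmax.json"))
    report <- list(
      f1_micro = evaluation$f1_micro, f1_macro = evaluation$f1_macro,
      f1_micro_filtered = evaluation_filtered$f1_micro,
      f1_macro_filtered = evaluation_filtered$f1_macro,
      n_test = nrow(predictions))
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      config = unclass(config),
      seed = config$seed,
      n_samples = ncol(beta), n_probes_input = nrow(beta),
      input_hash = digest_matrix(beta),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("methylosr")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      elapsed_sec = result$elapsed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

# Cheap content hash (sum-based) for run manifests; not cryptographic.
digest_matrix <- function(m) {
  v <- as.vector(m)
  sprintf("%.10e:%.10e:%d", sum(v), sum(v * seq_along(v) %% 97), length(v))
}
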