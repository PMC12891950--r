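#' Cross-model validation
#'
#' Applies a regressor pair trained on Luo-Rudy 1991 features to action
#' potentials from the structurally distinct ten Tusscher 2006 epicardial
#' model. Accuracy retained across models indicates the learned mapping
#' reflects physiology (Nernst-driven RMP shifts, K(ATP)-driven APD
#' shortening) rather than artifacts of one model's equations. A guard
#' rejects accidental same-model evaluation.
#'
#' @param pair A `regressor_pair` trained on LR91 data.
#' @param tt06_table Labeled feature table whose `model` column is
#'   `"tt06"`.
#' @return An `ap_evaluation` tagged `"tt06-validation"`.
#' @export
cross_model_validate <- function(pair, tt06_table) {
  if (!identical(pair$source_model, "lr91")) {
    abort("the regressor pair must be trained on LR91 data only.",
          class = "apdecon_protocol_error")
  }
  if (!all(tt06_table$model == "tt06")) {
    abort("validation table must come from the TT06 model (tag mismatch).",
          class = "apdecon_protocol_error")
  }
  evaluate(pair, tt06_table, tag = "tt06-validation")
}

#' Simulated pharmacological rescue
#'
#' Selects the most severely ATP-depleted cell of the TT06 validation
#' cohort (the severe-category row with maximal GK(ATP); ties broken by
#' maximal Ko), records its baseline biomarkers and predicted
#' \[K+\]o / pHi, then applies a virtual drug that completely blocks the
#' ATP-sensitive potassium channel (GK(ATP) = 0), re-simulates the same
#' cell — identical Ko and pHi — and re-analyzes it with the same
#' regressors. Only the simulation input GK(ATP) changes; the cell's true
#' Ko and pHi are untouched, so any improvement is in the predictions.
#'
#' @param pair A `regressor_pair` trained on LR91 data.
#' @param tt06_table Labeled TT06 feature table containing at least one
#'   severe-category row.
#' @param protocol Pacing protocol used for the re-simulation (identical
#'   to cohort generation by default).
#' @param config Study configuration.
#' @return A `rescue_report` list: `condition`, `baseline`/`treated`
#'   feature rows, `baseline_pred`/`treated_pred`, and a `delta` tibble.
#' @export
rescue_experiment <- function(pair, tt06_table,
                              protocol = stimulus_protocol(),
                              config = default_config()) {
  severe <- dplyr::filter(tt06_table, .data$category == "severe")
  if (nrow(severe) == 0) {
    abort("no severe-category row in the validation cohort.",
          class = "apdecon_protocol_error")
  }
  cell <- severe |>
    dplyr::arrange(dplyr::desc(.data$gkatp_ms_uf), dplyr::desc(.data$ko_mm)) |>
    dplyr::slice(1)

  baseline <- cell[FEATURE_COLS]
  baseline_pred <- predict(pair, baseline)

  treated_cond <- tibble::tibble(ko_mm = cell$ko_mm, phi = cell$phi,
                                 gkatp_ms_uf = 0, category = "severe")
  treated_trace <- simulate_ap(treated_cond, model = "tt06",
                               protocol = protocol, config = config)
  treated <- extract_features(treated_trace)
  treated_pred <- predict(pair, treated)

  delta <- tibble::tibble(
    quantity = c("apd90_ms", "rmp_mv", "ko_hat", "phi_hat"),
    baseline = c(baseline$apd90_ms, baseline$rmp_mv,
                 baseline_pred$ko_hat, baseline_pred$phi_hat),
    treated = c(treated$apd90_ms, treated$rmp_mv,
                treated_pred$ko_hat, treated_pred$phi_hat)) |>
    dplyr::mutate(change = .data$treated - .data$baseline)

  structure(list(
    condition = cell[c("ko_mm", "phi", "gkatp_ms_uf", "category")],
    baseline = baseline, treated = treated,
    baseline_pred = baseline_pred, treated_pred = treated_pred,
    delta = delta),
    class = "rescue_report")
}

#' @export
print.rescue_report <- function(x, ...) {
  cat(sprintf(
    "<rescue_report> severe TT06 cell: Ko %.2f mM, pHi %.2f, GKATP %.3f -> 0 mS/uF\n",
    x$condition$ko_mm, x$condition$phi, x$condition$gkatp_ms_uf))
  print(x$delta)
  invisible(x)
}

#' Run the full deconvolution study
#'
#' Reproduces the whole pipeline end to end: (1) generate the 150-AP LR91
#' training cohort and the 50-AP TT06 validation cohort; (2) split the
#' LR91 table 80/20 stratified by severity; (3) tune the forest
#' hyperparameters by 5-fold CV grid search; (4) train the 150-tree
#' potassium and pH regressors; (5) evaluate on the held-out LR91 split;
#' (6) cross-model validate on TT06; (7) run the simulated K(ATP)-block
#' rescue.
#'
#' @param config Study configuration, see [default_config()] /
#'   [read_config()].
#' @param seed Optional master seed; when given it overrides the cohort,
#'   validation and ML seeds with `seed`, `seed + 1`, `seed + 2`.
#' @param out_dir Optional directory; when given, feature tables (CSV),
#'   the per-row prediction tables, the model bundle and a JSON summary of
#'   every headline metric are written there.
#' @param verbose Log progress.
#' @return A list: `train_table`, `validation_table`, `split`,
#'   `hyperparameters`, `pair`, `holdout` and `transfer`
#'   (`ap_evaluation`s), `rescue`, and a flat `summary` list of the
#'   headline numbers.
#' @export
run_study <- function(config = default_config(), seed = NULL,
                      out_dir = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    config$cohort$training$seed <- seed
    config$cohort$validation$seed <- seed + 1L
    config$ml$seed <- seed + 2L
  }
  protocol <- do.call(stimulus_protocol, config$protocol)
  say <- function(...) if (verbose) message(sprintf(...))

  say("Generating LR91 training cohort (%d APs)...",
      sum(unlist(config$cohort$training$counts)))
  train_table <- generate_dataset(lr91_training_spec(config), protocol,
                                  config, verbose = FALSE)
  say("Generating TT06 validation cohort (%d APs)...",
      sum(unlist(config$cohort$validation$counts)))
  validation_table <- generate_dataset(tt06_validation_spec(config),
                                       protocol, config, verbose = FALSE)

  split <- split_cohort(train_table, config$ml$test_fraction,
                        seed = config$ml$seed)
  say("Tuning hyperparameters (%d grid points, %d-fold CV)...",
      nrow(default_grid(config)), config$ml$k_folds)
  hp <- tune_hyperparameters(split$train, default_grid(config),
                             k_folds = config$ml$k_folds,
                             n_trees = config$ml$n_trees,
                             seed = config$ml$seed)
  pair <- train_pair(split$train, hp, n_trees = config$ml$n_trees,
                     seed = config$ml$seed)

  holdout <- evaluate(pair, split$test, tag = "lr91-test")
  transfer <- cross_model_validate(pair, validation_table)
  rescue <- rescue_experiment(pair, validation_table, protocol, config)

  imp <- feature_importance(pair)
  top_feature <- function(target) {
    sub <- dplyr::filter(imp, .data$target == !!target)
    sub$feature[which.max(sub$importance)]
  }
  g_hold <- glance(holdout)
  g_trans <- glance(transfer)
  summary <- list(
    n_train = nrow(train_table),
    n_validation = nrow(validation_table),
    holdout_ko_mse = g_hold$mse_ko_mm,
    holdout_phi_mse = g_hold$mse_phi,
    transfer_ko_mse = g_trans$mse_ko_mm,
    transfer_phi_mse = g_trans$mse_phi,
    transfer_ko_spearman = g_trans$spearman_ko_mm,
    transfer_phi_spearman = g_trans$spearman_phi,
    top_feature_ko = top_feature("ko_mm"),
    top_feature_phi = top_feature("phi"),
    rescue_apd90_change_ms = rescue$delta$change[
      rescue$delta$quantity == "apd90_ms"],
    rescue_rmp_change_mv = rescue$delta$change[
      rescue$delta$quantity == "rmp_mv"],
    rescue_phi_hat_change = rescue$delta$change[
      rescue$delta$quantity == "phi_hat"])

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_table(train_table,
                        file.path(out_dir, "lr91_training_features.csv"))
    write_feature_table(validation_table,
                        file.path(out_dir, "tt06_validation_features.csv"))
    write_feature_table(tidy(holdout),
                        file.path(out_dir, "holdout_predictions.csv"))
    write_feature_table(tidy(transfer),
                        file.path(out_dir, "transfer_predictions.csv"))
    save_regressor_pair(pair, file.path(out_dir, "regressor_pair"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(train_table = train_table, validation_table = validation_table,
       split = split, hyperparameters = hp, pair = pair, holdout = holdout,
       transfer = transfer, rescue = rescue, summary = summary)
}
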