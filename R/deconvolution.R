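#' Default hyperparameter grid
#'
#' Grid searched by [tune_hyperparameters()]: tree depth limit
#' (0 = unlimited) crossed with the minimal node size eligible for a
#' split. The ensemble size is fixed at 150 trees and is not part of the
#' grid.
#'
#' @param config Study configuration.
#' @return A tibble with columns `max_depth` and `min_node_size`.
#' @export
default_grid <- function(config = default_config()) {
  tidyr::expand_grid(max_depth = config$ml$grid$max_depth,
                     min_node_size = config$ml$grid$min_node_size)
}

check_features <- function(table) {
  missing <- setdiff(FEATURE_COLS, names(table))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "apdecon_data_error")
  }
  bad <- which(!stats::complete.cases(table[FEATURE_COLS]) |
                 !apply(is.finite(as.matrix(table[FEATURE_COLS])), 1, all))
  if (length(bad) > 0) {
    abort(sprintf("non-finite feature value in row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apdecon_data_error")
  }
  invisible(TRUE)
}

fit_forest <- function(data, target, max_depth, min_node_size, n_trees,
                       seed) {
  ranger::ranger(
    dependent.variable.name = target,
    data = as.data.frame(data[, c(FEATURE_COLS, target)]),
    num.trees = n_trees,
    max.depth = max_depth,
    min.node.size = min_node_size,
    importance = "impurity",
    seed = seed,
    num.threads = 1)
}

#' Tune forest hyperparameters by cross-validated grid search
#'
#' For every grid point, runs k-fold cross-validation training one forest
#' per target (`ko_mm` and `phi`) and scores the point by the mean
#' absolute error of each target, standardized by that target's
#' standard deviation over the full training table and then averaged
#' across the two targets (so the mM-scale potassium error cannot dominate
#' the pH-scale error). Returns the grid point minimizing the average;
#' ties go to the smaller depth limit (unlimited counts as deepest), then
#' the earlier grid row.
#'
#' @param train Labeled feature table (training split).
#' @param grid Tibble of `max_depth` / `min_node_size` combinations.
#' @param k_folds Number of CV folds.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (fold assignment and forest fits).
#' @return A list with the selected `max_depth`, `min_node_size`, its
#'   standardized `score`, and the full `cv` results tibble.
#' @export
tune_hyperparameters <- function(train, grid = default_grid(), k_folds = 5,
                                 n_trees = 150, seed = 0) {
  if (nrow(grid) == 0) {
    abort("hyperparameter grid is empty.", class = "apdecon_spec_error")
  }
  if (nrow(train) < k_folds) {
    abort("fewer training rows than folds.", class = "apdecon_spec_error")
  }
  check_features(train)

  folds <- withr::with_seed(seed,
    sample(rep(seq_len(k_folds), length.out = nrow(train))))
  sds <- c(ko_mm = sd(train$ko_mm), phi = sd(train$phi))

  cv <- purrr::pmap_dfr(grid, function(max_depth, min_node_size) {
    maes <- purrr::map_dfr(seq_len(k_folds), function(f) {
      tr <- train[folds != f, , drop = FALSE]
      te <- train[folds == f, , drop = FALSE]
      purrr::map_dfr(c("ko_mm", "phi"), function(target) {
        fit <- fit_forest(tr, target, max_depth, min_node_size, n_trees,
                          seed)
        pred <- predict(fit, data = as.data.frame(te[FEATURE_COLS]))$predictions
        tibble::tibble(target = target,
                       mae = mean(abs(pred - te[[target]])))
      })
    })
    maes |>
      dplyr::group_by(.data$target) |>
      dplyr::summarise(cv_mae = mean(.data$mae), .groups = "drop") |>
      dplyr::mutate(max_depth = max_depth, min_node_size = min_node_size)
  })

  scores <- cv |>
    dplyr::mutate(std_mae = .data$cv_mae / sds[.data$target]) |>
    dplyr::group_by(.data$max_depth, .data$min_node_size) |>
    dplyr::summarise(score = mean(.data$std_mae), .groups = "drop")
  # preserve grid order for the final tie-break
  scores <- dplyr::left_join(
    dplyr::mutate(grid, .idx = dplyr::row_number()),
    scores, by = c("max_depth", "min_node_size"))
  depth_rank <- ifelse(scores$max_depth == 0, Inf, scores$max_depth)
  best <- scores[order(scores$score, depth_rank, scores$.idx), ][1, ]

  list(max_depth = best$max_depth, min_node_size = best$min_node_size,
       score = best$score, cv = cv)
}

#' Train the potassium/pH regressor pair
#'
#' Fits two independent random forests of `n_trees` bootstrap-resampled
#' trees on the six waveform biomarkers: one predicting extracellular
#' potassium (`ko_mm`), one predicting intracellular pH (`phi`).
#' Impurity-based feature importances are normalized to sum to one per
#' target.
#'
#' @param train Labeled feature table.
#' @param hyperparameters List with `max_depth` and `min_node_size`, e.g.
#'   from [tune_hyperparameters()].
#' @param n_trees Trees per forest (150 in the study design).
#' @param seed Integer seed; two trainings with the same seed produce
#'   identical forests.
#' @return A `regressor_pair` object with `predict()`, [evaluate()],
#'   [feature_importance()], [tidy()] and [glance()] methods.
#' @export
train_pair <- function(train, hyperparameters = list(max_depth = 0,
                                                     min_node_size = 5),
                       n_trees = 150, seed = 0) {
  if (nrow(train) == 0) {
    abort("training table is empty.", class = "apdecon_data_error")
  }
  check_features(train)
  hp <- hyperparameters
  k_model <- fit_forest(train, "ko_mm", hp$max_depth, hp$min_node_size,
                        n_trees, seed)
  ph_model <- fit_forest(train, "phi", hp$max_depth, hp$min_node_size,
                         n_trees, seed + 1L)
  normalize <- function(imp) {
    imp <- imp[FEATURE_COLS]
    if (sum(imp) > 0) imp / sum(imp) else imp
  }
  structure(list(
    k_model = k_model,
    ph_model = ph_model,
    hyperparameters = list(n_trees = n_trees, max_depth = hp$max_depth,
                           min_node_size = hp$min_node_size),
    seed = seed,
    importances = list(ko_mm = normalize(k_model$variable.importance),
                       phi = normalize(ph_model$variable.importance)),
    label_ranges = list(ko_mm = range(train$ko_mm), phi = range(train$phi)),
    source_model = unique(train$model) %||% NA_character_,
    n_train = nrow(train)),
    class = "regressor_pair")
}

#' @export
print.regressor_pair <- function(x, ...) {
  cat(sprintf(
    "<regressor_pair> %d trees, max_depth %s, min_node_size %d; trained on %d %s APs\n",
    x$hyperparameters$n_trees,
    ifelse(x$hyperparameters$max_depth == 0, "unlimited",
           x$hyperparameters$max_depth),
    x$hyperparameters$min_node_size, x$n_train,
    toupper(paste(x$source_model, collapse = "/"))))
  invisible(x)
}

#' Predict potassium and pH from waveform biomarkers
#'
#' @param object A `regressor_pair`.
#' @param new_data Data frame with the six biomarker columns (one or more
#'   rows).
#' @param ... Unused.
#' @return A tibble with `ko_hat` (mM) and `phi_hat` columns, one row per
#'   input row. Tree ensembles average leaf means, so predictions always
#'   lie within the range of the training labels.
#' @export
predict.regressor_pair <- function(object, new_data, ...) {
  check_features(new_data)
  nd <- as.data.frame(new_data[FEATURE_COLS])
  tibble::tibble(
    ko_hat = predict(object$k_model, data = nd)$predictions,
    phi_hat = predict(object$ph_model, data = nd)$predictions)
}

#' Evaluate a regressor pair on a labeled feature table
#'
#' Computes the per-target mean squared error between predicted and actual
#' values, plus the Spearman rank correlation, and keeps the per-row
#' predictions for plotting.
#'
#' @param pair A `regressor_pair`.
#' @param table Labeled feature table.
#' @param tag Dataset tag recorded in the report (e.g. `"lr91-test"`,
#'   `"tt06-validation"`).
#' @return An `ap_evaluation` object; see [tidy()] and [glance()].
#' @export
evaluate <- function(pair, table, tag = "lr91-test") {
  if (nrow(table) == 0) {
    abort("evaluation table is empty.", class = "apdecon_data_error")
  }
  pred <- predict(pair, table)
  predictions <- dplyr::bind_rows(
    tibble::tibble(target = "ko_mm", truth = table$ko_mm,
                   prediction = pred$ko_hat),
    tibble::tibble(target = "phi", truth = table$phi,
                   prediction = pred$phi_hat))
  metrics <- predictions |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      mse = mean((.data$prediction - .data$truth)^2),
      spearman = safe_spearman(.data$prediction, .data$truth),
      .groups = "drop")
  structure(list(metrics = metrics, predictions = predictions, tag = tag,
                 n = nrow(table)),
            class = "ap_evaluation")
}

# rank correlation, NA when degenerate (n < 2 or zero variance)
safe_spearman <- function(p, t) {
  if (length(p) < 2 || sd(p) == 0 || sd(t) == 0) return(NA_real_)
  suppressWarnings(cor(p, t, method = "spearman"))
}

#' @export
print.ap_evaluation <- function(x, ...) {
  cat(sprintf("<ap_evaluation> %s (n = %d)\n", x$tag, x$n))
  print(x$metrics)
  invisible(x)
}

#' Per-target feature importances
#'
#' Impurity-based importances of the six biomarkers, normalized to sum to
#' one per target.
#'
#' @param pair A `regressor_pair`.
#' @return A tibble with columns `target`, `feature`, `importance`.
#' @export
feature_importance <- function(pair) {
  purrr::imap_dfr(pair$importances, function(imp, target) {
    tibble::tibble(target = target, feature = names(imp),
                   importance = unname(imp))
  })
}

#' @rdname feature_importance
#' @param x A `regressor_pair` or `ap_evaluation`.
#' @param ... Unused.
#' @export
tidy.regressor_pair <- function(x, ...) feature_importance(x)

#' @rdname feature_importance
#' @export
glance.regressor_pair <- function(x, ...) {
  tibble::tibble(
    n_trees = x$hyperparameters$n_trees,
    max_depth = x$hyperparameters$max_depth,
    min_node_size = x$hyperparameters$min_node_size,
    seed = x$seed,
    source_model = paste(x$source_model, collapse = "/"),
    n_train = x$n_train)
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns the per-row predictions (long, one row per AP and
#' target); `glance()` returns a one-row summary with per-target MSE and
#' Spearman correlation.
#'
#' @param x An `ap_evaluation` from [evaluate()] or
#'   [cross_model_validate()].
#' @param ... Unused.
#' @export
tidy.ap_evaluation <- function(x, ...) x$predictions

#' @rdname tidy.ap_evaluation
#' @export
glance.ap_evaluation <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics, names_from = "target",
                             values_from = c("mse", "spearman"))
  dplyr::bind_cols(tibble::tibble(tag = x$tag, n = x$n), wide)
}

#' Plot predicted vs actual values of an evaluation
#'
#' @param object An `ap_evaluation`.
#' @param ... Unused.
#' @return A ggplot with one facet per target and the identity line.
#' @export
autoplot.ap_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$truth, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(title = sprintf("Predicted vs actual (%s)", object$tag),
                  x = "actual", y = "predicted") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-target feature importances
#'
#' @param pair A `regressor_pair`.
#' @return A ggplot object.
#' @export
plot_importance <- function(pair) {
  ggplot2::ggplot(feature_importance(pair),
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = "normalized impurity importance") +
    ggplot2::theme_minimal()
}

#' Persist / restore a trained regressor pair
#'
#' Writes a directory bundle: a JSON manifest (hyperparameters, seed,
#' source model, label ranges, normalized importances) plus the two forest
#' objects in R's native serialized form.
#'
#' @param pair A `regressor_pair`.
#' @param dir Bundle directory (created if needed).
#' @return `save_regressor_pair()` returns `dir` invisibly;
#'   `load_regressor_pair()` returns the restored `regressor_pair`.
#' @export
save_regressor_pair <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    hyperparameters = pair$hyperparameters,
    seed = pair$seed,
    source_model = pair$source_model,
    n_train = pair$n_train,
    label_ranges = pair$label_ranges,
    importances = lapply(pair$importances, as.list))  # keeps feature names
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(pair$k_model, file.path(dir, "k_model.rds"))
  saveRDS(pair$ph_model, file.path(dir, "ph_model.rds"))
  invisible(dir)
}

#' @rdname save_regressor_pair
#' @export
load_regressor_pair <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(
    k_model = readRDS(file.path(dir, "k_model.rds")),
    ph_model = readRDS(file.path(dir, "ph_model.rds")),
    hyperparameters = manifest$hyperparameters,
    seed = manifest$seed,
    importances = lapply(manifest$importances, function(x) unlist(x)),
    label_ranges = manifest$label_ranges,
    source_model = manifest$source_model,
    n_train = manifest$n_train),
    class = "regressor_pair")
}
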