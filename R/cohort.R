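#' Specify a simulated cohort
#'
#' A cohort specification names the ionic model, how many cells to draw per
#' severity category, the per-category parameter ranges, and the RNG seed.
#' `lr91_training_spec()` and `tt06_validation_spec()` return the default
#' study cohorts: 50/50/50 healthy/moderate/severe LR91 cells for training
#' and 25 moderate + 25 severe TT06 cells for cross-model validation.
#'
#' @param model `"lr91"` or `"tt06"`.
#' @param counts Named list/vector of per-category counts (>= 0); names
#'   must be a subset of `healthy`, `moderate`, `severe`.
#' @param seed Integer RNG seed for condition sampling.
#' @param ranges Per-category parameter ranges, each a list with two-element
#'   `ko`, `phi`, `gkatp` intervals nested inside the global bounds.
#' @param max_retries Redraws allowed per cohort slot when a sampled
#'   condition fails to produce an AP.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(model = c("lr91", "tt06"), counts, seed,
                        ranges = default_config()$cohort$ranges,
                        max_retries = 20) {
  model <- match.arg(model)
  counts <- as.list(counts)
  if (length(counts) == 0 || is.null(names(counts)) ||
      !all(names(counts) %in% names(ranges))) {
    abort("`counts` must be named by severity categories present in `ranges`.",
          class = "apdecon_spec_error")
  }
  if (any(unlist(counts) < 0)) {
    abort("counts must be non-negative.", class = "apdecon_spec_error")
  }
  b <- condition_bounds()
  for (cat in names(ranges)) {
    r <- ranges[[cat]]
    for (par in c("ko", "phi", "gkatp")) {
      iv <- r[[par]]
      if (length(iv) != 2 || iv[1] > iv[2] ||
          iv[1] < b[[par]][1] || iv[2] > b[[par]][2]) {
        abort(sprintf(
          "range `%s` of category '%s' must be an interval inside [%g, %g].",
          par, cat, b[[par]][1], b[[par]][2]),
          class = "apdecon_spec_error")
      }
    }
  }
  structure(list(model = model, counts = counts, seed = as.integer(seed),
                 ranges = ranges, max_retries = max_retries),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param config Study configuration, see [default_config()].
#' @export
lr91_training_spec <- function(config = default_config()) {
  tr <- config$cohort$training
  cohort_spec(tr$model, tr$counts, tr$seed, config$cohort$ranges,
              config$cohort$max_retries)
}

#' @rdname cohort_spec
#' @export
tt06_validation_spec <- function(config = default_config()) {
  va <- config$cohort$validation
  cohort_spec(va$model, va$counts, va$seed, config$cohort$ranges,
              config$cohort$max_retries)
}

#' Sample ischemic conditions for a cohort
#'
#' Draws each parameter independently and uniformly within its category
#' range. Deterministic under the spec's seed: the same spec always yields
#' the same conditions.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of conditions (`ko_mm`, `phi`, `gkatp_ms_uf`,
#'   `category`) with `sum(counts)` rows.
#' @export
sample_conditions <- function(spec) {
  withr::with_seed(spec$seed, sample_conditions_impl(spec))
}

sample_conditions_impl <- function(spec) {
  purrr::map_dfr(names(spec$counts), function(cat) {
    n <- spec$counts[[cat]]
    if (n == 0) return(NULL)
    purrr::map_dfr(seq_len(n), function(i) draw_condition(spec$ranges, cat))
  })
}

draw_condition <- function(ranges, cat) {
  r <- ranges[[cat]]
  tibble::tibble(
    ko_mm = runif(1, r$ko[1], r$ko[2]),
    phi = runif(1, r$phi[1], r$phi[2]),
    gkatp_ms_uf = runif(1, r$gkatp[1], r$gkatp[2]),
    category = cat)
}

#' Generate a labeled feature table
#'
#' The synthetic-data backbone of the study: samples ischemic conditions
#' per category, simulates each cell's paced action potential, extracts the
#' six biomarkers, and joins the ground-truth labels and the source-model
#' tag. A sampled condition whose beat fails to elicit an AP (amplitude
#' < 10 mV) is logged, dropped and redrawn within the same category, up to
#' `max_retries` redraws per slot.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [stimulus_protocol()].
#' @param config Study configuration.
#' @param traces_dir Optional directory; when given, each AP trace is also
#'   written there as CSV via [write_ap_trace()].
#' @param verbose Log per-condition outcomes with `message()`.
#' @return A tibble with one row per AP: the six biomarker columns followed
#'   by `ko_mm`, `phi`, `gkatp_ms_uf`, `category`, `model`.
#' @export
generate_dataset <- function(spec, protocol = stimulus_protocol(),
                             config = default_config(), traces_dir = NULL,
                             verbose = FALSE) {
  if (!is.null(traces_dir) && !dir.exists(traces_dir)) {
    dir.create(traces_dir, recursive = TRUE)
  }
  withr::with_seed(spec$seed, {
    rows <- list()
    idx <- 0L
    for (cat in names(spec$counts)) {
      for (slot in seq_len(spec$counts[[cat]])) {
        cond <- draw_condition(spec$ranges, cat)
        tries <- 0
        repeat {
          trace <- simulate_ap(cond, model = spec$model, protocol = protocol,
                               config = config)
          if (!isTRUE(attr(trace, "failed"))) break
          tries <- tries + 1
          if (verbose) {
            message(sprintf(
              "[%s/%s slot %d] failed beat (Ko=%.2f, pHi=%.2f, GKATP=%.3f); redrawing",
              spec$model, cat, slot, cond$ko_mm, cond$phi, cond$gkatp_ms_uf))
          }
          if (tries > spec$max_retries) {
            abort(sprintf(
              "cohort generation aborted: category '%s' exceeded %d redraws.",
              cat, spec$max_retries), class = "apdecon_cohort_error")
          }
          cond <- draw_condition(spec$ranges, cat)
        }
        idx <- idx + 1L
        if (!is.null(traces_dir)) {
          write_ap_trace(trace, file.path(
            traces_dir, sprintf("%s_%s_%03d.csv", spec$model, cat, idx)))
        }
        feats <- extract_features(trace)
        if (verbose) {
          message(sprintf(
            "[%s/%s slot %d] Ko=%.2f pHi=%.2f GKATP=%.3f -> APD90=%.1f ms",
            spec$model, cat, slot, cond$ko_mm, cond$phi, cond$gkatp_ms_uf,
            feats$apd90_ms))
        }
        rows[[idx]] <- dplyr::bind_cols(feats, cond,
                                        tibble::tibble(model = spec$model))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Stratified train/test split of a feature table
#'
#' Splits a labeled feature table into training and held-out test subsets,
#' stratified by severity category, under a fixed seed.
#'
#' @param table A labeled feature table.
#' @param test_fraction Fraction of each category held out.
#' @param seed Integer seed for the split.
#' @return A list with tibbles `train` and `test`.
#' @export
split_cohort <- function(table, test_fraction = 0.2, seed = 0) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  withr::with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(table)), table$category),
                              function(ix) {
      sample(ix, size = max(1, round(length(ix) * test_fraction)))
    }))
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE])
}
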