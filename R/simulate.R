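#' Define a pacing protocol
#'
#' The stimulus protocol paces the cell to a quasi-steady state before the
#' beat that is analyzed. Defaults: a -52 uA/uF, 1 ms depolarizing pulse at
#' a basic cycle length of 1000 ms, 10 conditioning beats, analysis of
#' beat 10. The stimulus fires `stim_delay` ms into each cycle so the
#' recorded analysis beat starts 1 ms before stimulus onset.
#'
#' @param amplitude Stimulus current density, uA/uF; negative values
#'   depolarize.
#' @param duration Pulse width, ms.
#' @param bcl Basic cycle length (pacing interval), ms.
#' @param n_beats Number of paced beats.
#' @param analysis_beat Index of the beat returned as the trace.
#' @param stim_delay Quiescent interval recorded before the stimulus, ms.
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(amplitude = -52, duration = 1, bcl = 1000,
                              n_beats = 10, analysis_beat = n_beats,
                              stim_delay = 1) {
  stopifnot(duration > 0, stim_delay >= 0, stim_delay + duration < bcl,
            n_beats >= 1, analysis_beat >= 1, analysis_beat <= n_beats)
  structure(list(amplitude = amplitude, duration = duration, bcl = bcl,
                 n_beats = n_beats, analysis_beat = analysis_beat,
                 stim_delay = stim_delay),
            class = "stimulus_protocol")
}

#' Simulate a paced action potential
#'
#' Integrates the chosen ionic model under an ischemic condition with a
#' stiff adaptive solver (lsoda, rtol = atol = 1e-6 by default), pacing
#' `n_beats` cycles from the model's published resting state, and returns
#' the analysis beat sampled on a uniform 0.05 ms grid from 1 ms before
#' stimulus onset to the end of the cycle.
#'
#' @param condition A one-row data frame (or named list) with `ko_mm`,
#'   `phi`, `gkatp_ms_uf`, e.g. from [ischemic_condition()].
#' @param model `"lr91"` or `"tt06"` (epicardial).
#' @param protocol A [stimulus_protocol()].
#' @param config Study configuration, see [default_config()].
#' @return An `ap_trace`: a tibble with columns `time_ms` (relative to the
#'   start of the analysis cycle) and `vm_mv`, carrying attributes
#'   `stim_onset`, `model`, `condition`, `protocol` and `failed` (`TRUE`
#'   when the beat never rose 10 mV above rest, i.e. no AP was elicited).
#' @examples
#' \donttest{
#' tr <- ischemic_condition(5.4, 7.4, 0) |> simulate_ap()
#' extract_features(tr)
#' }
#' @export
simulate_ap <- function(condition, model = c("lr91", "tt06"),
                        protocol = stimulus_protocol(),
                        config = default_config()) {
  model <- match.arg(model)
  cond <- as.list(condition)
  validate_condition(cond$ko_mm, cond$phi, cond$gkatp_ms_uf)

  pars <- switch(model,
    lr91 = lr91_params(cond$ko_mm, cond$phi, cond$gkatp_ms_uf, 0, config),
    tt06 = tt06_params(cond$ko_mm, cond$phi, cond$gkatp_ms_uf, 0, config))
  y <- switch(model, lr91 = lr91_initial_state(),
              tt06 = tt06_initial_state())
  sol <- config$solver
  pr <- protocol

  segments <- beat_segments(pr)
  trace <- NULL
  for (beat in seq_len(pr$n_beats)) {
    dense <- beat == pr$analysis_beat
    beat_out <- vector("list", length(segments))
    for (k in seq_along(segments)) {
      seg <- segments[[k]]
      times <- if (dense) {
        seq(seg$t0, seg$t1, by = sol$dt_out)
      } else {
        c(seg$t0, seg$t1)
      }
      pars[["istim"]] <- seg$istim
      out <- integrate_segment(model, y, times, pars, sol, cond)
      y <- out[nrow(out), -1]
      if (dense) beat_out[[k]] <- out
    }
    if (dense) {
      rows <- do.call(rbind, lapply(seq_along(beat_out), function(k) {
        o <- beat_out[[k]]
        if (k > 1) o <- o[-1, , drop = FALSE]  # drop duplicated boundary
        o
      }))
      trace <- tibble::tibble(time_ms = rows[, 1], vm_mv = rows[, 2])
    }
  }

  rest <- trace$vm_mv[max(which(trace$time_ms < pr$stim_delay))]
  failed <- (max(trace$vm_mv) - rest) < 10
  structure(trace,
            stim_onset = pr$stim_delay,
            model = model,
            condition = tibble::as_tibble(cond),
            protocol = pr,
            failed = failed,
            class = c("ap_trace", class(trace)))
}

beat_segments <- function(pr) {
  segs <- list()
  if (pr$stim_delay > 0) {
    segs <- c(segs, list(list(t0 = 0, t1 = pr$stim_delay, istim = 0)))
  }
  c(segs,
    list(list(t0 = pr$stim_delay, t1 = pr$stim_delay + pr$duration,
              istim = pr$amplitude),
         list(t0 = pr$stim_delay + pr$duration, t1 = pr$bcl, istim = 0)))
}

integrate_segment <- function(model, y, times, pars, sol, cond) {
  out <- tryCatch(
    deSolve::ode(y = as.double(y), times = times,
                 func = paste0(model, "_derivs"),
                 parms = as.double(pars),
                 dllname = "apdecon",
                 initfunc = paste0(model, "_initparms"),
                 rtol = sol$rtol, atol = sol$atol, method = "lsoda"),
    warning = function(w) {
      abort(simulation_error_msg(model, cond, conditionMessage(w)),
            class = "apdecon_simulation_error")
    })
  out <- unclass(out)
  if (nrow(out) != length(times) || any(!is.finite(out))) {
    abort(simulation_error_msg(model, cond, "non-finite or truncated solution"),
          class = "apdecon_simulation_error")
  }
  out
}

simulation_error_msg <- function(model, cond, why) {
  sprintf(
    "%s integration failed (Ko=%.3g mM, pHi=%.3g, GKATP=%.3g mS/uF): %s",
    toupper(model), cond$ko_mm, cond$phi, cond$gkatp_ms_uf, why)
}

#' @export
print.ap_trace <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf(
    "<ap_trace> %s | Ko %.2f mM, pHi %.2f, GKATP %.3f mS/uF%s\n",
    toupper(attr(x, "model")), cond$ko_mm, cond$phi, cond$gkatp_ms_uf,
    if (isTRUE(attr(x, "failed"))) " [failed beat]" else ""))
  NextMethod()
}

#' Plot an action potential trace
#'
#' @param object An `ap_trace` from [simulate_ap()].
#' @param ... Unused.
#' @return A ggplot object (membrane potential vs time).
#' @export
autoplot.ap_trace <- function(object, ...) {
  cond <- attr(object, "condition")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$vm_mv)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "time (ms)", y = "membrane potential (mV)",
      title = sprintf("%s action potential", toupper(attr(object, "model"))),
      subtitle = sprintf("Ko %.2f mM, pHi %.2f, GKATP %.3f mS/uF",
                         cond$ko_mm, cond$phi, cond$gkatp_ms_uf)) +
    ggplot2::theme_minimal()
}

#' Write / read an AP trace as CSV
#'
#' Two-column CSV (`time_ms`, `vm_mv`) with a commented metadata header
#' recording the model and the ischemic condition, one file per AP.
#'
#' @param trace An `ap_trace`.
#' @param path File path.
#' @return `write_ap_trace()` returns `path` invisibly; `read_ap_trace()`
#'   returns an `ap_trace` (without the protocol attribute).
#' @export
write_ap_trace <- function(trace, path) {
  cond <- attr(trace, "condition")
  header <- c(
    sprintf("# model: %s", attr(trace, "model")),
    sprintf("# ko_mm: %.17g", cond$ko_mm),
    sprintf("# phi: %.17g", cond$phi),
    sprintf("# gkatp_ms_uf: %.17g", cond$gkatp_ms_uf),
    sprintf("# category: %s", cond$category %||% NA_character_),
    sprintf("# stim_onset: %.17g", attr(trace, "stim_onset")))
  writeLines(header, path)
  suppressWarnings(utils::write.table(
    data.frame(time_ms = trace$time_ms, vm_mv = trace$vm_mv),
    path, append = TRUE, sep = ",", row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_ap_trace
#' @export
read_ap_trace <- function(path) {
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  cond <- tibble::tibble(ko_mm = as.numeric(meta$ko_mm),
                         phi = as.numeric(meta$phi),
                         gkatp_ms_uf = as.numeric(meta$gkatp_ms_uf),
                         category = meta$category)
  trace <- tibble::as_tibble(df)
  rest <- trace$vm_mv[max(which(trace$time_ms < as.numeric(meta$stim_onset)))]
  structure(trace,
            stim_onset = as.numeric(meta$stim_onset),
            model = meta$model,
            condition = cond,
            failed = (max(trace$vm_mv) - rest) < 10,
            class = c("ap_trace", class(trace)))
}
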