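#' Extract the six electrophysiological biomarkers from an AP trace
#'
#' Computes, from a uniformly sampled membrane-potential trace:
#' \describe{
#'   \item{`rmp_mv`}{Resting membrane potential: the sample immediately
#'     preceding stimulus onset.}
#'   \item{`peak_mv`}{Maximum potential after stimulus onset.}
#'   \item{`apa_mv`}{Action potential amplitude, `peak_mv - rmp_mv`.}
#'   \item{`dvdtmax_mv_ms`}{Maximum upstroke velocity: the largest forward
#'     difference slope between stimulus onset and the peak.}
#'   \item{`apd90_ms`, `apd50_ms`}{Action potential duration at 90% / 50%
#'     repolarization: time from activation (the instant of maximum
#'     upstroke velocity, first sample on ties) to the first downward
#'     crossing of `peak - x% * APA` after the peak, located by linear
#'     interpolation between samples.}
#' }
#'
#' @param trace An `ap_trace` from [simulate_ap()], or any data frame with
#'   `time_ms` and `vm_mv` columns.
#' @param stim_onset Stimulus onset time, ms; defaults to the trace
#'   attribute.
#' @return A one-row tibble with the six biomarkers.
#' @examples
#' pulse <- tibble::tibble(
#'   time_ms = seq(0, 250, by = 0.05),
#'   vm_mv = approx(x = c(0, 1, 2, 202, 250), y = c(-80, -80, 20, -80, -80),
#'                  xout = seq(0, 250, by = 0.05))$y)
#' extract_features(pulse, stim_onset = 1)
#' @export
extract_features <- function(trace, stim_onset = NULL) {
  stim_onset <- stim_onset %||% attr(trace, "stim_onset")
  if (is.null(stim_onset)) {
    abort("`stim_onset` is required when `trace` is not an `ap_trace`.",
          class = "apdecon_domain_error")
  }
  t <- trace$time_ms
  v <- trace$vm_mv
  if (length(t) < 3 || is.unsorted(t, strictly = TRUE)) {
    abort("trace must have a strictly increasing time grid.",
          class = "apdecon_domain_error")
  }

  pre <- which(t < stim_onset)
  if (length(pre) == 0) {
    abort("no samples precede stimulus onset.", class = "apdecon_domain_error")
  }
  rmp <- v[max(pre)]

  post <- which(t >= stim_onset)
  peak_rel <- which.max(v[post])
  peak_idx <- post[peak_rel]
  peak <- v[peak_idx]
  apa <- peak - rmp
  if (apa < 10) {
    abort(sprintf("degenerate trace: amplitude %.2f mV < 10 mV (failed beat).",
                  apa),
          class = "apdecon_degenerate_trace")
  }

  # upstroke: forward differences from stimulus onset to the peak
  up <- post[1]:max(post[1], peak_idx - 1)
  slopes <- (v[up + 1] - v[up]) / (t[up + 1] - t[up])
  dvdtmax <- max(slopes)
  # first sample attaining the maximum, with a relative tolerance so that
  # floating-point jitter on an analytically flat upstroke cannot push the
  # activation time to a later sample
  tie_tol <- 1e-9 * max(1, abs(dvdtmax))
  act_idx <- up[which(slopes >= dvdtmax - tie_tol)[1]]
  t_act <- t[act_idx]

  tibble::tibble(
    rmp_mv = rmp, peak_mv = peak, apa_mv = apa, dvdtmax_mv_ms = dvdtmax,
    apd90_ms = apd_at(t, v, peak_idx, peak - 0.90 * apa, t_act),
    apd50_ms = apd_at(t, v, peak_idx, peak - 0.50 * apa, t_act))
}

# first downward crossing of `thr` after the peak, linearly interpolated
apd_at <- function(t, v, peak_idx, thr, t_act) {
  i <- peak_idx
  n <- length(v)
  while (i < n) {
    if (v[i] >= thr && v[i + 1] < thr) {
      t_cross <- t[i] + (v[i] - thr) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
      return(t_cross - t_act)
    }
    i <- i + 1
  }
  abort(sprintf(
    "incomplete repolarization: trace never crosses %.2f mV after the peak.",
    thr), class = "apdecon_incomplete_repolarization")
}

#' Write / read a labeled feature table as CSV
#'
#' Plain CSV with one row per AP: the six biomarkers plus the ground-truth
#' condition (`ko_mm`, `phi`, `gkatp_ms_uf`, `category`) and the source
#' `model` tag.
#'
#' @param table A feature tibble, e.g. from [generate_dataset()].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
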