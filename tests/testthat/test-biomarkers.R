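test_that("piecewise-linear pulse biomarkers match their closed form exactly", {
  # flat -80 mV baseline, 1 ms rise to +20 mV, 200 ms fall back to -80:
  # RMP -80, Peak +20, APA 100, dV/dtmax 100 mV/ms,
  # APD90 = 1 + 90/0.5 = 181 ms, APD50 = 1 + 50/0.5 = 101 ms
  f <- extract_features(make_pulse_trace(), stim_onset = 1)
  expect_equal(f$rmp_mv, -80, tolerance = 1e-9)
  expect_equal(f$peak_mv, 20, tolerance = 1e-9)
  expect_equal(f$apa_mv, 100, tolerance = 1e-9)
  expect_equal(f$dvdtmax_mv_ms, 100, tolerance = 1e-9)
  expect_equal(f$apd90_ms, 181, tolerance = 1e-9)
  expect_equal(f$apd50_ms, 101, tolerance = 1e-9)
})

test_that("degenerate and incomplete traces raise typed errors", {
  flat <- tibble::tibble(time_ms = seq(0, 100, 0.05), vm_mv = -85)
  expect_error(extract_features(flat, stim_onset = 1),
               class = "apdecon_degenerate_trace")
  # truncate before 90% repolarization
  cut <- dplyr::filter(make_pulse_trace(), time_ms <= 100)
  expect_error(extract_features(cut, stim_onset = 1),
               class = "apdecon_incomplete_repolarization")
  expect_error(extract_features(make_pulse_trace()),
               class = "apdecon_domain_error")  # stim_onset unknown
})

test_that("voltage offset shifts potentials but leaves durations and slopes", {
  tr <- make_pulse_trace()
  f0 <- extract_features(tr, stim_onset = 1)
  for (offset in c(-12.5, 40)) {
    f1 <- extract_features(dplyr::mutate(tr, vm_mv = vm_mv + offset),
                           stim_onset = 1)
    expect_equal(f1$rmp_mv, f0$rmp_mv + offset, tolerance = 1e-9)
    expect_equal(f1$peak_mv, f0$peak_mv + offset, tolerance = 1e-9)
    expect_equal(f1$apa_mv, f0$apa_mv, tolerance = 1e-9)
    expect_equal(f1$dvdtmax_mv_ms, f0$dvdtmax_mv_ms, tolerance = 1e-9)
    expect_equal(f1$apd90_ms, f0$apd90_ms, tolerance = 1e-9)
    expect_equal(f1$apd50_ms, f0$apd50_ms, tolerance = 1e-9)
  }
})

test_that("time dilation scales durations by k and slopes by 1/k", {
  tr <- baseline_trace("lr91")
  f0 <- extract_features(tr)
  for (k in c(0.5, 2)) {
    dil <- tibble::tibble(time_ms = tr$time_ms * k, vm_mv = tr$vm_mv)
    f1 <- extract_features(dil, stim_onset = 1 * k)
    expect_equal(f1$apd90_ms, f0$apd90_ms * k, tolerance = 1e-9)
    expect_equal(f1$apd50_ms, f0$apd50_ms * k, tolerance = 1e-9)
    expect_equal(f1$dvdtmax_mv_ms, f0$dvdtmax_mv_ms / k, tolerance = 1e-9)
    expect_equal(f1$apa_mv, f0$apa_mv, tolerance = 1e-9)
  }
})

test_that("features agree with an independent re-implementation on a real AP", {
  # brute-force oracle written against the same sampled trace
  oracle <- function(t, v, onset) {
    rmp <- v[tail(which(t < onset), 1)]
    after <- t >= onset
    pk <- which(after)[which.max(v[after])]
    apa <- v[pk] - rmp
    sl <- -Inf; act <- NA
    for (i in which(after)[1]:(pk - 1)) {
      s <- (v[i + 1] - v[i]) / (t[i + 1] - t[i])
      if (s > sl) { sl <- s; act <- t[i] }
    }
    apd <- function(x) {
      thr <- v[pk] - x / 100 * apa
      for (i in pk:(length(v) - 1)) {
        if (v[i] >= thr && v[i + 1] < thr) {
          return(t[i] + (v[i] - thr) / (v[i] - v[i + 1]) *
                   (t[i + 1] - t[i]) - act)
        }
      }
      NA_real_
    }
    c(rmp = rmp, peak = v[pk], apa = apa, dvdt = sl,
      apd90 = apd(90), apd50 = apd(50))
  }
  tr <- baseline_trace("lr91")
  o <- oracle(tr$time_ms, tr$vm_mv, attr(tr, "stim_onset"))
  f <- extract_features(tr)
  expect_lt(abs(f$rmp_mv - o["rmp"]), 0.1)
  expect_lt(abs(f$peak_mv - o["peak"]), 0.1)
  expect_lt(abs(f$apa_mv - o["apa"]), 0.1)
  expect_lt(abs(f$apd90_ms - o["apd90"]), 0.1)
  expect_lt(abs(f$apd50_ms - o["apd50"]), 0.1)
  expect_equal(f$dvdtmax_mv_ms, unname(o["dvdt"]), tolerance = 1e-9)
})

test_that("invariants hold across the default LR91 cohort features", {
  tbl <- default_run()$train_table
  expect_equal(tbl$apa_mv, tbl$peak_mv - tbl$rmp_mv, tolerance = 1e-12)
  expect_true(all(tbl$apd50_ms <= tbl$apd90_ms))
  expect_true(all(tbl$dvdtmax_mv_ms > 0))
})
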