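test_that("derivative vectors at the published resting states match the reference implementation", {
  ref <- reference_baselines()
  d_lr <- lr91_derivatives(lr91_initial_state())
  d_tt <- tt06_derivatives(tt06_initial_state())
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  expect_lt(max(rel(unname(d_lr), ref$lr91_deriv_at_rest)), 1e-6)
  expect_lt(max(rel(unname(d_tt), ref$tt06_deriv_at_rest)), 1e-6)
})

test_that("gates clamped at their steady state have zero derivative", {
  # dg/dt = a(V)(1-g) - b(V)g is affine in g, so g_inf can be recovered
  # from derivative evaluations at g = 0 and g = 1 without access to the
  # rate functions; the derivative at g_inf must then vanish.
  for (model in c("lr91", "tt06")) {
    deriv <- switch(model, lr91 = lr91_derivatives, tt06 = tt06_derivatives)
    state0 <- switch(model, lr91 = lr91_initial_state(),
                     tt06 = tt06_initial_state())
    gates <- intersect(names(state0),
                       c("m", "h", "j", "d", "f", "f2", "x", "xr1", "xr2",
                         "xs", "s", "r"))
    for (v_clamp in c(-80, -40, 0, 20)) {
      st <- state0
      st["v"] <- v_clamp
      for (g in gates) {
        s0 <- st; s0[g] <- 0
        s1 <- st; s1[g] <- 1
        a <- deriv(s0)[g]          # alpha
        mb <- deriv(s1)[g]         # -beta
        g_inf <- a / (a - mb)
        st_inf <- st; st_inf[g] <- g_inf
        expect_lt(abs(deriv(st_inf)[g]), 1e-10)
      }
    }
  }
})

test_that("quiescent models settle to their known resting potentials", {
  ref <- reference_baselines()
  quiet <- stimulus_protocol(amplitude = 0, duration = 1, bcl = 1000,
                             n_beats = 10)
  v_lr <- pace_full("lr91", protocol = quiet)$beat_starts[10, "v"]
  expect_gt(v_lr, -85); expect_lt(v_lr, -83)
  expect_lt(abs(v_lr - ref$lr91_quiescent_v), 0.5)

  v_tt <- pace_full("tt06", protocol = quiet)$beat_starts[10, "v"]
  expect_gt(v_tt, -87); expect_lt(v_tt, -84)
  expect_lt(abs(v_tt - ref$tt06_quiescent_v), 0.5)

  # hyperkalemia: quiescent LR91 potential tracks E_K upward
  v_hyper <- pace_full("lr91", ko = 12.5, protocol = quiet)$beat_starts[10, "v"]
  expect_gt(v_hyper, -72)
  expect_lt(abs(v_hyper - ref$`lr91_quiescent_v_ko12.5`), 0.5)
})

test_that("unmodified models are recovered at baseline parameters", {
  # Ko = 5.4, pHi = 7.4, GKATP = 0 must leave the published equations
  # untouched: the ischemia terms contribute exactly nothing
  st <- lr91_initial_state()
  base <- lr91_derivatives(st)
  expect_equal(lr91_derivatives(st, ko_mm = 5.4, phi = 7.4, gkatp_ms_uf = 0),
               base, tolerance = 1e-12)
  # ... while each ischemic lever changes dV/dt
  expect_false(isTRUE(all.equal(
    lr91_derivatives(st, ko_mm = 8)["v"], base["v"])))
  expect_false(isTRUE(all.equal(
    lr91_derivatives(st, gkatp_ms_uf = 0.2)["v"], base["v"])))
})

test_that("gating variables remain inside [0,1] during paced integration", {
  for (model in c("lr91", "tt06")) {
    res <- pace_full(model, ko = 9, phi = 6.7, gkatp = 0.2)
    gates <- intersect(colnames(res$last_beat),
                       c("m", "h", "j", "d", "f", "f2", "fcass", "x",
                         "xr1", "xr2", "xs", "s", "r"))
    gm <- res$last_beat[, gates]
    expect_true(all(gm >= -1e-6 & gm <= 1 + 1e-6))
    # concentrations stay positive
    conc <- intersect(colnames(res$last_beat),
                      c("cai", "cass", "casr", "ki", "nai"))
    expect_true(all(res$last_beat[, conc] > 0))
  }
})

test_that("TT06 intracellular K+ does not drift at steady pacing", {
  res <- pace_full("tt06")
  ki <- res$beat_starts[, "ki"]
  expect_lt(abs(ki[10] - ki[9]), 0.1)  # mM per beat
})

test_that("state validation rejects malformed input", {
  expect_error(lr91_derivatives(rep(0, 5)), class = "apdecon_domain_error")
  st <- lr91_initial_state(); st["v"] <- NaN
  expect_error(lr91_derivatives(st), class = "apdecon_domain_error")
  expect_error(tt06_derivatives(rep(0.5, 18)), class = "apdecon_domain_error")
})
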