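#' @rdname lr91_derivatives
#' @export
lr91_state_names <- function() {
  c("v", "m", "h", "j", "d", "f", "x", "cai")
}

#' @rdname tt06_derivatives
#' @export
tt06_state_names <- function() {
  c("v", "ki", "nai", "cai", "cass", "casr", "rbar",
    "xr1", "xr2", "xs", "m", "h", "j", "d", "f", "f2", "fcass", "s", "r")
}

#' Published resting state of the Luo-Rudy 1991 model
#'
#' The quiescent initial condition at normokalemia from which every
#' simulation starts (each condition is simulated independently; no state
#' carry-over).
#' @return Named numeric vector of the 8 state variables.
#' @export
lr91_initial_state <- function() {
  c(v = -84.3801107371,
    m = 0.00171338077730188,
    h = 0.982660523699656,
    j = 0.989108212766685,
    d = 0.00302126301779861,
    f = 0.999967936476325,
    x = 0.0417603108167287,
    cai = 0.00017948816388306)
}

#' Published resting state of the ten Tusscher 2006 epicardial model
#' @return Named numeric vector of the 19 state variables.
#' @export
tt06_initial_state <- function() {
  c(v = -85.23, ki = 136.89, nai = 8.604, cai = 0.000126,
    cass = 0.00036, casr = 3.64, rbar = 0.9073,
    xr1 = 0.00621, xr2 = 0.4712, xs = 0.0095,
    m = 0.00172, h = 0.7444, j = 0.7045, d = 3.373e-5,
    f = 0.7888, f2 = 0.9755, fcass = 0.9953,
    s = 0.999998, r = 2.42e-8)
}

# Parameter vectors shared with the compiled right-hand sides; order must
# match src/lr91.c and src/tt06.c.
lr91_params <- function(ko, phi, gkatp, istim, config = default_config()) {
  phys <- config$physiology
  s <- acidosis_scale(phi, phys$acidosis_alpha)
  c(ko = ko, s_na = s, s_ca = s, gkatp = gkatp,
    katp_exp = phys$katp_exponent, istim = istim,
    ki = phys$lr91_ki_mm, g_na = 23, g_si = 0.09)
}

tt06_params <- function(ko, phi, gkatp, istim, config = default_config()) {
  phys <- config$physiology
  s <- acidosis_scale(phi, phys$acidosis_alpha)
  c(ko = ko, s_na = s, s_ca = s, gkatp = gkatp,
    katp_exp = phys$katp_exponent, istim = istim,
    g_na = 14.838, g_cal = 3.98e-5)
}

#' Evaluate the ionic-model right-hand sides
#'
#' Time derivatives of all state variables of the Luo-Rudy 1991
#' (`lr91_derivatives()`) or ten Tusscher 2006 epicardial
#' (`tt06_derivatives()`) model at a given state, with the three ischemia
#' modifications applied: `ko_mm` replaces extracellular K+ everywhere,
#' [acidosis_scale()] scales gNa and gsi/gCaL, and [ikatp_current()] is
#' added to the membrane current balance. With `ko_mm = 5.4`, `phi = 7.4`,
#' `gkatp_ms_uf = 0` the unmodified published models are recovered.
#'
#' These are thin wrappers over the compiled derivative kernels that
#' [simulate_ap()] integrates; they exist for inspection and testing of the
#' model equations.
#'
#' @param state Named or ordered numeric state vector (see
#'   `lr91_state_names()` / `tt06_state_names()`).
#' @param ko_mm,phi,gkatp_ms_uf Ischemia parameters.
#' @param istim Stimulus current density, uA/uF (negative = depolarizing).
#' @param config Study configuration, see [default_config()].
#' @return Named numeric vector of time derivatives (per ms).
#' @export
lr91_derivatives <- function(state, ko_mm = 5.4, phi = 7.4,
                             gkatp_ms_uf = 0, istim = 0,
                             config = default_config()) {
  validate_condition(ko_mm, phi, gkatp_ms_uf)
  state <- order_state(state, lr91_state_names())
  p <- lr91_params(ko_mm, phi, gkatp_ms_uf, istim, config)
  dy <- .Call("C_lr91_deriv", as.double(state), as.double(p),
              PACKAGE = "apdecon")
  setNames(dy, lr91_state_names())
}

#' @rdname lr91_derivatives
#' @export
tt06_derivatives <- function(state, ko_mm = 5.4, phi = 7.4,
                             gkatp_ms_uf = 0, istim = 0,
                             config = default_config()) {
  validate_condition(ko_mm, phi, gkatp_ms_uf)
  state <- order_state(state, tt06_state_names())
  p <- tt06_params(ko_mm, phi, gkatp_ms_uf, istim, config)
  dy <- .Call("C_tt06_deriv", as.double(state), as.double(p),
              PACKAGE = "apdecon")
  setNames(dy, tt06_state_names())
}

order_state <- function(state, nms) {
  if (length(state) != length(nms)) {
    abort(sprintf("state vector must have %d elements.", length(nms)),
          class = "apdecon_domain_error")
  }
  if (!is.null(names(state)) && all(nms %in% names(state))) {
    state <- state[nms]
  }
  if (any(!is.finite(state))) {
    abort("state vector contains non-finite values.",
          class = "apdecon_domain_error")
  }
  state
}
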