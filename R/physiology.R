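#' Nernst equilibrium potential for potassium
#'
#' Computes the K+ reversal potential \eqn{E_K = (RT/F)\,\ln([K^+]_o/[K^+]_i)}.
#' Elevated extracellular potassium (hyperkalemia) moves \eqn{E_K} toward
#' zero, which is why the resting membrane potential depolarizes during
#' ischemia.
#'
#' @param ko Extracellular potassium concentration, mM.
#' @param ki Intracellular potassium concentration, mM. Default 145 mM, the
#'   fixed intracellular K+ of the Luo-Rudy 1991 model.
#' @param temperature_k Absolute temperature, K. Default 310 K (37 C).
#' @return Equilibrium potential in mV. Vectorized over `ko`.
#' @examples
#' nernst_potassium(5.4)   # normokalemia, about -88 mV
#' nernst_potassium(12.5)  # severe hyperkalemia, about -65 mV
#' @export
nernst_potassium <- function(ko, ki = 145, temperature_k = 310) {
  if (any(ko <= 0) || any(ki <= 0) || any(temperature_k <= 0)) {
    abort("`ko`, `ki` and `temperature_k` must all be positive.",
          class = "apdecon_domain_error")
  }
  (8314.472 * temperature_k / 96485.3415) * log(ko / ki)
}

#' Acidosis conductance scale factor
#'
#' Intracellular acidosis reduces the maximal conductances of the fast
#' sodium current and the L-type/slow-inward calcium current. The reduction
#' is modeled as a linear function of the pH drop below the physiological
#' baseline of 7.4: `scale = max(0, 1 - alpha * (7.4 - phi))`. With the
#' default sensitivity `alpha = 0.25` per pH unit, severe acidosis
#' (pHi 6.5) reduces both conductances by 22.5%.
#'
#' @param phi Intracellular pH; must not exceed the 7.4 baseline (only
#'   acidosis is modeled).
#' @param alpha Fractional conductance reduction per pH unit, >= 0.
#' @return Dimensionless multiplicative scale in \[0, 1\].
#' @export
acidosis_scale <- function(phi, alpha = 0.25) {
  if (any(phi > 7.4)) {
    abort("`phi` must be <= 7.4: only acidosis (not alkalosis) is modeled.",
          class = "apdecon_domain_error")
  }
  if (any(alpha < 0)) {
    abort("`alpha` must be non-negative.", class = "apdecon_domain_error")
  }
  pmax(0, 1 - alpha * (7.4 - phi))
}

#' ATP-sensitive potassium current
#'
#' Current density of the sarcolemmal K(ATP) channel, the model's proxy for
#' ATP depletion. Uses the standard weak extracellular-K+ dependence of the
#' open-channel conductance:
#' \deqn{I_{K(ATP)} = G_{K(ATP)} (K_o/5.4)^{n} (V - E_K)}
#' with exponent `n = 0.24` and \eqn{E_K} from [nernst_potassium()].
#'
#' @param v Membrane potential, mV.
#' @param ko Extracellular potassium, mM.
#' @param gkatp Maximal conductance, mS/uF (equivalently nS/pF); 0 under
#'   normal ATP.
#' @param ki,temperature_k Passed to [nernst_potassium()].
#' @param exponent Ko-dependence exponent of the open-channel conductance.
#' @return Current density in uA/uF (numerically identical to pA/pF).
#' @export
ikatp_current <- function(v, ko, gkatp, ki = 145, temperature_k = 310,
                          exponent = 0.24) {
  if (any(gkatp < 0)) {
    abort("`gkatp` must be non-negative.", class = "apdecon_domain_error")
  }
  ek <- nernst_potassium(ko, ki, temperature_k)
  gkatp * (ko / 5.4)^exponent * (v - ek)
}
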