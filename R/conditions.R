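#' Construct an ischemic condition
#'
#' An ischemic condition is the ground-truth label of one simulated cell:
#' extracellular potassium `ko_mm` (hyperkalemia), intracellular pH `phi`
#' (acidosis) and the K(ATP) maximal conductance `gkatp_ms_uf` (ATP
#' depletion), plus a severity category. Values are validated against the
#' global physiological bounds of the framework: Ko in \[5.4, 12.5\] mM,
#' pHi in \[6.5, 7.4\], GK(ATP) in \[0, 0.3\] mS/uF.
#'
#' @param ko_mm Extracellular potassium, mM.
#' @param phi Intracellular pH.
#' @param gkatp_ms_uf K(ATP) maximal conductance, mS/uF.
#' @param category Severity category: `"healthy"`, `"moderate"` or
#'   `"severe"`.
#' @return A one-row tibble with columns `ko_mm`, `phi`, `gkatp_ms_uf`,
#'   `category`; rows from several calls can be combined with
#'   [dplyr::bind_rows()] and piped into [simulate_ap()].
#' @examples
#' ischemic_condition(5.4, 7.4, 0)            # healthy baseline
#' ischemic_condition(10, 6.7, 0.2, "severe")
#' @export
ischemic_condition <- function(ko_mm, phi, gkatp_ms_uf,
                               category = c("healthy", "moderate", "severe")) {
  category <- match.arg(category)
  validate_condition(ko_mm, phi, gkatp_ms_uf)
  tibble::tibble(ko_mm = ko_mm, phi = phi, gkatp_ms_uf = gkatp_ms_uf,
                 category = category)
}

condition_bounds <- function() {
  list(ko = c(5.4, 12.5), phi = c(6.5, 7.4), gkatp = c(0, 0.3))
}

validate_condition <- function(ko_mm, phi, gkatp_ms_uf) {
  b <- condition_bounds()
  check1 <- function(x, lim, what, unit) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        x < lim[1] || x > lim[2]) {
      abort(sprintf("%s must be a single value in [%g, %g] %s (got %s).",
                    what, lim[1], lim[2], unit, format(x)),
            class = "apdecon_domain_error")
    }
  }
  check1(ko_mm, b$ko, "Extracellular potassium `ko_mm`", "mM")
  check1(phi, b$phi, "Intracellular pH `phi`", "")
  check1(gkatp_ms_uf, b$gkatp, "K(ATP) conductance `gkatp_ms_uf`", "mS/uF")
  invisible(TRUE)
}
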