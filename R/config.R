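#' Default study configuration
#'
#' Returns the nested list of settings that govern every stage of the
#' pipeline: pacing protocol, physiological constants, solver tolerances,
#' cohort category ranges and seeds, and the machine-learning settings.
#' All values can be overridden from a YAML file via [read_config()]; a
#' documented copy of the schema ships at
#' `system.file("extdata", "default-config.yaml", package = "apdecon")`.
#'
#' The severity-category parameter ranges (mM for Ko, pH units for pHi,
#' mS/uF for GK(ATP)) define the package's graded ischemia protocol within
#' the global bounds Ko 5.4-12.5 mM, pHi 6.5-7.4,
#' GK(ATP) 0-0.3 mS/uF; see the package vignette for the rationale.
#'
#' @return A named nested list.
#' @export
default_config <- function() {
  list(
    protocol = list(
      amplitude = -52,     # uA/uF, negative = depolarizing
      duration = 1,        # ms
      bcl = 1000,          # ms, basic cycle length
      n_beats = 10,
      analysis_beat = 10,
      stim_delay = 1       # ms of quiescence recorded before the stimulus
    ),
    physiology = list(
      acidosis_alpha = 0.25,  # conductance reduction per pH unit
      katp_exponent = 0.24,   # Ko-dependence of the K(ATP) conductance
      temperature_k = 310,
      lr91_ki_mm = 145        # fixed intracellular K+ of the LR91 model
    ),
    solver = list(
      rtol = 1e-6,
      atol = 1e-6,
      dt_out = 0.05           # ms, output grid of the analysis beat
    ),
    cohort = list(
      training = list(model = "lr91", seed = 42,
                      counts = list(healthy = 50, moderate = 50, severe = 50)),
      validation = list(model = "tt06", seed = 43,
                        counts = list(moderate = 25, severe = 25)),
      max_retries = 20,
      ranges = list(
        healthy  = list(ko = c(5.4, 6.0),  phi = c(7.3, 7.4), gkatp = c(0, 0.01)),
        moderate = list(ko = c(7.0, 9.0),  phi = c(6.9, 7.1), gkatp = c(0.05, 0.15)),
        severe   = list(ko = c(9.0, 12.5), phi = c(6.5, 6.9), gkatp = c(0.15, 0.3))
      )
    ),
    ml = list(
      seed = 0,
      n_trees = 150,
      k_folds = 5,
      test_fraction = 0.2,
      grid = list(max_depth = c(0, 5, 10, 20),  # 0 = unlimited
                  min_node_size = c(2, 5, 10))
    )
  )
}

#' Read a study configuration file
#'
#' Reads a YAML configuration and merges it recursively over
#' [default_config()], so a file only needs to state the keys it changes.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  deep_merge(cfg, user)
}

deep_merge <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
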