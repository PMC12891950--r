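# apdecon study configuration (defaults).
# Any subset of keys may be overridden; omitted keys keep their defaults.

protocol:
  amplitude: -52.0      # stimulus current density, uA/uF (negative = depolarizing)
  duration: 1.0         # pulse width, ms
  bcl: 1000.0           # basic cycle length, ms
  n_beats: 10           # conditioning beats before analysis
  analysis_beat: 10     # beat returned as the trace
  stim_delay: 1.0       # quiescent ms recorded before the stimulus

physiology:
  acidosis_alpha: 0.25  # fractional gNa/gCaL reduction per pH unit below 7.4
  katp_exponent: 0.24   # Ko-dependence exponent of the K(ATP) conductance
  temperature_k: 310.0
  lr91_ki_mm: 145.0     # fixed intracellular K+ of the LR91 model, mM

solver:
  rtol: 1.0e-06
  atol: 1.0e-06
  dt_out: 0.05          # ms, uniform output grid of the analysis beat

cohort:
  training:
    model: lr91
    seed: 42
    counts: {healthy: 50, moderate: 50, severe: 50}
  validation:
    model: tt06
    seed: 43
    counts: {moderate: 25, severe: 25}
  max_retries: 20       # redraws allowed per slot after failed beats
  ranges:               # per-category sampling intervals
    healthy:
      ko: [5.4, 6.0]      # mM
      phi: [7.3, 7.4]
      gkatp: [0.0, 0.01]  # mS/uF
    moderate:
      ko: [7.0, 9.0]
      phi: [6.9, 7.1]
      gkatp: [0.05, 0.15]
    severe:
      ko: [9.0, 12.5]
      phi: [6.5, 6.9]
      gkatp: [0.15, 0.3]

ml:
  seed: 0
  n_trees: 150          # trees per forest (fixed, not tuned)
  k_folds: 5
  test_fraction: 0.2    # held-out share of the LR91 cohort
  grid:                 # grid-searched by 5-fold CV
    max_depth: [0, 5, 10, 20]       # 0 = unlimited
    min_node_size: [2, 5, 10]
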