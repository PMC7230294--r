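#' Bundled simulation scenarios
#'
#' Pre-configured [simulation_config()]s shaped like a paired crisis/steady
#' state targeted-metabolomics study on the default 188-metabolite panel:
#'
#' * `scenario_study()`: 39 pairs (plasma) or 40 pairs (rbc); 60 discriminant
#'   metabolites with log-fold effects of magnitude U(0.2, 0.8) and mixed
#'   signs; 35 poorly quantified null metabolites whose baseline sits at the
#'   LLOQ so that roughly half their values fall below it (these should be
#'   removed by the quantitation filter, leaving 153 measured metabolites).
#' * `scenario_strong_effect()`: as `scenario_study()` but effect magnitudes
#'   U(0.5, 0.8) — the parameter-recovery benchmark.
#' * `scenario_null()`: no planted effects — the calibration benchmark.
#'
#' @param seed Master seed for both metabolite selection and data generation.
#' @param matrix `"plasma"` (39 pairs) or `"rbc"` (40 pairs).
#' @param n_effects,n_poor Number of planted discriminant and poorly
#'   quantified metabolites.
#' @return A `simulation_config`.
#' @export
scenario_study <- function(seed = 1L, matrix = c("rbc", "plasma"),
                           n_effects = 60, n_poor = 35) {
  build_scenario(seed, match.arg(matrix), n_effects, n_poor,
                 effect_range = c(0.2, 0.8))
}

#' @rdname scenario_study
#' @export
scenario_strong_effect <- function(seed = 1L, matrix = c("rbc", "plasma"),
                                   n_effects = 60, n_poor = 35) {
  build_scenario(seed, match.arg(matrix), n_effects, n_poor,
                 effect_range = c(0.5, 0.8))
}

#' @rdname scenario_study
#' @export
scenario_null <- function(seed = 1L, matrix = c("rbc", "plasma"),
                          n_poor = 35) {
  build_scenario(seed, match.arg(matrix), 0, n_poor, effect_range = c(0, 0))
}

build_scenario <- function(seed, matrix, n_effects, n_poor, effect_range) {
  panel <- default_panel()
  n_pairs <- if (matrix == "plasma") 39L else 40L
  picks <- with_seed(derive_seed(seed, "scenario"), {
    poor <- sample(panel$metabolite_id, n_poor)
    eff <- sample(setdiff(panel$metabolite_id, poor), n_effects)
    mag <- runif(n_effects, effect_range[1], effect_range[2])
    sign <- rep_len(c(1, -1), n_effects)[sample.int(max(n_effects, 1))]
    list(poor = poor, eff = eff, delta = mag * sign[seq_len(n_effects)])
  })
  effects <- if (n_effects > 0) {
    tibble(metabolite_id = picks$eff, log_fold_effect = picks$delta)
  } else NULL
  baseline <- if (n_poor > 0) {
    i <- match(picks$poor, panel$metabolite_id)
    tibble(metabolite_id = picks$poor,
           log_mean = log(pmax(panel$lloq[i], 1e-6)),
           log_sd = NA_real_)
  } else NULL
  simulation_config(n_pairs, panel, effects = effects, baseline = baseline,
                    matrix = matrix, seed = seed)
}
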