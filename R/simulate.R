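#' Configure a synthetic paired-metabolomics simulation
#'
#' Builds the configuration for [simulate_dataset()]: a paired two-state
#' lognormal concentration model over a metabolite panel. Each metabolite j
#' has a baseline log-mean and log-sd; each patient contributes a shared
#' random intercept on the log scale, so the two states of one patient are
#' correlated with the configured `within_patient_corr`. Crisis effects are
#' additive shifts of the IC mean on the log scale (log-fold effects).
#'
#' Default baselines put each metabolite at the geometric midpoint of its
#' quantitation range with a log-sd drawn once per metabolite from
#' U(0.2, 0.6) — positive, right-skewed concentrations that rarely leave the
#' quantitation range unless a baseline is overridden.
#'
#' @param n_pairs Number of patients (>= 4); each contributes an IC and an OC
#'   sample.
#' @param panel Panel tibble (see [read_panel()]).
#' @param effects Tibble with columns `metabolite_id`, `log_fold_effect`
#'   (difference of mean log concentration, IC minus OC). Metabolites not
#'   listed have effect 0.
#' @param within_patient_corr Correlation in `[0, 1)` of a metabolite's log
#'   values across a patient's two states. Default 0.5.
#' @param baseline Optional tibble `metabolite_id, log_mean, log_sd`
#'   overriding the defaults for listed metabolites.
#' @param matrix Sample matrix label, `"plasma"` or `"rbc"`.
#' @param seed Master seed; per-metabolite streams are derived from it by
#'   keyed splitting, so adding metabolites does not reshuffle others.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_pairs, panel, effects = NULL,
                              within_patient_corr = 0.5, baseline = NULL,
                              matrix = "plasma", seed = 1L) {
  validate_panel(panel)
  if (n_pairs < 4) abort("n_pairs must be >= 4 (smaller designs cannot be split)")
  if (within_patient_corr < 0 || within_patient_corr >= 1) {
    abort("within_patient_corr must lie in [0, 1)")
  }
  if (is.null(effects)) {
    effects <- tibble(metabolite_id = character(), log_fold_effect = numeric())
  }
  effects <- as_tibble(effects)
  if (anyDuplicated(effects$metabolite_id)) {
    abort("effects must list each metabolite at most once")
  }
  bad <- setdiff(effects$metabolite_id, panel$metabolite_id)
  if (length(bad) > 0) {
    abort(paste0("effect metabolite(s) absent from panel: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(baseline)) {
    baseline <- as_tibble(baseline)
    bad <- setdiff(baseline$metabolite_id, panel$metabolite_id)
    if (length(bad) > 0) {
      abort(paste0("baseline metabolite(s) absent from panel: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(n_pairs = as.integer(n_pairs), panel = panel, effects = effects,
         within_patient_corr = within_patient_corr, baseline = baseline,
         matrix = matrix, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Default per-metabolite baseline: geometric midpoint of the quantitation
# range; log-sd drawn once per metabolite from its own derived stream.
default_baseline <- function(panel, seed) {
  log_mean <- (log(pmax(panel$lloq, 1e-6)) + log(panel$uloq)) / 2
  log_sd <- vapply(panel$metabolite_id, function(id) {
    with_seed(derive_seed(seed, paste0("sd/", id)), runif(1, 0.2, 0.6))
  }, numeric(1))
  tibble(metabolite_id = panel$metabolite_id, log_mean = log_mean,
         log_sd = unname(log_sd))
}

#' Simulate a paired two-state concentration dataset
#'
#' Draws, for every metabolite and patient, a bivariate-normal pair of log
#' concentrations (shared patient intercept giving the configured
#' within-patient correlation), adds the metabolite's log-fold effect to the
#' IC state, exponentiates, and derives censoring flags from the panel's
#' quantitation limits. Deterministic for a fixed config and seed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (a [paired_dataset()]) and `truth`
#'   (tibble `metabolite_id, log_fold_effect, discriminant` — the planted
#'   ground truth).
#' @examples
#' cfg <- simulation_config(8, default_panel()[1:10, ], seed = 42)
#' sim <- simulate_dataset(cfg)
#' sim$dataset
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$panel
  n <- config$n_pairs
  rho <- config$within_patient_corr

  base <- default_baseline(panel, config$seed)
  if (!is.null(config$baseline)) {
    i <- match(config$baseline$metabolite_id, base$metabolite_id)
    if ("log_mean" %in% names(config$baseline)) {
      base$log_mean[i] <- ifelse(is.na(config$baseline$log_mean),
                                 base$log_mean[i], config$baseline$log_mean)
    }
    if ("log_sd" %in% names(config$baseline)) {
      base$log_sd[i] <- ifelse(is.na(config$baseline$log_sd),
                               base$log_sd[i], config$baseline$log_sd)
    }
  }
  delta <- setNames(rep(0, nrow(panel)), panel$metabolite_id)
  delta[config$effects$metabolite_id] <- config$effects$log_fold_effect

  patient_ids <- sprintf("P%03d", seq_len(n))
  samples <- tibble(
    patient_id = rep(patient_ids, each = 2),
    state = rep(c("IC", "OC"), n),
    matrix = config$matrix
  )

  values <- matrix(NA_real_, nrow = 2 * n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$metabolite_id))
  for (j in seq_len(nrow(panel))) {
    id <- panel$metabolite_id[j]
    sdj <- base$log_sd[j]
    draws <- with_seed(derive_seed(config$seed, paste0("metab/", id)), {
      b <- rnorm(n, 0, sqrt(rho) * sdj)          # patient intercept
      e <- rnorm(2 * n, 0, sqrt(1 - rho) * sdj)  # state-specific noise
      list(b = b, e = e)
    })
    log_ic <- base$log_mean[j] + delta[[id]] + draws$b + draws$e[seq(1, 2 * n, 2)]
    log_oc <- base$log_mean[j] + draws$b + draws$e[seq(2, 2 * n, 2)]
    values[seq(1, 2 * n, 2), j] <- exp(log_ic)
    values[seq(2, 2 * n, 2), j] <- exp(log_oc)
  }

  ds <- apply_loq_censoring(paired_dataset(samples, values), panel)
  truth <- tibble(
    metabolite_id = panel$metabolite_id,
    log_fold_effect = unname(delta),
    discriminant = unname(delta) != 0
  )
  list(dataset = ds, truth = truth)
}
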