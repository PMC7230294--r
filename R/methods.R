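#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d component(s), %d metabolites, %d training samples\n",
              x$n_components, length(x$metabolites), nrow(x$scores)))
  if (!is.null(x$multilevel)) {
    cat(sprintf("  paired fit, multilevel decomposition: %s\n", x$multilevel))
  }
  cat(sprintf("  VIP >= 1: %d metabolite(s)\n", sum(x$vip >= 1)))
  invisible(x)
}

#' Tidy a fitted PLS-DA model
#'
#' One row per metabolite: VIP, oriented first-component loading (positive =
#' elevated in-crisis), per-component weights, and the implied direction.
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.plsda_model <- function(x, ...) {
  tibble(
    metabolite_id = x$metabolites,
    vip = unname(x$vip),
    loading = unname(x$oriented_loading),
    weight_1 = unname(x$W[, 1]),
    direction = ifelse(x$oriented_loading > 0, "increased", "decreased")
  )
}

#' @exportS3Method generics::glance
glance.plsda_model <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_metabolites = length(x$metabolites),
    n_samples = nrow(x$scores),
    n_vip_ge_1 = sum(x$vip >= 1),
    multilevel = isTRUE(x$multilevel)
  )
}

#' @export
print.plsda_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<plsda_ensemble> %d models (stride %s of %s combinations)\n",
              s$n_models, format(s$stride, scientific = FALSE),
              format(s$total_combinations, scientific = FALSE)))
  cat(sprintf("  validation: median AUROC %.3f, median p %.2g; AUROC >= 0.8: %d (%.0f%%)\n",
              s$median_val_auroc, s$median_val_p, s$n_val_auroc_ge_0.8,
              100 * s$n_val_auroc_ge_0.8 / s$n_models))
  cat(sprintf("  best models (AUROC >= %.2f): %d (%.1f%%)\n",
              x$config$bm_threshold, s$n_bm, 100 * s$bm_fraction))
  if (s$n_bm > 0) {
    cat(sprintf("  test: median AUROC %.3f, median p %.2g -> %s\n",
                s$median_test_auroc, s$median_test_p,
                if (s$pass) "PASS" else "FAIL"))
  } else {
    cat("  test: no best models -> FAIL\n")
  }
  invisible(x)
}

#' Tidy an ensemble result
#'
#' @param x A `plsda_ensemble`.
#' @param ... Unused.
#' @return The per-model tibble (`rank`, validation AUROC and p, best-model
#'   flag, test AUROC and p for best models).
#' @exportS3Method generics::tidy
tidy.plsda_ensemble <- function(x, ...) x$models

#' @exportS3Method generics::glance
glance.plsda_ensemble <- function(x, ...) {
  as_tibble(x$summary[c("n_models", "n_bm", "bm_fraction",
                        "n_val_auroc_ge_0.8", "median_val_auroc",
                        "median_val_p", "median_test_auroc", "median_test_p",
                        "pass")])
}

#' @export
print.paired_split <- function(x, ...) {
  cat(sprintf("<paired_split> trainval %d pairs / test %d pairs (seed %d)\n",
              length(x$trainval), length(x$test), x$seed))
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d pairs x %d metabolites (%s), %d planted effect(s), rho=%.2f, seed %d\n",
              x$n_pairs, nrow(x$panel), x$matrix, nrow(x$effects),
              x$within_patient_corr, x$seed))
  invisible(x)
}
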