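#' Bundled reference tables
#'
#' Small reference tables describing the paired crisis/steady-state targeted
#' metabolomics study design the pipeline reimplements, used by reports and
#' consistency checks:
#'
#' * `study_dimensions()`: per sample matrix, the number of patient pairs and
#'   the number of panel metabolites that passed quantitation QC.
#' * `reference_signature_breakdown(matrix)`: per-class counts of the
#'   discriminant metabolites (median VIP >= 1) reported for that matrix;
#'   their sum is the signature size (63 in plasma, 61 in red blood cells).
#'
#' @param matrix `"plasma"` or `"rbc"`.
#' @return A tibble.
#' @export
study_dimensions <- function() {
  readr::read_csv(system.file("extdata", "study_dimensions.csv",
                              package = "vocpls", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname study_dimensions
#' @export
reference_signature_breakdown <- function(matrix = c("plasma", "rbc")) {
  matrix <- match.arg(matrix)
  readr::read_csv(system.file("extdata",
                              paste0("signature_breakdown_", matrix, ".csv"),
                              package = "vocpls", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}
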