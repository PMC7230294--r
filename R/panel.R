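#' Metabolite panel specifications
#'
#' A panel specification is a tibble with one row per metabolite of a targeted
#' assay: its identifier, biochemical class, lower and upper limits of
#' quantitation (LLOQ/ULOQ, both in uM), and an optional acyl-chain carbon
#' count used to annotate lysophosphatidylcholines. The bundled default panel
#' has the composition of a 188-metabolite targeted kit: free carnitine (1),
#' acyl-carnitines (39), hexose (1), amino acids (21), biogenic amines (21)
#' and 105 lipids (14 lysoPC + 38 diacyl-PC + 38 acyl-alkyl-PC + 15
#' sphingomyelins).
#'
#' @param path Path to a panel file: CSV with header
#'   `metabolite_id,class,lloq,uloq[,acyl_carbons]`, or a JSON array of objects
#'   with the same fields.
#' @return A validated panel tibble.
#' @examples
#' panel <- default_panel()
#' panel_class_counts(panel)
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    panel <- as_tibble(raw)
  } else {
    panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!"acyl_carbons" %in% names(panel)) panel$acyl_carbons <- NA_integer_
  panel <- dplyr::mutate(
    panel,
    metabolite_id = as.character(.data$metabolite_id),
    class = as.character(.data$class),
    lloq = as.numeric(.data$lloq),
    uloq = as.numeric(.data$uloq),
    acyl_carbons = as.integer(.data$acyl_carbons)
  )
  validate_panel(panel)
  voc_log(event = "panel_loaded", n_metabolites = nrow(panel),
          classes = paste0(names(table(panel$class)), ":",
                           as.integer(table(panel$class)), collapse = ","))
  panel
}

#' @rdname read_panel
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "default_panel.csv", package = "vocpls",
                         mustWork = TRUE))
}

#' Validate a panel specification
#'
#' Checks the panel invariants: required columns, unique metabolite ids,
#' known class labels, and `0 <= lloq < uloq` for every entry.
#'
#' @param panel A panel tibble (see [read_panel()]).
#' @return The panel, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_panel <- function(panel) {
  required <- c("metabolite_id", "class", "lloq", "uloq")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- panel$metabolite_id[duplicated(panel$metabolite_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate metabolite id(s) in panel: ",
                 paste(unique(dup), collapse = ", ")))
  }
  unknown <- setdiff(unique(panel$class), metabolite_classes())
  if (length(unknown) > 0) {
    abort(paste0("unknown class label(s): ", paste(unknown, collapse = ", "),
                 "; expected one of ", paste(metabolite_classes(), collapse = ", ")))
  }
  if (any(is.na(panel$lloq)) || any(is.na(panel$uloq))) {
    abort("lloq/uloq must not contain missing values")
  }
  if (any(panel$lloq < 0)) abort("lloq must be >= 0 for every metabolite")
  bad <- panel$metabolite_id[panel$lloq >= panel$uloq]
  if (length(bad) > 0) {
    abort(paste0("lloq must be strictly below uloq; violated for: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(panel)
}

#' @rdname validate_panel
#' @export
metabolite_classes <- function() {
  c("free_carnitine", "acylcarnitine", "amino_acid", "biogenic_amine",
    "lysoPC", "PC_aa", "PC_ae", "sphingomyelin", "hexose")
}

#' @rdname read_panel
#' @export
panel_class_counts <- function(panel) {
  validate_panel(panel)
  dplyr::count(panel, .data$class, name = "n")
}
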