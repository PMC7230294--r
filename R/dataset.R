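#' Paired concentration datasets
#'
#' A `paired_dataset` holds a wide concentration table from a paired two-state
#' design: every patient contributes one in-crisis (`IC`) and one
#' out-of-crisis (`OC`) sample of the same matrix (`plasma` or `rbc`).
#' Concentrations are non-negative uM values; a parallel grid of censoring
#' flags records whether each value sits inside the assay's quantitation
#' range (`OK`), below the LLOQ (`BELOW_LLOQ`) or above the ULOQ
#' (`ABOVE_ULOQ`).
#'
#' @param samples Tibble with columns `patient_id`, `state` (`"IC"`/`"OC"`)
#'   and `matrix` (`"plasma"`/`"rbc"`), one row per sample.
#' @param values Numeric matrix, samples x metabolites, column names =
#'   metabolite ids.
#' @param flags Character matrix parallel to `values` with entries `OK`,
#'   `BELOW_LLOQ`, `ABOVE_ULOQ`; defaults to all-`OK`.
#' @return A `paired_dataset` object.
#' @export
paired_dataset <- function(samples, values, flags = NULL) {
  samples <- as_tibble(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(flags)) {
    flags <- matrix("OK", nrow(values), ncol(values), dimnames = dimnames(values))
  }
  ds <- structure(
    list(samples = samples, values = values, flags = flags,
         metabolites = colnames(values)),
    class = "paired_dataset"
  )
  validate_paired_dataset(ds)
  ds
}

validate_paired_dataset <- function(ds) {
  samples <- ds$samples
  required <- c("patient_id", "state", "matrix")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample metadata missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(samples$state %in% c("IC", "OC"))) {
    abort("state must be 'IC' or 'OC' for every sample")
  }
  if (nrow(samples) != nrow(ds$values)) {
    abort("sample metadata and concentration grid disagree on sample count")
  }
  if (!identical(dim(ds$values), dim(ds$flags))) {
    abort("concentration and censoring grids have different dimensions")
  }
  if (anyNA(ds$values)) abort("missing concentration cells are not allowed")
  if (any(ds$values < 0)) abort("concentrations must be non-negative")
  if (!all(ds$flags %in% c("OK", "BELOW_LLOQ", "ABOVE_ULOQ"))) {
    abort("censoring flags must be OK, BELOW_LLOQ or ABOVE_ULOQ")
  }
  key <- paste(samples$patient_id, samples$state, samples$matrix, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), , drop = FALSE]
    abort(paste0("duplicate sample key(s): ",
                 paste(unique(paste(dup$patient_id, dup$state, dup$matrix)),
                       collapse = "; ")))
  }
  # paired design: within each matrix, every patient has exactly IC and OC
  by_pm <- split(samples$state, paste(samples$matrix, samples$patient_id, sep = "\r"))
  unpaired <- names(by_pm)[!vapply(by_pm, function(s) {
    length(s) == 2 && setequal(s, c("IC", "OC"))
  }, logical(1))]
  if (length(unpaired) > 0) {
    ids <- vapply(strsplit(unpaired, "\r", fixed = TRUE), `[`, character(1), 2)
    abort(paste0("unpaired patient(s), need exactly one IC and one OC sample: ",
                 paste(unique(ids), collapse = ", ")))
  }
  invisible(ds)
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d samples (%d pairs) x %d metabolites = %d cells\n",
              nrow(x$values), nrow(x$values) / 2L, ncol(x$values),
              n_cells(x)))
  oor <- sum(x$flags != "OK")
  cat(sprintf("  matrices: %s; out-of-range cells: %d (%.1f%%)\n",
              paste(unique(x$samples$matrix), collapse = ", "),
              oor, 100 * oor / max(1, length(x$flags))))
  invisible(x)
}

#' @rdname paired_dataset
#' @param x,ds A `paired_dataset`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.paired_dataset <- function(x, ...) {
  dplyr::bind_cols(x$samples, as_tibble(x$values, .name_repair = "minimal"))
}

#' @rdname paired_dataset
#' @export
n_cells <- function(ds) {
  stopifnot(inherits(ds, "paired_dataset"))
  length(ds$values)
}

#' Read a wide concentration table
#'
#' Reads a wide-format CSV whose first three columns are `patient_id`,
#' `state`, `matrix`, followed by one column per metabolite. Metabolite
#' columns absent from `panel` are dropped with a warning; the retained
#' columns are re-ordered to panel order, and censoring flags are derived by
#' comparing each value against the panel's LLOQ/ULOQ.
#'
#' @param path CSV file path.
#' @param panel Panel tibble (see [read_panel()]).
#' @return A `paired_dataset`.
#' @export
read_concentrations <- function(path, panel) {
  validate_panel(panel)
  if (!file.exists(path)) abort(paste0("concentration file not found: ", path))
  # base parser: correctly rounded doubles, so written tables round-trip exactly
  tab <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
  meta_cols <- c("patient_id", "state", "matrix")
  missing <- setdiff(meta_cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("concentration table missing metadata column(s): ",
                 paste(missing, collapse = ", ")))
  }
  metab_cols <- setdiff(names(tab), meta_cols)
  unknown <- setdiff(metab_cols, panel$metabolite_id)
  if (length(unknown) > 0) {
    warn(paste0("dropping ", length(unknown),
                " metabolite column(s) absent from panel: ",
                paste(head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else ""))
    metab_cols <- setdiff(metab_cols, unknown)
  }
  keep <- panel$metabolite_id[panel$metabolite_id %in% metab_cols]
  samples <- dplyr::mutate(tab[meta_cols],
                           dplyr::across(dplyr::everything(), as.character))
  values <- as.matrix(tab[keep])
  if (!is.numeric(values)) abort("non-numeric concentration cell(s) found")
  ds <- paired_dataset(samples, values)
  apply_loq_censoring(ds, panel)
}

#' Write a paired dataset to CSV
#'
#' Writes the wide concentration table (`patient_id,state,matrix,<metabolites>`).
#' Values are serialized with 17 significant digits, so
#' `read_concentrations(write_concentrations(ds, f), panel)` reproduces the
#' values bit-for-bit and (for panel-consistent flags) the censoring grid.
#'
#' @param ds A `paired_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(ds, path) {
  stopifnot(inherits(ds, "paired_dataset"))
  tab <- as_tibble(ds)
  # 17 significant digits guarantee exact double round-trips
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Derive quantitation-range censoring flags
#'
#' Sets each cell's flag to `BELOW_LLOQ` when the value is strictly below the
#' metabolite's LLOQ, `ABOVE_ULOQ` when strictly above its ULOQ, `OK`
#' otherwise. Values themselves are left unchanged.
#'
#' @inheritParams write_concentrations
#' @param panel Panel tibble covering every metabolite in `ds`.
#' @return The dataset with updated flags.
#' @export
apply_loq_censoring <- function(ds, panel) {
  stopifnot(inherits(ds, "paired_dataset"))
  validate_panel(panel)
  missing <- setdiff(ds$metabolites, panel$metabolite_id)
  if (length(missing) > 0) {
    abort(paste0("metabolite(s) absent from panel: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  idx <- match(ds$metabolites, panel$metabolite_id)
  lloq <- panel$lloq[idx]
  uloq <- panel$uloq[idx]
  flags <- matrix("OK", nrow(ds$values), ncol(ds$values),
                  dimnames = dimnames(ds$values))
  below <- sweep(ds$values, 2, lloq, `<`)
  above <- sweep(ds$values, 2, uloq, `>`)
  flags[below] <- "BELOW_LLOQ"
  flags[above] <- "ABOVE_ULOQ"
  ds$flags <- flags
  ds
}

# Internal: split a dataset into helpers used across modules.
dataset_pairs <- function(ds) sort(unique(ds$samples$patient_id))
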