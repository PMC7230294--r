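#' Out-of-range summary per metabolite
#'
#' Tallies, per metabolite, how many values fall below the LLOQ, above the
#' ULOQ, or inside the quantitation range, from the dataset's censoring flags
#' alone (concentration magnitudes are never consulted).
#'
#' @param ds A [paired_dataset()] with populated censoring flags.
#' @return Tibble with columns `metabolite_id`, `n_below_lloq`,
#'   `n_above_uloq`, `n_ok`, `oor_fraction`.
#' @export
out_of_range_summary <- function(ds) {
  stopifnot(inherits(ds, "paired_dataset"))
  n <- nrow(ds$values)
  below <- colSums(ds$flags == "BELOW_LLOQ")
  above <- colSums(ds$flags == "ABOVE_ULOQ")
  tibble(
    metabolite_id = ds$metabolites,
    n_below_lloq = as.integer(below),
    n_above_uloq = as.integer(above),
    n_ok = as.integer(n - below - above),
    oor_fraction = unname(below + above) / n
  )
}

#' Chi-squared test of out-of-range counts against crisis status
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table of
#' in/out-of-quantitation-range counts by crisis state. Used to rescue
#' metabolites whose out-of-range pattern is itself crisis-related. With a
#' zero margin (e.g. no out-of-range values at all) the test is degenerate
#' and returns statistic 0, p 1, with a log note. A log note is also emitted
#' when any expected cell count falls below 5.
#'
#' @param n_oor_ic,n_ok_ic Out-of-range / in-range counts among IC samples.
#' @param n_oor_oc,n_ok_oc Same among OC samples.
#' @return Tibble with `statistic`, `p_value`, `degenerate`.
#' @export
chi_squared_rescue <- function(n_oor_ic, n_ok_ic, n_oor_oc, n_ok_oc) {
  o <- c(n_oor_ic, n_ok_ic, n_oor_oc, n_ok_oc)
  if (any(o < 0)) abort("counts must be non-negative")
  tab <- matrix(o, nrow = 2, byrow = TRUE)  # rows: IC, OC; cols: OOR, OK
  total <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (total == 0 || any(rs == 0) || any(cs == 0)) {
    voc_log(event = "chisq_degenerate", note = "zero margin; statistic 0, p 1")
    return(tibble(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  e <- outer(rs, cs) / total
  if (any(e < 5)) {
    voc_log(event = "chisq_small_expected", min_expected = signif(min(e), 3))
  }
  stat <- sum((tab - e)^2 / e)
  tibble(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         degenerate = FALSE)
}

#' Quantitation-range filter with chi-squared rescue
#'
#' Excludes metabolites with more than `threshold` (default 20%) of their
#' values outside the quantitation range, unless the out-of-range pattern is
#' related to crisis status: for each such metabolite a chi-squared test of
#' in/out-of-range counts against IC/OC state is run, and a significant
#' relation (p < `alpha`) rescues the metabolite as potentially discriminant.
#' A metabolite with out-of-range fraction exactly at the threshold is kept
#' (the exclusion rule is strictly greater-than).
#'
#' Out-of-range values of retained metabolites are imputed deterministically:
#' below-LLOQ values as LLOQ/2, above-ULOQ values as ULOQ (logged). Censoring
#' flags are preserved as a record of what was imputed.
#'
#' @param ds A [paired_dataset()] with populated flags.
#' @param panel Panel tibble supplying LLOQ/ULOQ for imputation.
#' @param threshold Maximum tolerated out-of-range fraction, in (0, 1).
#' @param alpha Rescue significance level.
#' @return List with `dataset` (filtered, imputed `paired_dataset`) and
#'   `report` (tibble: per-metabolite counts, rescue test, decision
#'   `KEPT`/`KEPT_BY_RESCUE`/`DROPPED`, and number of imputed cells).
#' @export
apply_quantitation_filter <- function(ds, panel, threshold = 0.20, alpha = 0.05) {
  stopifnot(inherits(ds, "paired_dataset"))
  validate_panel(panel)
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")

  summ <- out_of_range_summary(ds)
  ic <- ds$samples$state == "IC"
  oor <- ds$flags != "OK"

  decide <- function(j) {
    if (summ$oor_fraction[j] <= threshold) {
      return(list(decision = "KEPT", statistic = NA_real_, p = NA_real_))
    }
    res <- chi_squared_rescue(sum(oor[ic, j]), sum(!oor[ic, j]),
                              sum(oor[!ic, j]), sum(!oor[!ic, j]))
    list(decision = if (res$p_value < alpha) "KEPT_BY_RESCUE" else "DROPPED",
         statistic = res$statistic, p = res$p_value)
  }
  dec <- purrr::map(seq_along(ds$metabolites), decide)

  report <- dplyr::mutate(
    summ,
    rescue_statistic = purrr::map_dbl(dec, "statistic"),
    rescue_p = purrr::map_dbl(dec, "p"),
    decision = purrr::map_chr(dec, "decision")
  )

  keep <- report$decision != "DROPPED"
  values <- ds$values[, keep, drop = FALSE]
  flags <- ds$flags[, keep, drop = FALSE]
  idx <- match(colnames(values), panel$metabolite_id)
  n_imputed <- 0L
  for (j in seq_len(ncol(values))) {
    lo <- flags[, j] == "BELOW_LLOQ"
    hi <- flags[, j] == "ABOVE_ULOQ"
    values[lo, j] <- panel$lloq[idx[j]] / 2
    values[hi, j] <- panel$uloq[idx[j]]
    n_imputed <- n_imputed + sum(lo) + sum(hi)
  }
  report$n_imputed <- ifelse(keep, as.integer(colSums(ds$flags != "OK")), 0L)
  if (n_imputed > 0) {
    voc_log(event = "oor_imputation", n_cells = n_imputed,
            rule = "BELOW_LLOQ -> lloq/2, ABOVE_ULOQ -> uloq")
  }
  voc_log(event = "quantitation_filter",
          kept = sum(report$decision == "KEPT"),
          rescued = sum(report$decision == "KEPT_BY_RESCUE"),
          dropped = sum(report$decision == "DROPPED"))

  filtered <- ds
  filtered$values <- values
  filtered$flags <- flags
  filtered$metabolites <- colnames(values) %||% character(0)
  list(dataset = filtered, report = report)
}
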