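# Class color scheme for volcano plots: amino acids green, biogenic amines
# light green, (acyl-)carnitines brown, lysoPC light or dark blue by acyl
# chain length (< 22 vs >= 22 carbons), phosphatidylcholines orange,
# sphingomyelins yellow, hexose gray.
volcano_palette <- c(
  amino_acid = "#1B7837", biogenic_amine = "#A6DBA0",
  acylcarnitine = "#8C510A", free_carnitine = "#8C510A",
  lysoPC_short = "#9ECAE1", lysoPC_long = "#08519C",
  PC = "#F16913", sphingomyelin = "#FFD92F", hexose = "grey50"
)

color_group <- function(class, acyl_carbons) {
  dplyr::case_when(
    class == "lysoPC" & !is.na(acyl_carbons) & acyl_carbons < 22 ~ "lysoPC_short",
    class == "lysoPC" ~ "lysoPC_long",
    class %in% c("PC_aa", "PC_ae") ~ "PC",
    TRUE ~ class
  )
}

#' Volcano plot of median loading vs median VIP
#'
#' Each bubble is a metabolite at (median oriented loading, median VIP), with
#' a horizontal guide at the VIP selection threshold. Only selected
#' metabolites (median VIP at or above the threshold) are labeled. Positive
#' loadings indicate concentrations increased in-crisis. Bubble colors follow
#' the panel-class scheme (see `volcano_palette`).
#'
#' @param aggregates Tibble `metabolite_id`, `median_vip`, `median_loading`
#'   (e.g. the `aggregates` element of a `plsda_ensemble`), or the ensemble
#'   itself.
#' @param panel Panel tibble for class annotation (default bundled panel).
#' @param vip_threshold Selection guide (default 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(aggregates, panel = default_panel(), vip_threshold = 1) {
  if (inherits(aggregates, "plsda_ensemble")) {
    vip_threshold <- aggregates$config$vip_threshold %||% vip_threshold
    aggregates <- aggregates$aggregates
  }
  if (nrow(aggregates) == 0) abort("no aggregates to plot")
  dat <- dplyr::left_join(
    aggregates,
    panel[, c("metabolite_id", "class", "acyl_carbons")],
    by = "metabolite_id"
  )
  dat$group <- color_group(dat$class, dat$acyl_carbons)
  dat$selected <- dat$median_vip >= vip_threshold
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$median_loading, y = .data$median_vip)) +
    ggplot2::geom_hline(yintercept = vip_threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$group), shape = 21,
                        size = 3, alpha = 0.85, color = "grey25") +
    ggplot2::geom_text(
      data = dat[dat$selected, , drop = FALSE],
      ggplot2::aes(label = .data$metabolite_id),
      size = 2.4, vjust = -1, check_overlap = TRUE
    ) +
    ggplot2::scale_fill_manual(values = volcano_palette, name = "class") +
    ggplot2::labs(x = "median loading (positive = increased in-crisis)",
                  y = "median VIP") +
    ggplot2::theme_minimal()
}

#' Latent-variable or principal-component score plot
#'
#' Scatter of per-sample coordinates, in-crisis samples red and out-of-crisis
#' samples blue. For latent-variable coordinates oriented so that positive
#' LV1 is the in-crisis side, samples on the wrong side of LV1 = 0 are
#' counted as misallocated and reported in the caption.
#'
#' @param coordinates Tibble with a `state` column and two coordinate columns
#'   (e.g. the `coordinates` element of a `plsda_ensemble`, or PCA scores
#'   bound to sample metadata).
#' @param dims Names of the two coordinate columns (default first two
#'   matching `LV*`/`PC*`).
#' @param annotate_misallocation Count and report samples whose first
#'   coordinate sign disagrees with their class (LV coordinates only).
#' @return A ggplot object.
#' @export
plot_scores <- function(coordinates, dims = NULL, annotate_misallocation = TRUE) {
  cand <- grep("^(LV|PC)[0-9]+$", names(coordinates), value = TRUE)
  dims <- dims %||% head(cand, 2)
  if (length(dims) != 2) abort("need two coordinate columns to plot")
  cap <- NULL
  if (annotate_misallocation && grepl("^LV", dims[1]) &&
      "state" %in% names(coordinates)) {
    wrong <- sum((coordinates[[dims[1]]] > 0) != (coordinates$state == "IC"))
    cap <- sprintf("%d sample(s) misallocated by the %s = 0 boundary", wrong, dims[1])
  }
  ggplot2::ggplot(coordinates,
                  ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                               color = .data$state)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey85") +
    ggplot2::geom_vline(xintercept = 0, color = "grey85") +
    ggplot2::geom_point(size = 2.5, alpha = 0.9) +
    ggplot2::scale_color_manual(values = c(IC = "#D7301F", OC = "#0571B0"),
                                name = NULL,
                                labels = c(IC = "in-crisis", OC = "out-of-crisis")) +
    ggplot2::labs(x = dims[1], y = dims[2], caption = cap) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.plsda_ensemble <- function(object, type = c("volcano", "scores"), ...) {
  type <- match.arg(type)
  if (type == "volcano") plot_volcano(object, ...) else plot_scores(object$coordinates, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.paired_plsda <- function(object, ...) {
  coords <- dplyr::bind_cols(object$training_samples, as_tibble(object$scores))
  plot_scores(coords, ...)
}

# Write a figure as both PNG and SVG with fixed size (deterministic artifacts).
save_plot_bundle <- function(p, stem, width = 7, height = 5) {
  paths <- c(png = paste0(stem, ".png"), svg = paste0(stem, ".svg"))
  ggplot2::ggsave(paths["png"], p, width = width, height = height, dpi = 150)
  ggplot2::ggsave(paths["svg"], p, width = width, height = height,
                  device = grDevices::svg)
  invisible(paths)
}
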