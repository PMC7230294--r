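#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, the quantitation filter, the
#' cross-validation ensemble and reporting, writing all artifacts plus a
#' manifest recording the configuration, seeds and output paths. Re-running
#' with the same configuration reproduces the same outputs.
#'
#' @param config A list, or path to a JSON file, with elements:
#'   * `scenario`: list(`name` in `"study"`/`"strong_effect"`/`"null"`,
#'     `seed`, `matrix`) to simulate input data, **or**
#'   * `input`: list(`dataset`, `panel`) CSV paths to load measured data;
#'   * `filter`: optional list(`threshold`, `alpha`);
#'   * `ensemble`: optional list of [ensemble_config()] arguments;
#'   * `plots`: logical, write figures (default TRUE).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`dataset`, `truth`,
#'   `filter`, `ensemble`, `selection`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  truth <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    cfg <- stage("simulate", switch(
      sc$name %||% "study",
      study = scenario_study(seed = sc$seed %||% 1L, matrix = sc$matrix %||% "rbc"),
      strong_effect = scenario_strong_effect(seed = sc$seed %||% 1L,
                                             matrix = sc$matrix %||% "rbc"),
      null = scenario_null(seed = sc$seed %||% 1L, matrix = sc$matrix %||% "rbc"),
      abort(paste0("unknown scenario: ", sc$name))
    ))
    sim <- stage("simulate", simulate_dataset(cfg))
    ds <- sim$dataset
    truth <- sim$truth
    panel <- cfg$panel
    paths$dataset <- file.path(out_dir, "dataset.csv")
    write_concentrations(ds, paths$dataset)
    paths$ground_truth <- file.path(out_dir, "ground_truth.csv")
    readr::write_csv(truth, paths$ground_truth, progress = FALSE)
  } else if (!is.null(config$input)) {
    panel <- stage("load", if (is.null(config$input$panel)) default_panel()
                   else read_panel(config$input$panel))
    ds <- stage("load", read_concentrations(config$input$dataset, panel))
  } else {
    abort("config must provide either 'scenario' or 'input'")
  }

  fl <- stage("filter", apply_quantitation_filter(
    ds, panel,
    threshold = config$filter$threshold %||% 0.20,
    alpha = config$filter$alpha %||% 0.05
  ))
  paths$filter_report <- file.path(out_dir, "filter_report.tsv")
  readr::write_tsv(fl$report, paths$filter_report, progress = FALSE)

  ens_args <- config$ensemble %||% list()
  ens_cfg <- stage("ensemble", do.call(ensemble_config, ens_args))
  ens <- stage("ensemble", run_ensemble(fl$dataset, ens_cfg))
  paths$models <- file.path(out_dir, "models.tsv")
  readr::write_tsv(ens$models, paths$models, progress = FALSE)
  paths$aggregates <- file.path(out_dir, "aggregates.tsv")
  readr::write_tsv(ens$aggregates, paths$aggregates, progress = FALSE)
  paths$coordinates <- file.path(out_dir, "coordinates.tsv")
  readr::write_tsv(ens$coordinates, paths$coordinates, progress = FALSE)

  selection <- stage("report", select_discriminant(ens, panel = panel))
  paths$selection <- file.path(out_dir, "selection.tsv")
  readr::write_tsv(selection, paths$selection, progress = FALSE)

  paths$summary <- file.path(out_dir, "summary.json")
  summary <- c(ens$summary, list(
    n_selected = nrow(selection),
    selected_by_class = as.list(setNames(signature_class_counts(selection)$n,
                                         signature_class_counts(selection)$class))
  ))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  if (isTRUE(config$plots %||% TRUE) && ens$summary$n_bm > 0) {
    paths <- c(paths, as.list(stage("report", {
      v <- save_plot_bundle(plot_volcano(ens, panel = panel),
                            file.path(out_dir, "volcano"))
      s <- save_plot_bundle(plot_scores(ens$coordinates),
                            file.path(out_dir, "scores"))
      setNames(c(v, s), c("volcano_png", "volcano_svg", "scores_png", "scores_svg"))
    })))
  }

  manifest <- list(
    package = "vocpls",
    version = as.character(utils::packageVersion("vocpls")),
    config = config,
    outputs = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dataset = ds, truth = truth, filter = fl, ensemble = ens,
                 selection = selection, manifest = manifest))
}
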