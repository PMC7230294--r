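#' Outer training-validation / test split of patient pairs
#'
#' Randomly assigns patient pairs to the training-validation set (up to 30
#' pairs, three quarters of all pairs) and the held-out test set, keeping each
#' patient's two samples together. With 40 pairs the split is 30/10; with 39
#' pairs, 30/9. Deterministic for a fixed seed; both sides are returned in
#' sorted order so downstream unranking is canonical.
#'
#' @param pair_ids Patient identifiers (one per pair).
#' @param seed Integer seed for the shuffle.
#' @return A `paired_split` list with `trainval` and `test`.
#' @export
make_outer_split <- function(pair_ids, seed = 1L) {
  pair_ids <- unique(as.character(pair_ids))
  n <- length(pair_ids)
  if (n < 8) abort("need at least 8 pairs to form an outer split")
  n_tv <- min(30L, as.integer(ceiling(0.75 * n)))
  shuffled <- with_seed(seed, sample(pair_ids))
  structure(
    list(trainval = sort(shuffled[seq_len(n_tv)]),
         test = sort(shuffled[-seq_len(n_tv)]),
         seed = as.integer(seed)),
    class = "paired_split"
  )
}

#' Ensemble configuration
#'
#' Parameters of the systematic cross-validation ensemble.
#'
#' @param inner_train_size Pairs per inner training set (default 20; the
#'   remaining training-validation pairs form the validation set).
#' @param stride Rank stride for systematic sampling of the lexicographic
#'   combination sequence; `NULL` (default) derives it as
#'   `max(1, floor(C(n_trainval, k) / target_models))` — for 20-of-30 this is
#'   exactly 1287, yielding 23,345 models.
#' @param target_models Intended model count used to derive `stride`.
#' @param bm_threshold Validation AUROC at or above which a model is a "best
#'   model" (default 0.95).
#' @param vip_threshold Median VIP at or above which a metabolite is selected
#'   (default 1).
#' @param seed Seed for the outer split.
#' @param multilevel Use the within-patient decomposition inside each model.
#' @param n_components Latent variables per model.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(inner_train_size = 20, stride = NULL,
                            target_models = 23345, bm_threshold = 0.95,
                            vip_threshold = 1, seed = 1L, multilevel = TRUE,
                            n_components = 2) {
  if (!is.null(stride) && stride < 1) abort("stride must be >= 1")
  if (target_models < 1) abort("target_models must be >= 1")
  if (bm_threshold < 0 || bm_threshold > 1) abort("bm_threshold must lie in [0, 1]")
  structure(
    list(inner_train_size = as.integer(inner_train_size), stride = stride,
         target_models = target_models, bm_threshold = bm_threshold,
         vip_threshold = vip_threshold, seed = as.integer(seed),
         multilevel = isTRUE(multilevel), n_components = n_components),
    class = "ensemble_config"
  )
}

# Internal: rows of each state per pair, in a fixed pair order.
pair_rows <- function(samples, pair_order) {
  ic <- match(paste(pair_order, "IC"), paste(samples$patient_id, samples$state))
  oc <- match(paste(pair_order, "OC"), paste(samples$patient_id, samples$state))
  list(ic = ic, oc = oc)
}

# Internal: build the model-input matrix and labels for a set of pairs,
# optionally multilevel-decomposed with supplied grand means.
assemble_pairs <- function(values, rows, idx, multilevel, grand_mean = NULL) {
  xic <- values[rows$ic[idx], , drop = FALSE]
  xoc <- values[rows$oc[idx], , drop = FALSE]
  if (multilevel) {
    gm <- grand_mean %||% ((colSums(xic) + colSums(xoc)) / (2 * length(idx)))
    d <- (xic - xoc) / 2
    x <- rbind(sweep(d, 2, gm, `+`), sweep(-d, 2, gm, `+`))
  } else {
    gm <- NULL
    x <- rbind(xic, xoc)
  }
  list(x = x, y = rep(c(1, 0), each = length(idx)), grand_mean = gm)
}

#' Run the systematic paired PLS-DA ensemble
#'
#' The core procedure: the training-validation pairs are split into every
#' lexicographic combination of `inner_train_size` training pairs, sampled
#' systematically every `stride` ranks. Each sampled model is a paired PLS-DA
#' fitted on its training pairs only (within-patient decomposition and
#' unit-variance scaling both estimated on the training pairs), then scored
#' on its validation pairs by AUROC and the exact Mann-Whitney p-value. Best
#' models (validation AUROC >= `bm_threshold`) are re-scored on the outer
#' test pairs, and their per-metabolite VIPs and oriented loadings and
#' per-sample latent coordinates are aggregated as medians after sign
#' alignment (component 1 oriented so positive = in-crisis; component 2
#' aligned to the lowest-rank best model by loading correlation).
#'
#' The overall ensemble passes when the median test AUROC is at least 0.8
#' and the median test p-value at most 0.05.
#'
#' @param ds A filtered [paired_dataset()].
#' @param config An [ensemble_config()].
#' @return A `plsda_ensemble`: list with `models` (per-model tibble),
#'   `aggregates` (per-metabolite medians), `coordinates` (per-sample median
#'   latent coordinates), `summary` (counts, medians, pass flag), `split`,
#'   `config`.
#' @export
run_ensemble <- function(ds, config = ensemble_config()) {
  stopifnot(inherits(ds, "paired_dataset"), inherits(config, "ensemble_config"))
  pairs <- dataset_pairs(ds)
  split <- make_outer_split(pairs, config$seed)
  tv <- split$trainval
  k <- config$inner_train_size
  if (k >= length(tv)) abort("inner_train_size must be below the number of trainval pairs")

  total <- count_combinations(length(tv), k)
  stride <- config$stride %||% max(1, floor(total / config$target_models))
  ranks <- stride_indices(total, stride)
  n_models <- length(ranks)
  voc_log(event = "ensemble_start", trainval_pairs = length(tv),
          test_pairs = length(split$test), combinations = total,
          stride = stride, models = n_models)

  rows <- pair_rows(ds$samples, c(tv, split$test))
  names(rows$ic) <- names(rows$oc) <- c(tv, split$test)
  values <- ds$values
  tv_idx <- seq_along(tv)
  test_idx <- length(tv) + seq_along(split$test)

  val_auroc <- val_p <- numeric(n_models)
  bm_models <- list()
  bm_rank <- numeric(0)

  for (m in seq_len(n_models)) {
    train_local <- unrank_combination(ranks[m], length(tv), k)
    val_local <- setdiff(tv_idx, train_local)
    tr <- assemble_pairs(values, rows, train_local, config$multilevel)
    model <- fit_plsda(tr$x, tr$y, n_components = config$n_components, scale = TRUE)
    va <- assemble_pairs(values, rows, val_local, config$multilevel, tr$grand_mean)
    scores <- predict(model, va$x)
    ev <- auroc_pvalue(scores, va$y == 1, positive = TRUE)
    val_auroc[m] <- ev$auroc
    val_p[m] <- ev$p_value
    if (ev$auroc >= config$bm_threshold) {
      model$grand_mean <- tr$grand_mean
      bm_models[[length(bm_models) + 1]] <- model
      bm_rank <- c(bm_rank, ranks[m])
    }
    if (m %% 1000 == 0) voc_log(event = "ensemble_progress", models_done = m)
  }

  is_bm <- val_auroc >= config$bm_threshold
  n_bm <- length(bm_models)
  test_auroc <- test_p <- rep(NA_real_, n_models)
  coords_list <- vector("list", n_bm)
  if (n_bm > 0) {
    bm_pos <- which(is_bm)
    for (b in seq_len(n_bm)) {
      model <- bm_models[[b]]
      te <- assemble_pairs(values, rows, test_idx, config$multilevel,
                           model$grand_mean)
      ev <- auroc_pvalue(predict(model, te$x), te$y == 1, positive = TRUE)
      test_auroc[bm_pos[b]] <- ev$auroc
      test_p[bm_pos[b]] <- ev$p_value
      tvp <- assemble_pairs(values, rows, tv_idx, config$multilevel,
                            model$grand_mean)
      coords_list[[b]] <- compute_scores(model, prepare_newdata(model, tvp$x))
    }
    agg <- aggregate_bm_medians(bm_models, coords_list)
    coordinates <- dplyr::bind_cols(
      tibble(patient_id = rep(tv, 2), state = rep(c("IC", "OC"), each = length(tv))),
      agg$coordinates
    )
    aggregates <- agg$aggregates
  } else {
    warn("no best model reached the validation AUROC threshold; aggregates are empty")
    aggregates <- tibble(metabolite_id = character(), median_vip = numeric(),
                         median_loading = numeric())
    coordinates <- tibble(patient_id = character(), state = character(),
                          LV1 = numeric(), LV2 = numeric())
  }

  summary <- list(
    n_models = n_models, n_bm = n_bm, bm_fraction = n_bm / n_models,
    n_val_auroc_ge_0.8 = sum(val_auroc >= 0.8),
    median_val_auroc = median(val_auroc), median_val_p = median(val_p),
    median_test_auroc = if (n_bm > 0) median(test_auroc, na.rm = TRUE) else NA_real_,
    median_test_p = if (n_bm > 0) median(test_p, na.rm = TRUE) else NA_real_,
    stride = stride, total_combinations = total
  )
  summary$pass <- isTRUE(summary$median_test_auroc >= 0.8 &&
                           summary$median_test_p <= 0.05)

  structure(
    list(
      models = tibble(rank = ranks, val_auroc = val_auroc, val_p = val_p,
                      is_bm = is_bm, test_auroc = test_auroc, test_p = test_p),
      aggregates = aggregates, coordinates = coordinates,
      summary = summary, split = split, config = config
    ),
    class = "plsda_ensemble"
  )
}

#' Median aggregation of best models
#'
#' Aligns component signs across best models, then takes per-metabolite
#' marginal medians of VIP and oriented first-component loading and
#' per-sample medians of the latent coordinates. Component 1 of each model is
#' oriented so its y-loading is positive (positive loading = elevated
#' in-crisis); remaining components are aligned to the first (reference)
#' model by the sign of the loading-vector correlation.
#'
#' @param models List of `plsda_model`s (the best models, lowest rank first).
#' @param coordinates List of score matrices (samples x components), parallel
#'   to `models`, all over the same samples.
#' @return List with `aggregates` (tibble `metabolite_id`, `median_vip`,
#'   `median_loading`) and `coordinates` (tibble of median `LV` columns).
#' @export
aggregate_bm_medians <- function(models, coordinates) {
  if (length(models) == 0) abort("need at least one best model to aggregate")
  n_comp <- ncol(models[[1]]$P)
  ref <- NULL
  aligned <- purrr::map2(models, coordinates, function(model, coords) {
    flips <- numeric(n_comp)
    flips[1] <- if (model$q[1] >= 0) 1 else -1
    if (n_comp > 1) {
      for (a in 2:n_comp) {
        flips[a] <- if (is.null(ref)) 1 else {
          cc <- sum(model$P[, a] * ref[, a])
          if (cc >= 0) 1 else -1
        }
      }
    }
    P <- sweep(model$P, 2, flips, `*`)
    if (is.null(ref)) ref <<- P
    list(vip = model$vip, loading = P[, 1],
         coords = sweep(coords, 2, flips, `*`))
  })
  vips <- do.call(rbind, purrr::map(aligned, "vip"))
  loadings <- do.call(rbind, purrr::map(aligned, "loading"))
  coord_arr <- simplify2array(purrr::map(aligned, "coords"))
  if (length(dim(coord_arr)) == 2) dim(coord_arr) <- c(dim(coord_arr), 1)
  med_coords <- apply(coord_arr, c(1, 2), median)
  colnames(med_coords) <- paste0("LV", seq_len(ncol(med_coords)))
  list(
    aggregates = tibble(
      metabolite_id = colnames(vips) %||% models[[1]]$metabolites,
      median_vip = unname(apply(vips, 2, median)),
      median_loading = unname(apply(loadings, 2, median))
    ),
    coordinates = as_tibble(med_coords)
  )
}

#' Select discriminant metabolites
#'
#' Metabolites whose median VIP across best models reaches the threshold,
#' with direction read from the oriented loading (positive = increased
#' in-crisis), sorted by VIP, optionally annotated with panel classes.
#'
#' @param x A `plsda_ensemble` or an aggregates tibble
#'   (`metabolite_id`, `median_vip`, `median_loading`).
#' @param vip_threshold Selection threshold on median VIP (default from the
#'   ensemble config, else 1).
#' @param panel Optional panel tibble for class annotation.
#' @return Tibble `metabolite_id`, (`class`), `median_vip`, `median_loading`,
#'   `direction`, sorted by decreasing VIP.
#' @export
select_discriminant <- function(x, vip_threshold = NULL, panel = NULL) {
  if (inherits(x, "plsda_ensemble")) {
    vip_threshold <- vip_threshold %||% x$config$vip_threshold
    x <- x$aggregates
  }
  vip_threshold <- vip_threshold %||% 1
  out <- dplyr::filter(x, .data$median_vip >= vip_threshold)
  out <- dplyr::mutate(
    out, direction = ifelse(.data$median_loading > 0, "increased", "decreased"))
  if (!is.null(panel)) {
    out <- dplyr::left_join(
      out, panel[, c("metabolite_id", "class")], by = "metabolite_id")
    out <- out[, c("metabolite_id", "class", "median_vip", "median_loading",
                   "direction")]
  }
  dplyr::arrange(out, dplyr::desc(.data$median_vip))
}

#' Per-class counts of a discriminant selection
#'
#' @param selection Output of [select_discriminant()] with a `class` column,
#'   or any tibble with `class` and optionally `n_selected`.
#' @return Tibble `class`, `n`, plus a `total` attribute; summing the
#'   per-class counts reproduces the total number of selected metabolites.
#' @export
signature_class_counts <- function(selection) {
  counts <- if ("n_selected" %in% names(selection)) {
    dplyr::summarise(dplyr::group_by(selection, .data$class),
                     n = sum(.data$n_selected), .groups = "drop")
  } else {
    dplyr::count(selection, .data$class, name = "n")
  }
  attr(counts, "total") <- sum(counts$n)
  counts
}
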