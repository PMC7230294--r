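test_that("binomial counts are exact and validated", {
  expect_equal(count_combinations(30, 20), 30045015)
  expect_equal(count_combinations(7, 0), 1)
  expect_equal(count_combinations(6, 3), ncol(combn(6, 3)))
  expect_error(count_combinations(3, 5), "0 <= k <= n")
  expect_error(count_combinations(-1, 0), "0 <= k <= n")
  expect_error(count_combinations(200, 100), "exceeds exact")
})

test_that("unranking reproduces the full lexicographic enumeration", {
  expect_equal(unrank_combination(0, 9, 4), 1:4)
  expect_equal(unrank_combination(count_combinations(9, 4) - 1, 9, 4), 6:9)
  for (n in 2:8) {
    for (k in 1:(n - 1)) {
      ref <- combn(n, k)
      got <- vapply(seq_len(ncol(ref)) - 1, unrank_combination, integer(k),
                    n = n, k = k)
      expect_equal(matrix(got, nrow = k), ref)  # bijection, in lex order
    }
  }
  expect_error(unrank_combination(20, 6, 3), "rank")
  expect_error(unrank_combination(-1, 6, 3), "rank")
})

test_that("stride sampling yields the documented rank counts", {
  ranks <- stride_indices(count_combinations(30, 20), 1287)
  expect_length(ranks, 23345)
  expect_equal(ranks[1], 0)
  expect_equal(ranks[2] - ranks[1], 1287)
  expect_equal(stride_indices(10, 1), 0:9)
  expect_equal(stride_indices(10, 50), 0)
  expect_equal(stride_indices(10, 50, offset = 3), 3)
  expect_warning(empty <- stride_indices(10, 2, offset = 10), "offset")
  expect_length(empty, 0)
})

test_that("outer splits mirror the study design and keep pairs intact", {
  p40 <- sprintf("P%02d", 1:40)
  s40 <- make_outer_split(p40, seed = 4)
  expect_length(s40$trainval, 30)
  expect_length(s40$test, 10)
  expect_length(intersect(s40$trainval, s40$test), 0)
  expect_setequal(c(s40$trainval, s40$test), p40)

  s39 <- make_outer_split(sprintf("P%02d", 1:39), seed = 4)
  expect_length(s39$trainval, 30)
  expect_length(s39$test, 9)

  expect_identical(make_outer_split(p40, seed = 4), s40)
  s40b <- make_outer_split(p40, seed = 5)
  expect_false(identical(s40b$trainval, s40$trainval))
  expect_length(s40b$trainval, 30)
  expect_error(make_outer_split(sprintf("P%d", 1:7), 1), "at least 8")
})

test_that("sampled models never split a pair across train/validation/test", {
  sim <- random_dataset(12, 6, seed = 9)
  cfg <- ensemble_config(inner_train_size = 5, stride = 7, seed = 2)
  ens <- suppressWarnings(run_ensemble(sim$dataset, cfg))
  tv <- ens$split$trainval
  expect_length(intersect(tv, ens$split$test), 0)
  for (r in ens$models$rank) {
    train <- tv[unrank_combination(r, length(tv), 5)]
    val <- setdiff(tv, train)
    expect_length(intersect(train, val), 0)
    expect_length(intersect(train, ens$split$test), 0)
    expect_setequal(c(train, val), tv)
  }
})

test_that("a single-model ensemble's medians equal that model's values", {
  sim <- simulate_dataset(scenario_strong_effect(seed = 6))
  fl <- apply_quantitation_filter(sim$dataset, default_panel())
  cfg <- ensemble_config(stride = count_combinations(30, 20) + 1, seed = 6)
  ens <- run_ensemble(fl$dataset, cfg)
  expect_equal(ens$summary$n_models, 1L)
  expect_equal(ens$summary$median_val_auroc, ens$models$val_auroc[1])
  if (ens$summary$n_bm == 1) {
    expect_equal(ens$summary$median_test_auroc, ens$models$test_auroc[1])
    expect_equal(sum(ens$aggregates$median_vip^2),
                 length(ens$aggregates$metabolite_id), tolerance = 1e-8)
  }
})

test_that("ensembles are deterministic for identical inputs", {
  sim <- random_dataset(12, 8, seed = 14)
  # plant a signal so best models exist
  ic <- sim$dataset$samples$state == "IC"
  sim$dataset$values[ic, 1:3] <- sim$dataset$values[ic, 1:3] * 3
  cfg <- ensemble_config(inner_train_size = 6, target_models = 60, seed = 3)
  a <- run_ensemble(sim$dataset, cfg)
  b <- run_ensemble(sim$dataset, cfg)
  expect_identical(a$models, b$models)
  expect_identical(a$aggregates, b$aggregates)
  expect_identical(a$coordinates, b$coordinates)
  expect_gt(a$summary$n_bm, 0)
})

test_that("median aggregation aligns signs and reduces to hand medians", {
  withr::with_seed(61, {
    x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("m", 1:5)))
    y <- rep(c(1, 0), 10)
    fit <- fit_plsda(x, y)
    coords <- as.matrix(project(fit, x))

    one <- aggregate_bm_medians(list(fit), list(coords))
    expect_equal(one$aggregates$median_vip, unname(fit$vip))
    s1 <- if (fit$q[1] >= 0) 1 else -1
    expect_equal(one$aggregates$median_loading, unname(s1 * fit$P[, 1]))

    # an exact sign-flip of every component aggregates to the same medians
    flipped <- fit
    flipped$W <- -fit$W
    flipped$P <- -fit$P
    flipped$q <- -fit$q
    flipped$scores <- -fit$scores
    two <- aggregate_bm_medians(list(fit, flipped), list(coords, -coords))
    expect_equal(two$aggregates, one$aggregates)
    expect_equal(two$coordinates, one$coordinates)
  })

  # hand-set VIPs: median of (0.5, 1.0, 1.5) is 1.0
  fake <- function(vip1) {
    m <- list(vip = c(m1 = vip1, m2 = 0.2), q = c(1, 1),
              P = matrix(c(0.6, 0.4, 0.1, 0.2), 2,
                         dimnames = list(c("m1", "m2"), NULL)))
    class(m) <- "plsda_model"
    m
  }
  cs <- matrix(0, 4, 2)
  agg <- aggregate_bm_medians(list(fake(0.5), fake(1.0), fake(1.5)),
                              list(cs, cs, cs))
  expect_equal(agg$aggregates$median_vip, c(1.0, 0.2))
})

test_that("discriminant selection applies the VIP threshold and directions", {
  agg <- tibble::tibble(
    metabolite_id = c("m1", "m2", "m3"),
    median_vip = c(1.2, 0.8, 1.0),
    median_loading = c(0.5, 0.4, -0.3)
  )
  sel <- select_discriminant(agg, vip_threshold = 1)
  expect_equal(sel$metabolite_id, c("m1", "m3"))
  expect_equal(sel$direction, c("increased", "decreased"))

  none <- select_discriminant(agg, vip_threshold = 2)
  expect_equal(nrow(none), 0)

  sel2 <- select_discriminant(agg, vip_threshold = 1, panel = tiny_panel(3))
  expect_equal(sel2$class, c("amino_acid", "amino_acid"))
  counts <- signature_class_counts(sel2)
  expect_equal(attr(counts, "total"), 2)
})

test_that("label permutation destroys held-out performance", {
  sim <- simulate_dataset(simulation_config(
    16, tiny_panel(12),
    effects = tibble::tibble(metabolite_id = paste0("m", 1:6),
                             log_fold_effect = rep(c(0.9, -0.9), 3)),
    seed = 71
  ))
  cfg <- ensemble_config(inner_train_size = 6, target_models = 80, seed = 5,
                         bm_threshold = 0.9)
  real <- run_ensemble(sim$dataset, cfg)
  expect_gte(real$summary$median_test_auroc, 0.8)

  shuffled <- sim$dataset
  flip <- withr::with_seed(2, sample(c(TRUE, FALSE), 16, replace = TRUE))
  swap <- rep(flip, each = 2)
  states <- shuffled$samples$state
  shuffled$samples$state[swap] <- ifelse(states[swap] == "IC", "OC", "IC")
  perm <- suppressWarnings(run_ensemble(shuffled, cfg))
  expect_lte(perm$summary$median_val_auroc, 0.8)
  expect_gte(perm$summary$median_val_auroc, 0.2)
  expect_lt(perm$summary$median_val_auroc,
            real$summary$median_val_auroc - 0.15)
})

test_that("doubling planted effects does not hurt held-out performance", {
  for (s in 1:2) {
    base_eff <- tibble::tibble(metabolite_id = paste0("m", 1:4),
                               log_fold_effect = c(0.25, -0.25, 0.25, -0.25))
    run <- function(mult) {
      eff <- dplyr::mutate(base_eff, log_fold_effect = log_fold_effect * mult)
      sim <- simulate_dataset(simulation_config(16, tiny_panel(10),
                                                effects = eff, seed = 80 + s))
      cfg <- ensemble_config(inner_train_size = 8, target_models = 60,
                             seed = s, bm_threshold = 0.9)
      suppressWarnings(run_ensemble(sim$dataset, cfg))$summary$median_val_auroc
    }
    expect_gte(run(2) + 0.05, run(1))
  }
})
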