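test_that("unit-variance scaling uses training parameters only", {
  x <- cbind(m1 = c(1, 2, 3), m2 = c(2, 4, 9))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(unname(xs[, 1]), c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  expect_equal(unname(colMeans(xs)), c(0, 0))
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1))

  held_out <- cbind(m1 = c(10, 11), m2 = c(1, 2))
  hs <- apply_scaler(sc, held_out)
  expect_gt(abs(mean(hs[, 1])), 1)  # no re-centering on new data

  bad <- cbind(m1 = c(1, 2, 3), m2 = c(7, 7, 7))
  expect_error(fit_scaler(bad), "constant column.*m2")
})

test_that("multilevel decomposition is the within-pair reflection about the grand mean", {
  # single metabolite, pairs (a, b): outputs g +/- (a - b)/2
  values <- matrix(c(4, 10, 8, 2), ncol = 1, dimnames = list(NULL, "m1"))
  pid <- c("A", "A", "B", "B")
  g <- mean(values)
  out <- multilevel_decompose(values, pid)
  expect_equal(unname(out[, 1]), c(g + (4 - 10) / 2, g - (4 - 10) / 2,
                                   g + (8 - 2) / 2, g - (8 - 2) / 2))

  same <- matrix(c(5, 5, 9, 9), ncol = 1, dimnames = list(NULL, "m1"))
  expect_equal(unname(multilevel_decompose(same, pid)[, 1]), rep(7, 4))

  expect_error(multilevel_decompose(values, c("A", "A", "B", "C")), "unpaired")
})

test_that("within- plus between-pair variance reproduces total variance", {
  withr::with_seed(31, {
    values <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("m", 1:3)))
    pid <- rep(sprintf("P%02d", 1:20), each = 2)
    for (j in 1:3) {
      v <- values[, j]
      pm <- tapply(v, pid, mean)[pid]
      ss_within <- sum((v - pm)^2)
      ss_between <- sum((pm - mean(v))^2)
      expect_equal(ss_within + ss_between, sum((v - mean(v))^2))
      # the decomposition retains exactly the within part around the grand mean
      d <- multilevel_decompose(values, pid)[, j]
      expect_equal(sum((d - mean(v))^2), ss_within)
    }
  })
})

test_that("a single perfectly informative metabolite yields a perfect model", {
  y <- rep(c(1, 0), 10)
  x <- cbind(m1 = y * 2 + 1 + rep(c(0.01, -0.01), 5, each = 2))
  fit <- fit_plsda(x, y, n_components = 1)
  expect_equal(abs(unname(fit$W[1, 1])), 1)
  expect_equal(auroc(predict(fit, x), y == 1, positive = TRUE), 1)
  expect_equal(unname(fit$vip), 1)  # p = 1 -> VIP exactly 1
})

test_that("NIPALS matches the closed form on orthonormal predictors", {
  # X columns orthonormal, y = first column: w1 = (1, 0), q1 = 1 recovers y
  x <- cbind(m1 = c(1, -1, 0, 0) / sqrt(2), m2 = c(0, 0, 1, -1) / sqrt(2))
  y <- x[, 1]
  fit <- fit_plsda(x, y, n_components = 1, scale = FALSE)
  expect_equal(unname(fit$W[, 1]), c(1, 0))
  t1 <- x %*% fit$W[, 1]
  expect_equal(fit$q[1], sum((y - mean(y)) * t1) / sum(t1^2))
  expect_equal(unname(predict(fit, x)), unname(y))
})

test_that("score vectors of distinct components are orthogonal", {
  withr::with_seed(23, {
    x <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("m", 1:8)))
    y <- rep(c(1, 0), 15)
    fit <- fit_plsda(x, y, n_components = 3)
    g <- crossprod(fit$scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  })
})

test_that("VIP normalization holds and flags planted effects", {
  withr::with_seed(29, {
    x <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(NULL, paste0("m", 1:12)))
    y <- rep(c(1, 0), 20)
    fit <- fit_plsda(x, y)
    expect_equal(sum(fit$vip^2), 12, tolerance = 1e-8)
  })
  sim <- simulate_dataset(simulation_config(
    500, tiny_panel(6),
    effects = tibble::tibble(metabolite_id = "m3", log_fold_effect = 0.5),
    seed = 8
  ))
  fit <- fit_paired_plsda(sim$dataset)
  expect_equal(names(which.max(fit$vip)), "m3")
  expect_gt(fit$vip["m3"], max(fit$vip[-3]))
})

test_that("prediction equals the explicit regression-vector reconstruction", {
  withr::with_seed(41, {
    x <- matrix(rnorm(24 * 6), 24, 6, dimnames = list(NULL, paste0("m", 1:6)))
    y <- rep(c(1, 0), 12)
    fit <- fit_plsda(x, y, n_components = 2)
    xs <- apply_scaler(fit$scaler, x)
    b <- fit$W %*% solve(crossprod(fit$P, fit$W)) %*% fit$q
    expect_equal(predict(fit, x), drop(fit$y_mean + xs %*% b))
    # mean sample scores at the class midpoint
    mid <- matrix(fit$scaler$mean, 1, dimnames = list(NULL, paste0("m", 1:6)))
    expect_equal(unname(predict(fit, mid)), fit$y_mean)
  })
})

test_that("projection is self-consistent and matches hand arithmetic", {
  withr::with_seed(43, {
    x <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("m1", "m2")))
    y <- rep(c(1, 0), 10)
    fit <- fit_plsda(x, y, n_components = 2)
    pr <- project(fit, x)
    expect_equal(as.matrix(pr), fit$scores, ignore_attr = TRUE)
    expect_equal(unlist(pr[3, ]), unlist(project(fit, x[c(3, 3), ])[1, ]),
                 ignore_attr = TRUE)
    # hand computation for a held-out pair of samples
    new <- matrix(c(0.4, -1.1, 0.2, 0.9), 2, dimnames = list(NULL, c("m1", "m2")))
    ns <- sweep(sweep(new, 2, fit$scaler$mean), 2, fit$scaler$sd, `/`)
    t1 <- ns %*% fit$W[, 1]
    t2 <- (ns - t1 %*% t(fit$P[, 1])) %*% fit$W[, 2]
    expect_equal(as.matrix(project(fit, new)), cbind(LV1 = t1, LV2 = t2),
                 ignore_attr = TRUE)
  })
})

test_that("metabolite permutation permutes VIP/loadings but not predictions", {
  withr::with_seed(47, {
    x <- matrix(rnorm(30 * 7), 30, 7, dimnames = list(NULL, paste0("m", 1:7)))
    y <- rep(c(1, 0), 15)
    perm <- sample(7)
    f1 <- fit_plsda(x, y)
    f2 <- fit_plsda(x[, perm], y)
    expect_equal(f2$vip, f1$vip[perm])
    expect_equal(abs(f2$oriented_loading), abs(f1$oriented_loading[perm]))
    expect_equal(predict(f2, x[, perm]), predict(f1, x))
    expect_equal(auroc(predict(f2, x[, perm]), y == 1, positive = TRUE),
                 auroc(predict(f1, x), y == 1, positive = TRUE))
  })
})

test_that("paired fit applies training grand means to held-out pairs", {
  sim <- simulate_dataset(simulation_config(
    20, tiny_panel(5),
    effects = tibble::tibble(metabolite_id = c("m1", "m4"),
                             log_fold_effect = c(0.8, -0.8)),
    seed = 51
  ))
  ds <- sim$dataset
  train_idx <- ds$samples$patient_id %in% sprintf("P%03d", 1:15)
  train <- paired_dataset(ds$samples[train_idx, ], ds$values[train_idx, ])
  test <- paired_dataset(ds$samples[!train_idx, ], ds$values[!train_idx, ])
  fit <- fit_paired_plsda(train)
  expect_equal(fit$grand_mean, colMeans(train$values))
  scores <- predict(fit, test)
  expect_gt(auroc(scores, test$samples$state), 0.5)
  coords <- project_paired(fit, test)
  expect_equal(names(coords), c("patient_id", "state", "matrix", "LV1", "LV2"))
})

test_that("our NIPALS agrees with an independent PLS-DA implementation", {
  withr::with_seed(53, {
    x <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("m", 1:10)))
    x[, 1] <- x[, 1] + rep(c(1, 0), 15)
    y <- rep(c("IC", "OC"), 15)
    ours <- fit_plsda(x, y, n_components = 2)
    ref <- mixOmics::plsda(x, factor(y), ncomp = 2, scale = TRUE)
    for (a in 1:2) {
      expect_gt(abs(cor(ours$scores[, a], ref$variates$X[, a])), 0.999)
    }
    ref_vip <- mixOmics::vip(ref)
    expect_gt(cor(ours$vip, ref_vip[, 2]), 0.99)
  })
})
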