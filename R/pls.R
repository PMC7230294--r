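#' Unit-variance scaling fitted on training data
#'
#' Estimates per-column mean and sample standard deviation (n - 1 denominator)
#' on a training table; `apply_scaler()` centers and scales any table with the
#' training parameters only, so held-out data never leak into the scaling.
#'
#' @param x Numeric matrix (samples x metabolites), column names required.
#' @return A `voc_scaler` with `mean` and `sd` vectors.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("scaling needs at least 2 training samples")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  constant <- colnames(x)[s < 1e-12]
  if (length(constant) > 0) {
    abort(paste0("constant column(s) cannot be unit-variance scaled: ",
                 paste(head(constant, 5), collapse = ", "),
                 " (should have been filtered)"))
  }
  structure(list(mean = mu, sd = s), class = "voc_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `voc_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "voc_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$mean, `-`), 2, scaler$sd, `/`)
}

#' Within-patient (multilevel) decomposition
#'
#' For a paired design, replaces each value by its within-patient deviation
#' re-centered at the grand mean: `value - patient mean + grand mean`. The
#' two states of a patient become symmetric about the grand mean, removing
#' between-patient variation before the supervised step. When applying to
#' held-out samples, pass the training grand means via `grand_mean`.
#'
#' @param values Numeric matrix, samples x metabolites.
#' @param patient_id Patient label per row; every patient must contribute
#'   exactly two rows.
#' @param grand_mean Per-metabolite grand means; defaults to column means of
#'   `values`.
#' @return Matrix of the same shape.
#' @export
multilevel_decompose <- function(values, patient_id,
                                 grand_mean = colMeans(values)) {
  values <- as.matrix(values)
  tab <- table(patient_id)
  if (any(tab != 2)) {
    abort(paste0("unpaired sample(s) for patient(s): ",
                 paste(names(tab)[tab != 2], collapse = ", ")))
  }
  pm <- rowsum(values, patient_id) / 2
  dev <- values - pm[as.character(patient_id), , drop = FALSE]
  sweep(dev, 2, grand_mean, `+`)
}

#' Fit a PLS1 discriminant model by NIPALS
#'
#' Partial least squares regression of a binary class code on a (typically
#' unit-variance scaled) concentration table, computed by the NIPALS
#' sequence: for each component `a`, `w_a` proportional to `X_a'y_a`
#' (normalized to unit length), scores `t_a = X_a w_a`, X-loadings
#' `p_a = X_a't_a / t_a't_a`, y-loading `q_a = y_a't_a / t_a't_a`, then
#' deflation of `X` and `y`. The sign of each weight vector is fixed so its
#' largest-magnitude coordinate is positive (sign indeterminacy removed
#' within a fit). Deflation stops early (logged) when `t_a't_a` falls below
#' `1e-12`.
#'
#' The model stores per-metabolite VIP values,
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` with
#' `ssy_a = q_a^2 t_a't_a`, so that `sum_j VIP_j^2` equals the number of
#' metabolites, and an oriented first-component loading (sign flipped so that
#' positive means elevated in the positive class, IC).
#'
#' @param x Numeric matrix, samples x metabolites.
#' @param y Binary class code per sample (IC = 1, OC = 0), or labels
#'   convertible via `positive`.
#' @param n_components Number of latent variables (default 2).
#' @param scale Fit a unit-variance scaler on `x` first (default TRUE).
#' @param positive Positive-class label when `y` is not numeric.
#' @return A `plsda_model`.
#' @export
fit_plsda <- function(x, y, n_components = 2, scale = TRUE, positive = "IC") {
  x <- as.matrix(x)
  if (!is.numeric(y)) y <- as.numeric(as_positive(y, positive))
  if (length(unique(y)) < 2) abort("need both classes in training data")
  if (all(y %in% c(0, 1)) && min(table(y)) < 2) {
    abort("need at least 2 samples per class")
  }
  if (n_components > min(nrow(x) - 1, ncol(x))) {
    abort("n_components must be <= min(n_samples - 1, n_metabolites)")
  }
  scaler <- if (scale) fit_scaler(x) else NULL
  xs <- if (scale) apply_scaler(scaler, x) else x
  y_mean <- mean(y)

  p_var <- ncol(xs)
  xa <- xs
  ya <- y - y_mean
  W <- P <- matrix(0, p_var, 0)
  Tm <- matrix(0, nrow(xs), 0)
  q <- tt <- numeric(0)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      voc_log(event = "nipals_early_stop", component = a, reason = "degenerate weight")
      break
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w
    t_a <- drop(xa %*% w)
    tta <- sum(t_a^2)
    if (tta < 1e-12) {
      voc_log(event = "nipals_early_stop", component = a, reason = "degenerate scores")
      break
    }
    p_a <- drop(crossprod(xa, t_a)) / tta
    q_a <- sum(ya * t_a) / tta
    xa <- xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W <- cbind(W, w)
    P <- cbind(P, p_a)
    Tm <- cbind(Tm, t_a)
    q <- c(q, q_a)
    tt <- c(tt, tta)
  }
  if (ncol(W) == 0) abort("no usable PLS component (X carries no class signal)")
  dimnames(W) <- dimnames(P) <- list(colnames(x), paste0("LV", seq_len(ncol(W))))
  colnames(Tm) <- colnames(W)

  ssy <- q^2 * tt
  vip <- sqrt(p_var * drop(W^2 %*% ssy) / sum(ssy))
  orientation <- if (q[1] >= 0) 1 else -1
  model <- structure(
    list(W = W, P = P, q = q, scores = Tm, tt = tt, scaler = scaler,
         y_mean = y_mean, n_components = ncol(W), metabolites = colnames(x),
         vip = setNames(vip, colnames(x)),
         oriented_loading = setNames(orientation * P[, 1], colnames(x)),
         y_map = c(IC = 1, OC = 0)),
    class = "plsda_model"
  )
  model
}

# Internal: latent scores of new (already prepared + scaled) data.
compute_scores <- function(model, xs) {
  Tm <- matrix(0, nrow(xs), model$n_components)
  xa <- xs
  for (a in seq_len(model$n_components)) {
    Tm[, a] <- drop(xa %*% model$W[, a])
    xa <- xa - tcrossprod(Tm[, a], model$P[, a])
  }
  colnames(Tm) <- colnames(model$W)
  Tm
}

prepare_newdata <- function(model, x) {
  x <- as.matrix(x)
  if (!setequal(colnames(x), model$metabolites)) {
    abort("new data must carry exactly the model's metabolite set")
  }
  x <- x[, model$metabolites, drop = FALSE]
  if (!is.null(model$scaler)) apply_scaler(model$scaler, x) else x
}

#' Predict continuous class scores
#'
#' `y_hat = mean(y_train) + sum_a q_a t_a(new)`, with latent scores computed
#' from the stored weights and loadings after applying the training scaler.
#' Scores are monotone in class evidence; 0.5 is the class midpoint.
#'
#' @param object A `plsda_model`.
#' @param x New data matrix with the model's metabolite set.
#' @param ... Unused.
#' @return Numeric score per sample.
#' @export
predict.plsda_model <- function(object, x, ...) {
  Tm <- compute_scores(object, prepare_newdata(object, x))
  drop(object$y_mean + Tm %*% object$q)
}

#' Project samples onto the latent variables
#'
#' @inheritParams predict.plsda_model
#' @param model A `plsda_model`.
#' @return Tibble with one `LV` column per component.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "plsda_model"))
  as_tibble(compute_scores(model, prepare_newdata(model, x)))
}

#' Fit a paired PLS-DA on a paired dataset
#'
#' High-level interface: extracts the concentration grid and IC/OC coding
#' from a [paired_dataset()], optionally removes between-patient variation by
#' [multilevel_decompose()], unit-variance scales, and fits [fit_plsda()].
#' Prediction and projection on new paired data repeat the same preparation
#' with training parameters (training grand means for the multilevel step,
#' training scaler).
#'
#' @param ds A filtered [paired_dataset()].
#' @param n_components Latent variables (default 2).
#' @param multilevel Apply the within-patient decomposition (default TRUE).
#' @return A `paired_plsda` (inherits `plsda_model`).
#' @export
fit_paired_plsda <- function(ds, n_components = 2, multilevel = TRUE) {
  stopifnot(inherits(ds, "paired_dataset"))
  x <- ds$values
  if (multilevel) {
    gm <- colMeans(x)
    x <- multilevel_decompose(x, ds$samples$patient_id, gm)
  } else {
    gm <- NULL
  }
  model <- fit_plsda(x, ds$samples$state, n_components = n_components,
                     scale = TRUE, positive = "IC")
  model$multilevel <- multilevel
  model$grand_mean <- gm
  model$training_samples <- ds$samples
  class(model) <- c("paired_plsda", class(model))
  model
}

# Internal: preparation shared by predict/project on paired data.
prepare_paired <- function(model, ds) {
  stopifnot(inherits(ds, "paired_dataset"))
  x <- ds$values[, model$metabolites, drop = FALSE]
  if (isTRUE(model$multilevel)) {
    x <- multilevel_decompose(x, ds$samples$patient_id,
                              model$grand_mean[model$metabolites])
  }
  x
}

#' @export
predict.paired_plsda <- function(object, x, ...) {
  if (inherits(x, "paired_dataset")) x <- prepare_paired(object, x)
  NextMethod(object, x = x)
}

#' @rdname project
#' @export
project_paired <- function(model, ds) {
  stopifnot(inherits(model, "paired_plsda"))
  dplyr::bind_cols(ds$samples, project(model, prepare_paired(model, ds)))
}
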