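#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs where
#' the positive outscores the negative, ties counted 1/2. Computed from rank
#' sums, so it is invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric classifier scores, higher = more crisis-like.
#' @param labels Class labels, any type; `positive` names the positive class.
#' @param positive The positive-class label (default `"IC"`; for
#'   logical labels `TRUE` is positive).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(1, 2, 2, 3), c("OC", "IC", "OC", "IC"))
#' @export
auroc <- function(scores, labels, positive = "IC") {
  pos <- as_positive(labels, positive)
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) abort("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

as_positive <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  labels == positive
}

#' AUROC with a two-sided p-value against chance
#'
#' Tests AUROC = 0.5 through the equivalent Mann-Whitney U statistic. For
#' untied scores with both class sizes at most `exact_max` the exact
#' permutation distribution of the rank sum is used (dynamic programming over
#' subset rank sums); with ties, a seeded Monte-Carlo permutation test
#' (`mc_draws` label permutations); otherwise a normal approximation with tie
#' correction. The method used is recorded.
#'
#' @inheritParams auroc
#' @param exact_max Largest class size for the exact method (default 12;
#'   the pipeline's validation sets are 10 vs 10).
#' @param mc_draws Monte-Carlo permutations used when scores are tied.
#' @return One-row tibble: `auroc`, `p_value`, `n_pos`, `n_neg`, `method`.
#' @export
auroc_pvalue <- function(scores, labels, positive = "IC",
                         exact_max = 12, mc_draws = 10000) {
  pos <- as_positive(labels, positive)
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) abort("both classes must be present")
  a <- auroc(scores, pos, TRUE)
  u <- a * n1 * n2
  ties <- anyDuplicated(scores) > 0

  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    dist <- ranksum_distribution(n1, n2)  # P(W = w), w = rank sum of positives
    w <- u + n1 * (n1 + 1) / 2
    wi <- round(w) - min(dist$support) + 1
    p_le <- sum(dist$prob[seq_len(wi)])
    p_ge <- sum(dist$prob[wi:length(dist$prob)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else if (ties && n1 <= exact_max && n2 <= exact_max) {
    mu <- n1 * n2 / 2
    obs <- abs(u - mu)
    n <- n1 + n2
    r <- rank(scores, ties.method = "average")
    exceed <- with_seed(derive_seed(sum(n1, n2, round(u * 64)), "auroc_mc"), {
      sum(vapply(seq_len(mc_draws), function(i) {
        rp <- sum(r[sample.int(n, n1)]) - n1 * (n1 + 1) / 2
        abs(rp - mu) >= obs - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (1 + mc_draws)
    method <- "mc_permutation"
  } else {
    # normal approximation with tie correction and continuity correction
    n <- n1 + n2
    tie_counts <- table(scores)
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal_approx"
  }
  tibble(auroc = a, p_value = max(p, .Machine$double.xmin),
         n_pos = as.integer(n1), n_neg = as.integer(n2), method = method)
}

# Exact null distribution of the positive-class rank sum W for untied scores:
# number of n1-subsets of ranks 1..(n1+n2) attaining each sum, by dynamic
# programming; cached per (n1, n2).
ranksum_cache <- new.env(parent = emptyenv())

ranksum_distribution <- function(n1, n2) {
  key <- paste(n1, n2)
  if (!is.null(ranksum_cache[[key]])) return(ranksum_cache[[key]])
  n <- n1 + n2
  min_w <- n1 * (n1 + 1) / 2
  max_w <- sum((n - n1 + 1):n)
  # counts[k + 1, s + 1] = number of k-subsets of {1..i} with sum s
  counts <- matrix(0, n1 + 1, max_w + 1)
  counts[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in min(i, n1):1) {
      reach <- (max_w - i + 1)
      s_idx <- seq_len(reach)
      counts[k + 1, s_idx + i] <- counts[k + 1, s_idx + i] + counts[k, s_idx]
    }
  }
  freq <- counts[n1 + 1, (min_w + 1):(max_w + 1)]
  out <- list(support = min_w:max_w, prob = freq / sum(freq))
  ranksum_cache[[key]] <- out
  out
}

#' PCA sample coordinates
#'
#' Principal component coordinates of a samples x variables table after
#' column centering and (by default) unit-variance scaling — the unsupervised
#' check for sample grouping and outliers. Potential outliers (absolute
#' coordinate beyond 3 standard deviations on a reported component) are
#' flagged but never removed.
#'
#' @param x Numeric matrix or data frame, samples x variables.
#' @param n_components Number of components to report; truncated (with a log
#'   note) if it exceeds the table's rank.
#' @param scale Unit-variance scale columns before decomposition.
#' @return List with `scores` (tibble `PC1`, `PC2`, ..., plus
#'   `potential_outlier`), and `explained_variance` (fractions,
#'   non-increasing).
#' @export
pca_scores <- function(x, n_components = 2, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 samples")
  fit <- prcomp(x, center = TRUE, scale. = scale)
  rank <- sum(fit$sdev > 1e-12)
  if (n_components > rank) {
    voc_log(event = "pca_truncated", requested = n_components, rank = rank)
    n_components <- rank
  }
  sc <- fit$x[, seq_len(n_components), drop = FALSE]
  sds <- apply(sc, 2, sd)
  sds[sds < 1e-12] <- Inf
  out_flag <- rowSums(abs(sweep(sc, 2, sds, "/")) > 3) > 0
  list(
    scores = dplyr::bind_cols(as_tibble(sc),
                              tibble(potential_outlier = unname(out_flag))),
    explained_variance = fit$sdev[seq_len(n_components)]^2 / sum(fit$sdev^2)
  )
}
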