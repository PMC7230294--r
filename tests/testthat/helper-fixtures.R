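options(vocpls.quiet = TRUE)

# Small panel builder: k metabolites named m1..mk with configurable limits.
tiny_panel <- function(k = 4, lloq = 1, uloq = 1000, class = "amino_acid") {
  tibble::tibble(
    metabolite_id = paste0("m", seq_len(k)),
    class = rep_len(class, k),
    lloq = rep_len(lloq, k),
    uloq = rep_len(uloq, k),
    acyl_carbons = NA_integer_
  )
}

# Paired dataset from a values matrix: rows alternate IC/OC per patient.
tiny_dataset <- function(values, matrix = "plasma") {
  n <- nrow(values) / 2
  samples <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", seq_len(n)), each = 2),
    state = rep(c("IC", "OC"), n),
    matrix = matrix
  )
  paired_dataset(samples, values)
}

# Random paired dataset with seeded values in a comfortable mid-range.
random_dataset <- function(n_pairs, k, seed = 1, lloq = 0.001, uloq = 1e6) {
  panel <- tiny_panel(k, lloq = lloq, uloq = uloq)
  values <- withr::with_seed(seed, {
    matrix(exp(rnorm(2 * n_pairs * k, log(10), 0.5)), 2 * n_pairs, k)
  })
  colnames(values) <- panel$metabolite_id
  list(dataset = apply_loq_censoring(tiny_dataset(values), panel), panel = panel)
}

# Brute-force AUROC oracle: explicit pair counting.
auroc_bruteforce <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  total <- 0
  for (p in ps) total <- total + sum(p > ns) + 0.5 * sum(p == ns)
  total / (length(ps) * length(ns))
}
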