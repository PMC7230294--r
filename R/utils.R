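# Internal helpers: logging and reproducible sub-stream seeding.

voc_log <- function(...) {
  if (isTRUE(getOption("vocpls.quiet", FALSE))) return(invisible(NULL))
  fields <- c(...)
  inform(paste(names(fields), unname(fields), sep = "=", collapse = " "))
  invisible(NULL)
}

# Derive a child seed from a master seed and a string key. Keys (metabolite or
# patient identifiers) give each entity its own stream, so extending a panel
# does not reshuffle the draws of existing metabolites.
derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h * 7919 + 1) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (same contract as withr::with_seed, kept dependency-free).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
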