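# Shared fixtures, built in code at test time.

# Small, fast generator settings for unit tests (the full 20-participant
# study conditions are exercised in the acceptance tests).
small_gen <- function(n = 3L, ...) {
  generator_params(n_participants = n, ...)
}

# One cached small dataset reused across test files.
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(default_design(), small_gen(), seed = 101L)
    ds
  }
})

# Trial-level 2x2x2 cell data for n participants with iid noise (one value
# per cell), for ANOVA calibration-style tests.
random_cells_2x2x2 <- function(n, effect_priming = 0, effect_association = 0) {
  grid <- expand.grid(priming = c("primed", "unprimed"),
                      association = c("strong", "weak"),
                      repetition = c("first", "second"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(n), function(p) {
    g <- grid
    g$participant <- p
    g$value <- stats::rnorm(nrow(g)) +
      effect_priming * (g$priming == "unprimed") +
      effect_association * (g$association == "weak")
    g
  }))
}
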