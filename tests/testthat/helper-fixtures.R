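# Small in-code fixtures shared across test files.

# proteome matrix from an explicit intensity matrix; default 2 stages x 4 reps
toy_pm <- function(intensity, n_stages = 2, n_reps = ncol(intensity) / n_stages,
                   mol_mass = rep(50000, nrow(intensity)),
                   stages = paste0("S", seq_len(n_stages))) {
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("p%02d", seq_len(nrow(intensity)))
  proteome_matrix(intensity, mol_mass,
                  col_stage = rep(stages, each = n_reps),
                  col_replicate = rep(seq_len(n_reps), times = n_stages),
                  stages = stages)
}

# well-conditioned positive signature: one dominant marker per stage plus a
# shared baseline, n_per_stage markers each
toy_signature <- function(n_stages = 5, n_per_stage = 2, contrast = 10,
                          baseline = 1) {
  m <- n_stages * n_per_stage
  sig <- matrix(baseline, m, n_stages,
                dimnames = list(sprintf("m%02d", seq_len(m)),
                                paste0("S", seq_len(n_stages))))
  for (i in seq_len(m))
    sig[i, ((i - 1) %% n_stages) + 1] <- contrast
  sig
}

# random simplex vectors without touching the package's generator
rand_simplex <- function(n, k) {
  g <- matrix(stats::rexp(n * k), n, k)
  g / rowSums(g)
}

# default-condition pipeline run shared by acceptance checks (computed once)
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(suppressMessages(
        run_pipeline(pipeline_config(seed = 1))))
    cache
  }
})
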