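# shared fixtures: all generated in code, deterministic under fixed seeds

# a tiny trace set for fast model/training tests (d = 8)
tiny_traces <- function(n = 4, seed = 7) {
  set.seed(seed)
  grid <- seq(0, 7, by = 1)
  base <- 1 - exp(-0.6 * pmax(grid - 1.5, 0))
  traces <- vapply(seq_len(n), function(i)
    pmax(base * (8 + rnorm(1)) + rnorm(length(grid), 0, 0.3), 0),
    numeric(length(grid)))
  time_trace_set(grid, traces)
}

# small preset dataset (fewer traces than the paper-scale 50)
small_dataset <- function(preset = "unimodal", n = 10, seed = 1) {
  ps <- preset_scenarios(n_traces = n, seed = seed)
  generate_dataset(ps[[preset]])
}

# quick training configuration for unit tests (deliberately short)
quick_config <- function(epochs = 60, seed = 1, ...) {
  training_config(max_epochs = epochs, patience = epochs, seed = seed,
                  collocation = 30, profile_points = 4, profile_epochs = 20,
                  profile_init_epochs = 30, profile_refine = FALSE, ...)
}

# regenerates the exact samples whose dip values were frozen from the
# reference AS 217 implementation into dip_reference.csv
dip_reference_samples <- function() {
  set.seed(20260911)
  out <- vector("list", 100)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    type <- c("normal", "uniform", "bimodal", "weak_bimodal", "gamma")[(i %% 5) + 1]
    x <- switch(type,
      normal = rnorm(n), uniform = runif(n),
      bimodal = c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 8)),
      weak_bimodal = c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 2)),
      gamma = rgamma(n, 8, 2))
    out[[i]] <- list(id = i, n = n, type = type, x = x)
  }
  out
}
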