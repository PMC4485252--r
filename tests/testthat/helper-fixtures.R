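# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# Ten runs with the standard protocol parameters (one participant's session).
ten_runs <- function() {
  if (is.null(.fixtures$ten_runs)) {
    .fixtures$ten_runs <- lapply(1:10, function(i) build_run(seed = 1000 + i))
  }
  .fixtures$ten_runs
}

# A small design-matrix pair reused by GLM tests.
source_dm <- function() {
  if (is.null(.fixtures$source_dm)) {
    .fixtures$source_dm <- build_design_matrix(ten_runs(), "lower", "source")
  }
  .fixtures$source_dm
}

# A balanced 7 x 3 x 2 x 2 response table with known structure.
toy_response_table <- function(seed = 42, interaction = 0.09) {
  set.seed(seed)
  grid <- expand.grid(participant = 1:7, area = c("V1", "V2", "V3"),
                      presentation = c("upper", "lower"),
                      source = c("above", "below"),
                      stringsAsFactors = FALSE)
  base <- 0.8 +
    0.05 * (grid$presentation == "upper") +
    0.02 * (grid$source == "below") +
    interaction * (grid$presentation == "lower") * (grid$source == "below")
  grid$psc <- base + rnorm(nrow(grid), sd = 0.05)
  grid
}

# Minimal hand-rolled design matrix wrapper for oracle-sized problems.
tiny_design <- function(X, condition_cols, drift_cols,
                        run_index = rep(1L, nrow(X)), tr = 2) {
  structure(list(
    X = X, condition_cols = condition_cols, drift_cols = drift_cols,
    run_index = run_index, time_s = (seq_len(nrow(X)) - 1) * tr,
    tr = tr, n_volumes = nrow(X), censor_n = 0L,
    condition_spec = "custom", presentation = "lower"
  ), class = "design_matrix")
}
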