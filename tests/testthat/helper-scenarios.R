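# Scenario runs shared across acceptance tests. Each bundle is computed at
# most once per test session; sizes are the scenario defaults (documented in
# the methods vignette), which keep every criterion under its runtime
# budget on one CPU.

.acc_cache <- new.env(parent = emptyenv())

ACC_SEED <- 20260912L
ACC_TRUNC_GRID <- c(0, 0.2, 0.4, 0.6)

acc_scenario <- function(name, truncate = TRUE) {
  key <- paste0(name, if (truncate) "_t" else "")
  if (is.null(.acc_cache[[key]])) {
    .acc_cache[[key]] <- suppressWarnings(run_scenario(
      name, seed = ACC_SEED,
      truncation_grid = if (truncate) ACC_TRUNC_GRID else NULL))
  }
  .acc_cache[[key]]
}

acc_classification <- function(name, truncate = TRUE) {
  key <- paste0("cls_", name, if (truncate) "_t" else "")
  if (is.null(.acc_cache[[key]])) {
    bundle <- acc_scenario(name, truncate)
    .acc_cache[[key]] <- run_classification(bundle$dataset, seed = ACC_SEED)
  }
  .acc_cache[[key]]
}
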