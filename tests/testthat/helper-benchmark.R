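# Full benchmark run: simulate a preset, bin, fit, and score against truth.
run_benchmark <- function(preset, seed, config = workflow_config()) {
  sim <- simulate_bifurcation(scenario_presets(preset, seed = seed))
  bm <- bin_pseudotime(sim$experiment)
  be <- suppressMessages(aggregate_bins(sim$experiment, bm))
  res <- run_trajectory_de(be, config)
  truth <- sim$truth$de[match(res$gene, sim$truth$gene)]
  list(results = res, truth = truth, binned = be)
}
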