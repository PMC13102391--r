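# Simulate one scenario at a given seed, run the decomposition and both
# early-phase group comparisons, and return the two rank-test p-values.
# Bootstrap CIs are skipped: only the p-values matter for recovery
# checks.
scenario_pvalues <- function(scenario, seed, n_mice_per_group = 10) {
  res <- run_full_analysis(scenario, n_mice_per_group = n_mice_per_group,
                           seed = seed, n_boot = 0)
  c(init = res$comparisons$init_vs_learning$test$p_value,
    consol = res$comparisons$learning_vs_consolidated$test$p_value)
}
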