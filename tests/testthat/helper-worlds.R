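# Shared synthetic worlds for the analysis-pipeline tests.

# Amount-threshold cyclin world: size-proportional synthesis with a constant
# amount threshold (adder-like; steady-state division size ~13.5 units,
# ~107-min cycles). The constant "true" threshold in fluorescence units makes
# this the natural world for threshold-recovery tests.
threshold_world <- function(threshold_sd = 4, synthesis_noise_sd = 0.05) {
  cdc13_params(synthesis_rate = 0.07,
               synthesis_noise_sd = synthesis_noise_sd,
               threshold_mean = 80, threshold_sd = threshold_sd,
               birth_level_factor = 0.7,
               synthesis_mode = "size_proportional",
               threshold_mode = "amount")
}

threshold_world_truth <- 80

make_threshold_tables <- function(n_cells, cv, seed, pars = threshold_world()) {
  rbind(synth_cyclin_table(n_cells, "permissive", cyclin = pars,
                           expression_noise_cv = cv, seed = seed),
        synth_cyclin_table(n_cells, "restrictive", cyclin = pars,
                           expression_noise_cv = cv, seed = seed + 1))
}

# Bernoulli septation table drawn directly from a Hill dose-response: the
# quick generator for fitting tests that do not need population dynamics.
bernoulli_sept_table <- function(curve, sizes, seed) {
  stopifnot(inherits(curve, "hill_curve"))
  set.seed(seed)
  data.frame(cell_id = seq_along(sizes), size = sizes,
             septated = stats::runif(length(sizes)) < hill_eval(curve, sizes),
             fluor = NA_real_, condition = "permissive")
}
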