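# shared fixtures: the reference parameter set and the main-experiment
# concentrations; all synthetic data is generated in code at test time

ref_params <- function() camnet_params()

main_conc <- function() concentrations(0.713, 0.0237)

# draw a random but valid (params, variant, conc, x) instance
random_instance <- function() {
  list(
    params = camnet_params(k_apo = runif(1, 0, 1), k_nlobe = runif(1, 0, 5),
                           k_clobe = runif(1, 0, 50), k_both = runif(1, 0, 2000),
                           ca_assoc_N = runif(1, 0, 20),
                           ca_assoc_C = runif(1, 0, 20)),
    variant = model_variant(sample(1:3, 1),
                            sample(c("WT", "N", "C", "NC"), 1)),
    conc = concentrations(runif(1, 0.01, 50), runif(1, 0.001, 5)),
    x = runif(1, 0, 50)
  )
}

# small, fast synthetic plate dataset (three replicates everywhere)
small_plate <- function(seed = 1, cv = 0.02, mutants = c("WT", "N")) {
  reps <- stats::setNames(rep(3L, length(mutants) + 1),
                          c(mutants, "baseline"))
  simulate_fret(mutants = mutants, n_replicates = reps,
                noise = noise_model(channel_cv = cv), seed = seed)
}

# the study's observed binding calls for the three Table-style variants
observed_study_calls <- function() {
  data.frame(
    mutant = rep(c("WT", "N", "C"), each = 2),
    regime = rep(c("zero_ca", "high_ca"), 3),
    call = c("NB", "B", "NB", "B", "NB", "NB"),
    stringsAsFactors = FALSE
  )
}
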