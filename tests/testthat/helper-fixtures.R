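# shared small fixtures, built in code

.accumimic_test_env <- new.env(parent = emptyenv())

small_design <- function(n_subjects = 1, n_trials = 40, seed = 11) {
  generate_design(n_subjects, n_trials, seed = seed)
}

# closed-form probability of absorption at the upper boundary for a
# constant-drift diffusion between static bounds (start z_rel * a from the
# lower bound, unit diffusion)
p_upper_closed <- function(v, a, z_rel) {
  if (abs(v) < 1e-12) return(z_rel)
  (1 - exp(-2 * v * z_rel * a)) / (1 - exp(-2 * v * a))
}
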