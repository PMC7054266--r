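# Shared fixtures: a reference parameter set, quick engine configs, and the
# analytic absorption probability of a constant-drift diffusion between two
# absorbing bounds (the independent oracle for engine/simulator checks).

p_ref <- function() se_params(v = 3, x_th = 0.6, t = 0.3, s_t = 0.1,
                              b = 2.5, x_b = 0.1)

p_basic <- function() se_params(v = 1, x_th = 0.5, t = 0.3)

# P(absorb at upper bound) for drift v, bounds at 0 and a, start z
absorb_prob <- function(v, z, a, s = 1) {
  (1 - exp(-2 * v * z / s^2)) / (1 - exp(-2 * v * a / s^2))
}

# defective empirical CDFs of simulated trials evaluated on a time grid
empirical_defective_cdf <- function(rts, flags, grid) {
  n <- length(rts)
  vapply(grid, function(g) sum(flags & rts <= g) / n, 0)
}

make_recovery_data <- function(params, n_per_cond, seed) {
  set.seed(seed)
  rbind(simulate_trials(params, 0, n_per_cond),
        simulate_trials(params, 1, n_per_cond))
}
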