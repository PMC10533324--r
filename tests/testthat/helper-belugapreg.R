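# Shared fixtures, all built in code.

# Two-group world used throughout: resting vs pregnant moments from the
# carcass validation sample.
two_group_specs <- function(n_per_group = 100L) {
  list(
    group_spec("resting", n_per_group, 3.1, 4.5),
    group_spec("pregnant", n_per_group, 365, 244)
  )
}

two_group_log_bp <- function(seed, n_per_group = 100L) {
  log_bp(simulate_known_samples(two_group_specs(n_per_group),
                                seed = seed)$bp_tissue_ng_g)
}

# Point-mass mixture fit: every draw identical; handy for closed-form checks.
point_mass_mixture <- function(mu, sigma, w, draws = 50L) {
  mixture_fit(
    mu = matrix(mu, draws, length(mu), byrow = TRUE),
    sigma = matrix(sigma, draws, length(mu), byrow = TRUE),
    w = matrix(w, draws, length(mu), byrow = TRUE)
  )
}

# A small known-status table with colour classes, for pipeline tests.
demo_samples <- function(seed = 1L, n_unknown = 60L) {
  known <- simulate_known_samples(reference_group_specs(), seed = seed)
  unknown <- simulate_unknown_population(biopsy_population_spec(), n_unknown,
                                         seed = seed + 1L)
  rbind(known, unknown)
}
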