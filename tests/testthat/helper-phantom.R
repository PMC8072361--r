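# Shared fixtures, built in code. The default AIF and a small phantom reused
# across test files; heavier acceptance-scale objects are memoised in
# helper-acceptance.R.

default_aif <- function() synthesize_aif(aif_params())

mini_phantom <- function(delay = 0, noise = noise_scales()[["myocardium"]],
                         nreal = 4, seed = 11, time_scale = 60) {
  build_phantom(phantom_spec(fp_values = seq(0.48, 3.9, length.out = 5),
                             vp_values = c(0.04, 0.07, 0.1),
                             realizations_per_tile = nreal,
                             delay = delay, noise_sigma = noise, seed = seed,
                             kinetic_time_scale = time_scale))
}

# small Bayesian grid for fast unit tests (the default grids are used in the
# acceptance suite)
small_bayes_config <- function(...) {
  bayes_config(bf_grid = exp(seq(log(0.2), log(8), length.out = 24)),
               delay_grid = seq(0, 4.2, by = 0.35),
               eps_grid = exp(seq(log(1e-3), log(1e3), length.out = 12)),
               residue_support_max = 60, ...)
}
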