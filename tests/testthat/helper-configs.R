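# Small configurations used across tests: desk-scale worlds that keep the
# reference (pure R) engine fast while exercising every code path.

config_with <- function(defaults, overrides) {
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

small_fixed_config <- function(...) {
  config_with(list(n_individuals = 40L, n_patches = 30L,
                   payoff_variance = 100, turnover = 0.05,
                   skew = skew_config("fixed_proportion"),
                   max_rounds = 60L, replicates = 5L), list(...))
}

small_asexual_config <- function(beta = 0.5, ...) {
  config_with(list(n_individuals = 40L, n_patches = 30L,
                   payoff_variance = 100, turnover = 0.05,
                   skew = skew_config("asexual", beta = beta),
                   max_rounds = 60L, replicates = 5L), list(...))
}

small_sexual_config <- function(beta_f = 0.9, beta_m = 0.1, ...) {
  config_with(list(n_individuals = 40L, n_patches = 30L,
                   payoff_variance = 100, turnover = 0.05,
                   skew = skew_config("sexual", beta_f = beta_f,
                                      beta_m = beta_m),
                   max_rounds = 60L, replicates = 5L), list(...))
}

# A mature individual with a given payoff history (most recent first).
mature_individual <- function(history, alpha = 0, window = 5L) {
  ind <- new_individual(1L, alpha, age = max(length(history), window))
  ind$history <- history
  ind
}
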