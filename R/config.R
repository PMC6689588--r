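# Flat YAML keys accepted by load_config() and their config destinations.
.config_keys <- c(
  "n_individuals", "n_patches", "mean_payoff", "payoff_variance",
  "turnover", "learn_prob", "delta", "discount_r", "fitness_mode",
  "mode", "criterion", "beta", "beta_f", "beta_m", "mutation_rate",
  "death_prob", "max_age", "strict_sex_ratio", "max_rounds", "replicates",
  "init_alpha", "force_individual_learning", "naive_learning"
)

#' Load a simulation configuration from a YAML file
#'
#' Reads a flat YAML mapping, applies the standard defaults for every key
#' not present (an empty file yields the full default configuration), and
#' validates the result.  Unknown keys are rejected with an error naming
#' the key.  The provenance of every field (`"default"` or `"file"`) is
#' attached as the `"provenance"` attribute, and the resolved
#' configuration round-trips through [save_config()].
#'
#' Recognised keys: `n_individuals`, `n_patches`, `mean_payoff`,
#' `payoff_variance`, `turnover`, `learn_prob`, `delta` (fitness window),
#' `discount_r`, `fitness_mode`, `mode`, `criterion`, `beta`, `beta_f`,
#' `beta_m`, `mutation_rate` (a probability or the string `"1/N"`),
#' `death_prob`, `max_age`, `strict_sex_ratio`, `max_rounds`,
#' `replicates`, `init_alpha`, `force_individual_learning`,
#' `naive_learning`.
#'
#' @param path path to a YAML file.
#' @return A validated `sl_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' Build a configuration from a flat named list
#'
#' The programmatic equivalent of [load_config()]; used by the command
#' line interface to merge file values with flag overrides.
#'
#' @param values named list of configuration keys (see [load_config()]).
#' @param provenance character label recorded for the supplied keys.
#' @return A validated `sl_config`.
#' @export
config_from_list <- function(values, provenance = "file") {
  unknown <- setdiff(names(values), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- function(key, default) if (key %in% names(values)) values[[key]] else default

  mode <- g("mode", "asexual")
  fitness <- fitness_params(window = g("delta", 5L),
                            discount = g("discount_r", 0.2),
                            mode = g("fitness_mode", "windowed"))
  skew <- skew_config(
    mode = mode,
    criterion = g("criterion", "minimum_income"),
    beta = g("beta", 1),
    beta_f = g("beta_f", if (mode == "sexual") 1 else NULL),
    beta_m = g("beta_m", if (mode == "sexual") 1 else NULL),
    mutation_rate = g("mutation_rate", "1/N"),
    death_prob = g("death_prob", 0.01),
    max_age = g("max_age", 100L),
    strict_sex_ratio = g("strict_sex_ratio", FALSE))
  cfg <- sim_config(
    n_individuals = g("n_individuals", 1000L),
    n_patches = g("n_patches", 1000L),
    mean_payoff = g("mean_payoff", 4),
    payoff_variance = g("payoff_variance", 100),
    turnover = g("turnover", 10^-1.5),
    learn_prob = g("learn_prob", 0.2),
    fitness = fitness,
    skew = skew,
    max_rounds = g("max_rounds", 5000L),
    replicates = g("replicates", 200L),
    init_alpha = g("init_alpha", NULL),
    force_individual_learning = g("force_individual_learning", FALSE),
    naive_learning = g("naive_learning", "alpha"))
  prov <- setNames(rep("default", length(.config_keys)), .config_keys)
  prov[names(values)] <- provenance
  attr(cfg, "provenance") <- prov
  cfg
}

# Flatten an sl_config back to the YAML key set.
config_to_list <- function(config) {
  skew <- config$skew
  fp <- config$fitness
  out <- list(
    n_individuals = config$n_individuals,
    n_patches = config$n_patches,
    mean_payoff = config$mean_payoff,
    payoff_variance = config$payoff_variance,
    turnover = config$turnover,
    learn_prob = config$learn_prob,
    delta = fp$window,
    discount_r = fp$discount,
    fitness_mode = fp$mode,
    mode = skew$mode,
    criterion = skew$criterion,
    beta = skew$beta,
    mutation_rate = skew$mutation_rate,
    death_prob = skew$death_prob,
    max_age = skew$max_age,
    strict_sex_ratio = skew$strict_sex_ratio,
    max_rounds = config$max_rounds,
    replicates = config$replicates,
    init_alpha = config$init_alpha,
    force_individual_learning = config$force_individual_learning,
    naive_learning = config$naive_learning)
  if (!is.null(skew$beta_f)) out$beta_f <- skew$beta_f
  if (!is.null(skew$beta_m)) out$beta_m <- skew$beta_m
  out
}

#' Write a configuration to YAML
#'
#' Serialises the resolved configuration so that reloading it with
#' [load_config()] yields an identical configuration; numeric values are
#' written at full precision to avoid round-trip drift.
#'
#' @param config an `sl_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path,
                   precision = 17L, handlers = NULL)
  invisible(path)
}

#' @export
print.sl_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sl_config> N=%d, M=%d, mean payoff %g, variance %g, ",
           "turnover %g\n  mode=%s, criterion=%s, learn_prob=%g, ",
           "delta=%d, r=%g, max_rounds=%d\n"),
    x$n_individuals, x$n_patches, x$mean_payoff, x$payoff_variance,
    x$turnover, x$skew$mode, x$skew$criterion, x$learn_prob,
    x$fitness$window, x$fitness$discount, x$max_rounds))
  invisible(x)
}
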