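#' Simulation configuration
#'
#' Collects every model parameter with its standard default: populations of
#' N = 1000 individuals on M = 1000 patches, mean patch payoff 4, learning
#' probability 0.2, fitness window 5 with discount rate 0.2, random death
#' probability 0.01, maximum age 100, mutation rate 1/N, and runs of at
#' most 5000 rounds.  The reference environment is an uneven world
#' (payoff variance 100) with intermediate turnover 10^-1.5.
#'
#' @param n_individuals population size N.
#' @param n_patches number of patches M.
#' @param mean_payoff mean patch payoff.
#' @param payoff_variance patch payoff variance (1 = even world, 100 =
#'   uneven world).
#' @param turnover per-patch per-round payoff redraw probability.
#' @param learn_prob probability that an individual spends a round
#'   learning rather than exploiting.
#' @param fitness an [fitness_params()] object.
#' @param skew an [skew_config()] object.
#' @param max_rounds maximum number of rounds per run.
#' @param replicates default replicate count for [run_replicates()].
#' @param init_alpha initial strategy composition: `"half"` (exactly half
#'   the population social learners, alpha = 1), `"random"` (independent
#'   fair draws of 0/1 per individual), `"all_social"`, `"all_individual"`,
#'   or a numeric vector of length `n_individuals` with values in \[0, 1\]
#'   (continuous propensities are allowed in fixed-proportion runs only).
#' @param force_individual_learning if `TRUE`, disables the social channel
#'   entirely (every learning turn is individual); used for equivalence
#'   checks.
#' @param naive_learning what an exploiter with an empty memory (a naive
#'   newborn) does with its forced learning turn: `"alpha"` (default) treats
#'   it as an ordinary learning turn, social with probability alpha, so
#'   naive social learners immediately copy; `"individual"` makes naive
#'   individuals sample a random patch regardless of alpha.
#' @return An object of class `sl_config`.
#' @examples
#' cfg <- sim_config(payoff_variance = 1, turnover = 0.01,
#'                   skew = skew_config("fixed_proportion"))
#' @export
sim_config <- function(n_individuals = 1000L, n_patches = 1000L,
                       mean_payoff = 4, payoff_variance = 100,
                       turnover = 10^-1.5, learn_prob = 0.2,
                       fitness = fitness_params(),
                       skew = skew_config("asexual"),
                       max_rounds = 5000L, replicates = 200L,
                       init_alpha = NULL,
                       force_individual_learning = FALSE,
                       naive_learning = c("alpha", "individual")) {
  naive_learning <- match.arg(naive_learning)
  if (is.null(init_alpha))
    init_alpha <- if (skew$mode == "sexual") "random" else "half"
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_patches = as.integer(n_patches),
    mean_payoff = mean_payoff,
    payoff_variance = payoff_variance,
    turnover = turnover,
    learn_prob = learn_prob,
    fitness = fitness,
    skew = skew,
    max_rounds = as.integer(max_rounds),
    replicates = as.integer(replicates),
    init_alpha = init_alpha,
    force_individual_learning = isTRUE(force_individual_learning),
    naive_learning = naive_learning
  ), class = "sl_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks ranges and cross-field consistency; errors name the offending
#' field and constraint.  Returns the config invisibly so it can be used
#' in pipelines.
#'
#' @param config an `sl_config`.
#' @export
validate_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(config$n_individuals >= 1, "`n_individuals` must be >= 1")
  chk(config$n_patches >= 1, "`n_patches` must be >= 1")
  chk(config$mean_payoff > 0, "`mean_payoff` must be > 0")
  chk(config$payoff_variance > 0, "`payoff_variance` must be > 0")
  chk(config$turnover >= 0 && config$turnover <= 1,
      "`turnover` must be a probability in [0, 1]")
  chk(config$learn_prob >= 0 && config$learn_prob <= 1,
      "`learn_prob` must be a probability in [0, 1]")
  chk(inherits(config$fitness, "sl_fitness_params"),
      "`fitness` must come from fitness_params()")
  chk(inherits(config$skew, "sl_skew_config"),
      "`skew` must come from skew_config()")
  chk(config$max_rounds >= 1, "`max_rounds` must be >= 1")
  chk(config$replicates >= 1, "`replicates` must be >= 1")
  ia <- config$init_alpha
  if (is.character(ia)) {
    chk(ia %in% c("half", "random", "all_social", "all_individual"),
        "`init_alpha` must be one of \"half\", \"random\", \"all_social\", \"all_individual\", or a numeric vector")
  } else {
    chk(is.numeric(ia) && length(ia) == config$n_individuals,
        "`init_alpha` vector must have length `n_individuals`")
    chk(all(ia >= 0 & ia <= 1), "`init_alpha` values must lie in [0, 1]")
    if (config$skew$mode != "fixed_proportion")
      chk(all(ia %in% c(0, 1)),
          "evolutionary modes require binary init_alpha (0/1); continuous propensities are supported in fixed_proportion mode only")
  }
  invisible(config)
}

# mutation spec "1/N" resolves against the configured population size
resolved_mutation_rate <- function(config) {
  mu <- config$skew$mutation_rate
  if (identical(mu, "1/N")) 1 / config$n_individuals else mu
}

# initial alpha values per the configured composition
init_alpha_values <- function(config) {
  n <- config$n_individuals
  ia <- config$init_alpha
  if (is.numeric(ia)) return(ia)
  switch(ia,
    half = {
      a <- numeric(n)
      a[sample.int(n, floor(n / 2))] <- 1
      a
    },
    random = as.numeric(runif(n) < 0.5),
    all_social = rep(1, n),
    all_individual = rep(0, n)
  )
}

# sexual populations start with an even split of females and males
init_sex_values <- function(config) {
  n <- config$n_individuals
  if (config$skew$mode != "sexual") return(rep("none", n))
  s <- rep(c("female", "male"), length.out = n)
  sample(s)
}

#' Run a single simulation
#'
#' Executes rounds until fixation (evolutionary modes: all individuals
#' share the same alpha) or `max_rounds`, whichever comes first.
#' Fixed-proportion runs always last exactly `max_rounds` as their
#' composition cannot fix.  Fully reproducible given `(config, seed)`.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed for this run.
#' @param engine `"cpp"` (default; full-scale runs) or `"r"` (reference
#'   engine composed from the exported per-operation functions; intended
#'   for small configurations).  The engines implement the same algorithm
#'   but do not consume random numbers in the same order, so matching
#'   seeds give statistically equivalent, not identical, trajectories.
#' @param log_individuals if `TRUE`, keep a long-format per-round,
#'   per-individual log (columns round, ident, alpha, sex, action, patch,
#'   collected).  Memory-hungry; meant for small runs and audits.
#' @return An object of class `sl_run`: a list with `rounds` (per-round
#'   summary data.frame), `final` (per-individual table for the last
#'   executed round, before that round's mortality), `termination`
#'   (`round` and `cause`, `"fixation"` or `"max_rounds"`),
#'   `max_conservation_error`, `seed`, `config` and optionally `log`.
#' @export
run_single <- function(config, seed, engine = c("cpp", "r"),
                       log_individuals = FALSE) {
  engine <- match.arg(engine)
  validate_config(config)
  set.seed(seed)
  res <- if (engine == "cpp") run_engine_cpp_wrap(config, log_individuals)
         else run_engine_r(config, log_individuals)
  res$seed <- seed
  res$engine <- engine
  res$config <- config
  class(res) <- "sl_run"
  res
}

run_engine_cpp_wrap <- function(config, log_individuals) {
  skew <- config$skew
  fp <- config$fitness
  alpha <- init_alpha_values(config)
  sex <- init_sex_values(config)
  sex_code <- match(sex, c("female", "male", "none")) - 1L
  ages <- sample.int(skew$max_age, config$n_individuals, replace = TRUE) - 1L
  mode_code <- match(skew$mode, c("fixed_proportion", "asexual", "sexual")) - 1L
  crit_code <- match(skew$criterion,
                     c("minimum_income", "relative_income")) - 1L
  fmode_code <- match(fp$mode, c("windowed", "single_round")) - 1L
  out <- .run_engine_cpp(
    config$n_individuals, config$n_patches,
    config$mean_payoff, config$payoff_variance,
    config$turnover, config$learn_prob,
    fp$window, fp$discount, fmode_code,
    mode_code, crit_code,
    if (is.null(skew$beta)) 1 else skew$beta,
    if (is.null(skew$beta_f)) 1 else skew$beta_f,
    if (is.null(skew$beta_m)) 1 else skew$beta_m,
    resolved_mutation_rate(config), skew$death_prob, skew$max_age,
    config$max_rounds, alpha, sex_code, ages,
    config$force_individual_learning, skew$strict_sex_ratio,
    identical(config$naive_learning, "alpha"), log_individuals)
  if (out$n_pool_fallback > 0)
    warning(sprintf("parent pool fell back to all survivors in %d round(s)",
                    out$n_pool_fallback))
  res <- list(rounds = out$rounds, final = out$final,
              termination = list(round = out$termination_round,
                                 cause = out$termination_cause),
              max_conservation_error = out$max_conservation_error)
  if (log_individuals) res$log <- out$log
  res
}

run_engine_r <- function(config, log_individuals) {
  env <- create_environment(config$n_patches, config$mean_payoff,
                            config$payoff_variance, config$turnover)
  pop <- init_population(config)
  state <- init_round_state(config$n_individuals, config$n_patches)
  records <- vector("list", config$max_rounds)
  logs <- if (log_individuals) vector("list", config$max_rounds)
  term_cause <- "max_rounds"
  term_round <- config$max_rounds
  max_err <- 0
  evolutionary <- config$skew$mode != "fixed_proportion"
  for (t in seq_len(config$max_rounds)) {
    stp <- step_round(pop, env, state, config)
    pop <- stp$population
    env <- stp$env
    state <- stp$state
    records[[t]] <- cbind(round = t, stp$record)
    max_err <- max(max_err, stp$record$conservation_error)
    if (log_individuals)
      logs[[t]] <- data.frame(
        round = t, ident = state$ident, alpha = state$alpha,
        sex = state$sex, action = state$action, patch = state$patch,
        collected = state$collected, stringsAsFactors = FALSE)
    if (evolutionary) {
      a <- vapply(pop, `[[`, numeric(1), "alpha")
      if (all(a == a[1])) {
        term_cause <- "fixation"
        term_round <- t
        break
      }
    }
    if (t == config$max_rounds) term_round <- t
  }
  rounds <- do.call(rbind, records[seq_len(term_round)])
  final <- data.frame(
    ident = state$ident, alpha = state$alpha, sex = state$sex,
    age = state$age, action = state$action, patch = state$patch,
    collected = state$collected, stringsAsFactors = FALSE)
  res <- list(rounds = rounds, final = final,
              termination = list(round = term_round, cause = term_cause),
              max_conservation_error = max_err)
  if (log_individuals)
    res$log <- do.call(rbind, logs[seq_len(term_round)])
  res
}

#' @export
print.sl_run <- function(x, ...) {
  cat(sprintf(
    "<sl_run> mode=%s, %d rounds (%s), final social-learning frequency %.3f\n",
    x$config$skew$mode, x$termination$round, x$termination$cause,
    x$rounds$freq_social[nrow(x$rounds)]))
  invisible(x)
}

# Seeds for replicate i are the i-th draws of a stream seeded with
# base_seed, so a replicate set can be extended without changing the seeds
# of the replicates already run.
derive_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max, n)
}

#' Run seeded replicates
#'
#' Runs `n_replicates` independent replicates of the same configuration,
#' each with its own seed derived from `base_seed`.  Re-running with the
#' same arguments reproduces every replicate exactly; extending
#' `n_replicates` keeps the seeds of existing replicates unchanged.
#'
#' @param config an [sim_config()] object.
#' @param n_replicates number of replicates (default taken from the
#'   config).
#' @param base_seed integer seed for the replicate seed stream.
#' @param engine passed to [run_single()].
#' @return An object of class `sl_replicates`: a list of `sl_run` objects
#'   with the config and seeds attached as attributes.
#' @export
run_replicates <- function(config, n_replicates = config$replicates,
                           base_seed = 1L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(base_seed, n_replicates)
  runs <- lapply(seq_len(n_replicates), function(i)
    run_single(config, seeds[i], engine = engine))
  structure(runs, class = "sl_replicates", config = config, seeds = seeds,
            base_seed = base_seed)
}

#' @export
print.sl_replicates <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sl_replicates> %d runs, mode=%s, sigma2=%g, tau=%g\n",
              length(x), cfg$skew$mode, cfg$payoff_variance, cfg$turnover))
  invisible(x)
}

# The cells of a sweep as a data.frame (exposed for inspection/tests).
build_sweep_cells <- function(beta = NULL, turnover = NULL,
                              payoff_variance = NULL,
                              beta_f = NULL, beta_m = NULL) {
  sexual <- !is.null(beta_f) || !is.null(beta_m)
  if (sexual) {
    if (is.null(beta_f) || is.null(beta_m))
      stop("sexual sweeps need both `beta_f` and `beta_m`", call. = FALSE)
    cells <- expand.grid(beta_f = beta_f, beta_m = beta_m,
                         turnover = turnover %||% NA_real_,
                         payoff_variance = payoff_variance %||% NA_real_,
                         KEEP.OUT.ATTRS = FALSE)
  } else {
    if (is.null(beta)) stop("asexual sweeps need `beta`", call. = FALSE)
    cells <- expand.grid(beta = beta, turnover = turnover %||% NA_real_,
                         payoff_variance = payoff_variance %||% NA_real_,
                         KEEP.OUT.ATTRS = FALSE)
  }
  cells
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter sweep
#'
#' Runs seeded replicates for every cell of a grid over reproductive skew,
#' turnover and payoff variance (asexual grids) or over sex-specific skews
#' `beta_f` x `beta_m` (sexual grids).  Grid values left `NULL` fall back
#' to the template configuration's value.
#'
#' @param config template [sim_config()]; each cell overrides its swept
#'   fields.
#' @param beta,turnover,payoff_variance numeric grids (asexual sweeps).
#' @param beta_f,beta_m numeric grids for sexual sweeps (both or neither).
#' @param n_replicates replicates per cell.
#' @param base_seed seed; every cell gets an independent derived seed
#'   stream, so results do not depend on cell order.
#' @param engine passed to [run_single()].
#' @return A long-format data.frame with one row per (cell, replicate):
#'   swept parameters, `replicate`, `seed`, evolved social-learning
#'   frequencies (`freq_social`, `freq_social_f`, `freq_social_m`),
#'   final-round mean collected payoffs by strategy, and the termination
#'   round and cause.
#' @export
sweep_grid <- function(config, beta = NULL, turnover = NULL,
                       payoff_variance = NULL, beta_f = NULL, beta_m = NULL,
                       n_replicates = config$replicates, base_seed = 1L,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cells <- build_sweep_cells(beta, turnover, payoff_variance, beta_f, beta_m)
  if (nrow(cells) == 0) stop("empty sweep grid", call. = FALSE)
  cell_seeds <- derive_seeds(base_seed, nrow(cells))
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- config
    cell <- cells[ci, , drop = FALSE]
    if (!is.null(cell$beta)) cfg$skew$beta <- cell$beta
    if (!is.null(cell$beta_f)) cfg$skew$beta_f <- cell$beta_f
    if (!is.null(cell$beta_m)) cfg$skew$beta_m <- cell$beta_m
    if (!is.na(cell$turnover)) cfg$turnover <- cell$turnover
    if (!is.na(cell$payoff_variance))
      cfg$payoff_variance <- cell$payoff_variance
    reps <- run_replicates(cfg, n_replicates, base_seed = cell_seeds[ci],
                           engine = engine)
    seeds <- attr(reps, "seeds")
    rows <- lapply(seq_along(reps), function(i) {
      r <- reps[[i]]
      last <- r$rounds[nrow(r$rounds), ]
      ex <- r$final[r$final$action == "exploit", ]
      soc <- ex$alpha >= 0.5
      data.frame(
        cell,
        replicate = i, seed = seeds[i],
        freq_social = last$freq_social,
        freq_social_f = last$freq_social_f,
        freq_social_m = last$freq_social_m,
        mean_collected_social =
          if (any(soc)) mean(ex$collected[soc]) else NA_real_,
        mean_collected_individual =
          if (any(!soc)) mean(ex$collected[!soc]) else NA_real_,
        termination_round = r$termination$round,
        termination_cause = r$termination$cause,
        row.names = NULL, stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$turnover[is.na(res$turnover)] <- config$turnover
  res$payoff_variance[is.na(res$payoff_variance)] <- config$payoff_variance
  res
}

#' Write the per-round individual log of a run as tidy CSV
#'
#' @param run an `sl_run` produced with `log_individuals = TRUE`.
#' @param path output file.
#' @export
write_round_log <- function(run, path) {
  if (is.null(run$log))
    stop("run has no individual log; use run_single(..., log_individuals = TRUE)",
         call. = FALSE)
  write.csv(run$log, path, row.names = FALSE)
  invisible(path)
}
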