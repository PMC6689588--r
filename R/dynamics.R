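#' Initialise a population
#'
#' Builds the starting population for a run.  Starting ages are drawn
#' uniformly on `{0, ..., max_age - 1}` so mature individuals exist from
#' the first rounds; memories and payoff histories start empty.
#'
#' @param config an `sl_config` (see [sim_config()]).
#' @return An object of class `sl_population`: a list of
#'   [new_individual()] objects.
#' @export
init_population <- function(config) {
  n <- config$n_individuals
  alpha <- init_alpha_values(config)
  sex <- init_sex_values(config)
  ages <- sample.int(config$skew$max_age, n, replace = TRUE) - 1L
  pop <- vector("list", n)
  for (i in seq_len(n))
    pop[[i]] <- new_individual(i, alpha[i], sex[i], ages[i])
  structure(pop, class = "sl_population")
}

#' Empty round state
#'
#' Holds what carries over between rounds: which patch each individual
#' exploited in the previous round (the demonstrator pool for social
#' learning), and the most recent round's occupancy and collected payoffs.
#'
#' @param n_individuals population size.
#' @param n_patches number of patches.
#' @return An object of class `sl_round_state`.
#' @export
init_round_state <- function(n_individuals, n_patches) {
  structure(list(
    prev_patch = rep(NA_integer_, n_individuals),
    occupancy = integer(n_patches),
    collected = numeric(n_individuals),
    action = rep(NA_character_, n_individuals),
    patch = rep(NA_integer_, n_individuals)
  ), class = "sl_round_state")
}

#' Draw this round's actions
#'
#' Each individual independently becomes a learner with probability
#' `learn_prob` and an exploiter otherwise.  An exploiter whose memory is
#' empty knows of no patch to exploit and is reassigned as an individual
#' learner for the round (flagged in `forced`).
#'
#' @param pop an `sl_population`.
#' @param learn_prob probability of learning in a round (the standard
#'   default of 0.2 lives in [sim_config()]).
#' @return A list with integer index vectors `learners`, `exploiters` and
#'   `forced` (the subset of `learners` that was reassigned).
#' @export
draw_actions <- function(pop, learn_prob) {
  if (learn_prob < 0 || learn_prob > 1)
    stop("`learn_prob` must be a probability", call. = FALSE)
  n <- length(pop)
  learner <- logical(n)
  forced <- logical(n)
  for (i in seq_len(n)) {
    learner[i] <- runif(1) < learn_prob
    if (!learner[i] && length(pop[[i]]$memory) == 0) {
      learner[i] <- TRUE
      forced[i] <- TRUE
    }
  }
  list(learners = which(learner), exploiters = which(!learner),
       forced = which(forced))
}

#' Resolve simultaneous patch exploitation
#'
#' All exploiters commit to their chosen patches, occupancy is counted
#' once, and each exploiter of patch m collects pi_m / n_m (exploitative
#' scramble competition: patch payoffs are shared equally).  Each exploiter
#' then stores the realised per-capita payoff as its new memory of that
#' patch.
#'
#' @param pop an `sl_population`.
#' @param choices named integer vector mapping exploiter index (names) to
#'   chosen patch.
#' @param env an `sl_env`.
#' @return A list with the updated `population`, the `occupancy` count per
#'   patch and the `collected` payoff per individual (0 for non-exploiters).
#' @export
resolve_exploitation <- function(pop, choices, env) {
  n_patches <- length(env$payoffs)
  occupancy <- tabulate(choices, nbins = n_patches)
  collected <- numeric(length(pop))
  for (k in seq_along(choices)) {
    i <- as.integer(names(choices)[k])
    m <- choices[[k]]
    share <- env$payoffs[m] / occupancy[m]
    collected[i] <- share
    pop[[i]] <- update_memory(pop[[i]], m, share)
  }
  list(population = pop, occupancy = occupancy, collected = collected)
}

#' Learn about a uniformly random patch
#'
#' Individual learning: the learner inspects one patch drawn uniformly
#' from all patches and stores its expected payoff, pi_m / n_m given the
#' current round's occupancy (pi_m itself when the patch is unoccupied).
#'
#' @param ind an `sl_individual`.
#' @param env an `sl_env`.
#' @param occupancy integer vector of current exploiter counts per patch.
#' @return The individual with its memory updated; the observed patch is
#'   attached as attribute `"patch"`.
#' @export
individual_learn <- function(ind, env, occupancy) {
  m <- sample.int(length(env$payoffs), 1L)
  phat <- if (occupancy[m] > 0) env$payoffs[m] / occupancy[m] else env$payoffs[m]
  ind <- update_memory(ind, m, phat)
  attr(ind, "patch") <- m
  ind
}

#' Learn socially from a previous-round exploiter
#'
#' Social learning: a demonstrator is drawn uniformly from all individuals
#' that exploited a patch in the previous round (any strategy, any sex,
#' self included), and the learner stores the expected payoff of the
#' demonstrator's patch, computed from the *current* payoff and occupancy.
#' If nobody exploited in the previous round the learner falls back to
#' [individual_learn()].
#'
#' @inheritParams individual_learn
#' @param prev_patch integer vector: the patch each individual exploited
#'   last round, `NA` for individuals that did not exploit.
#' @return The individual with its memory updated; attribute `"patch"`
#'   records the observed patch and attribute `"social"` whether a
#'   demonstrator was available.
#' @export
social_learn <- function(ind, env, occupancy, prev_patch) {
  demos <- which(!is.na(prev_patch))
  if (length(demos) == 0) {
    ind <- individual_learn(ind, env, occupancy)
    attr(ind, "social") <- FALSE
    return(ind)
  }
  d <- demos[sample.int(length(demos), 1L)]
  m <- prev_patch[d]
  phat <- if (occupancy[m] > 0) env$payoffs[m] / occupancy[m] else env$payoffs[m]
  ind <- update_memory(ind, m, phat)
  attr(ind, "patch") <- m
  attr(ind, "social") <- TRUE
  ind
}

#' Execute one simulation round (reference engine)
#'
#' Runs the fixed within-round event order: (1) action draw; (2) exploiters
#' commit to their best remembered patch; (3) occupancy and scramble
#' payoffs resolved simultaneously; (4) learners observe individually or
#' socially using the current payoffs and occupancy; (5) payoff histories
#' and ages advance; (6) environmental turnover; (7) mortality and
#' replacement.  This is the readable, per-operation composition of the
#' model; [run_single()] with `engine = "cpp"` runs the same algorithm in
#' C++ for full-scale simulations.
#'
#' @param pop an `sl_population`.
#' @param env an `sl_env`.
#' @param state an `sl_round_state` from the previous round (or
#'   [init_round_state()]).
#' @param config an `sl_config`.
#' @return A list with updated `population`, `env`, `state` and a one-row
#'   data.frame `record` of round summaries.  `state` describes the round
#'   just executed (actions, observed/exploited patches, collected
#'   payoffs) for the population *before* mortality and replacement.
#' @export
step_round <- function(pop, env, state, config) {
  n <- length(pop)
  n_patches <- length(env$payoffs)
  fp <- config$fitness
  skew <- config$skew

  # (1) + (2): actions, patch commitment
  acts <- draw_actions(pop, config$learn_prob)
  choices <- vapply(acts$exploiters, function(i) best_remembered_patch(pop[[i]]),
                    integer(1))
  names(choices) <- acts$exploiters

  # (3) simultaneous exploitation
  res <- resolve_exploitation(pop, choices, env)
  pop <- res$population
  occupancy <- res$occupancy
  collected <- res$collected

  # (4) learning with current payoffs and occupancy
  action <- rep(NA_character_, n)
  patch <- rep(NA_integer_, n)
  action[acts$exploiters] <- "exploit"
  patch[acts$exploiters] <- choices
  for (i in acts$learners) {
    go_social <- FALSE
    if ((identical(config$naive_learning, "alpha") || !(i %in% acts$forced)) &&
        !isTRUE(config$force_individual_learning) &&
        pop[[i]]$alpha > 0) {
      go_social <- if (pop[[i]]$alpha >= 1) TRUE else runif(1) < pop[[i]]$alpha
    }
    if (go_social) {
      pop[[i]] <- social_learn(pop[[i]], env, occupancy, state$prev_patch)
      action[i] <- if (isTRUE(attr(pop[[i]], "social")))
        "learn_social" else "learn_individual"
    } else {
      pop[[i]] <- individual_learn(pop[[i]], env, occupancy)
      action[i] <- "learn_individual"
    }
    patch[i] <- attr(pop[[i]], "patch")
    attr(pop[[i]], "patch") <- NULL
    attr(pop[[i]], "social") <- NULL
  }

  # (5) histories and ages
  for (i in seq_len(n)) {
    pop[[i]] <- push_payoff(pop[[i]], collected[i], fp$window)
    pop[[i]]$age <- pop[[i]]$age + 1L
  }
  prev_patch <- ifelse(action == "exploit", patch, NA_integer_)

  # conservation audit (before turnover): collected payoffs equal the
  # payoffs of the occupied patches
  conservation_error <-
    abs(sum(collected) - sum(env$payoffs[occupancy > 0]))

  alpha <- vapply(pop, `[[`, numeric(1), "alpha")
  sexes <- vapply(pop, `[[`, character(1), "sex")
  ages <- vapply(pop, `[[`, integer(1), "age")
  idents <- vapply(pop, `[[`, numeric(1), "ident")
  is_social <- alpha >= 0.5
  exp_idx <- acts$exploiters
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  var_or_na <- function(x) if (length(x) > 1) var(x) else NA_real_
  coll_s <- collected[exp_idx][is_social[exp_idx]]
  coll_i <- collected[exp_idx][!is_social[exp_idx]]

  # (6) turnover
  env <- apply_turnover(env)

  # (7) mortality and replacement
  mort <- apply_mortality(pop, skew)
  pop <- replace_dead(pop, mort, config)

  alpha_after <- vapply(pop, `[[`, numeric(1), "alpha")
  sex_after <- vapply(pop, `[[`, character(1), "sex")
  record <- data.frame(
    freq_social = mean(alpha_after),
    freq_social_f = mean_or_na(alpha_after[sex_after == "female"]),
    freq_social_m = mean_or_na(alpha_after[sex_after == "male"]),
    n_learners = length(acts$learners),
    n_exploit_social = sum(is_social[exp_idx]),
    n_exploit_individual = sum(!is_social[exp_idx]),
    mean_collected_social = mean_or_na(coll_s),
    mean_collected_individual = mean_or_na(coll_i),
    var_collected_social = var_or_na(coll_s),
    var_collected_individual = var_or_na(coll_i),
    total_collected = sum(collected),
    deaths = length(mort$dead),
    conservation_error = conservation_error
  )

  # pre-mortality snapshot of the round's actors (for final-round tables)
  state <- structure(list(
    prev_patch = prev_patch,
    occupancy = occupancy,
    collected = collected,
    action = action,
    patch = patch,
    ident = idents,
    alpha = alpha,
    sex = sexes,
    age = ages
  ), class = "sl_round_state")
  # replacement clears the demonstrator record of the dead
  state$prev_patch[mort$dead] <- NA_integer_

  list(population = pop, env = env, state = state, record = record)
}
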