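make_informed_pop <- function(n, alpha = 0) {
  pop <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- new_individual(i, alpha, age = 10L)
    pop[[i]] <- update_memory(ind, i, 1.0)
  }
  structure(pop, class = "sl_population")
}

test_that("action draws split learners and exploiters as specified", {
  set.seed(1)
  pop <- make_informed_pop(50)
  a0 <- draw_actions(pop, 0)
  expect_length(a0$learners, 0)
  expect_length(a0$exploiters, 50)
  a1 <- draw_actions(pop, 1)
  expect_length(a1$learners, 50)

  # empty-memory exploiters are reassigned to learning
  naive <- structure(lapply(1:30, function(i) new_individual(i, 1)),
                     class = "sl_population")
  an <- draw_actions(naive, 0)
  expect_length(an$exploiters, 0)
  expect_setequal(an$forced, 1:30)

  # binomial expectation of the learner count (before reassignment)
  n <- 2000
  pop2 <- make_informed_pop(n)
  k <- length(draw_actions(pop2, 0.2)$learners)
  expect_lt(abs(k - n * 0.2), 3 * sqrt(n * 0.2 * 0.8))
})

test_that("scramble competition shares patch payoffs equally", {
  env <- create_environment(5, 4, 1, 0)
  env$payoffs <- c(4, 7, 1, 2, 3)
  pop <- make_informed_pop(3)
  choices <- c(`1` = 1L, `2` = 1L, `3` = 2L)
  res <- resolve_exploitation(pop, choices, env)
  expect_equal(res$collected[1:2], c(2, 2))  # 4 shared by two
  expect_equal(res$collected[3], 7)          # alone keeps the lot
  expect_equal(res$occupancy, c(2L, 1L, 0L, 0L, 0L))
  # conservation: total collected equals payoff of occupied patches
  expect_equal(sum(res$collected), sum(env$payoffs[res$occupancy > 0]))
  # memories updated to the realised per-capita share
  expect_equal(res$population[[1]]$memory[["1"]], 2)
  expect_equal(res$population[[3]]$memory[["2"]], 7)
})

test_that("individual learning observes expected payoff under occupancy", {
  env <- create_environment(1, 4, 1, 0)
  env$payoffs <- 4
  ind <- new_individual(1, 0)
  # unoccupied patch: expected payoff is the full patch payoff
  got <- individual_learn(ind, env, occupancy = 0L)
  expect_equal(attr(got, "patch"), 1L)  # M = 1: always that patch
  expect_equal(got$memory[["1"]], 4)
  # two current exploiters: expected payoff is the per-capita share
  got2 <- individual_learn(ind, env, occupancy = 2L)
  expect_equal(got2$memory[["1"]], 2)
})

test_that("social learning copies a previous-round exploiter's patch", {
  env <- create_environment(6, 4, 1, 0)
  env$payoffs <- c(1, 1, 1, 1, 6, 1)
  occupancy <- c(0L, 0L, 0L, 0L, 3L, 0L)
  prev <- c(NA, NA, 5L, NA)  # only individual 3 exploited last round
  ind <- new_individual(9, 1)
  got <- social_learn(ind, env, occupancy, prev)
  expect_true(attr(got, "social"))
  expect_equal(attr(got, "patch"), 5L)
  expect_equal(got$memory[["5"]], 2)  # 6 / 3 current occupancy
  # fresh observations overwrite stale entries
  ind2 <- update_memory(new_individual(10, 1), 5, 99)
  got2 <- social_learn(ind2, env, occupancy, prev)
  expect_equal(got2$memory[["5"]], 2)
  # nobody exploited last round: forced fallback to individual learning
  set.seed(2)
  got3 <- social_learn(ind, env, occupancy, rep(NA_integer_, 4))
  expect_false(attr(got3, "social"))
  expect_length(got3$memory, 1)
})

test_that("a round conserves payoffs, occupancy and population size", {
  cfg <- small_fixed_config()
  set.seed(31)
  env <- create_environment(cfg$n_patches, cfg$mean_payoff,
                            cfg$payoff_variance, cfg$turnover)
  pop <- init_population(cfg)
  state <- init_round_state(cfg$n_individuals, cfg$n_patches)
  ages0 <- vapply(pop, `[[`, integer(1), "age")
  for (t in 1:10) {
    out <- step_round(pop, env, state, cfg)
    expect_equal(out$record$conservation_error, 0, tolerance = 1e-12)
    expect_length(out$population, cfg$n_individuals)
    # occupancy counts exactly the exploiters
    expect_equal(sum(out$state$occupancy),
                 sum(out$state$action == "exploit"))
    # every individual acted exactly once
    expect_false(anyNA(out$state$action))
    pop <- out$population; env <- out$env; state <- out$state
  }
  # survivors age by exactly one round per round
  ages <- vapply(pop, `[[`, integer(1), "age")
  survivors <- vapply(pop, `[[`, numeric(1), "ident") <= cfg$n_individuals
  expect_true(all(ages[survivors] == ages0[survivors] + 10L))
})

test_that("social learners only ever learn previously exploited patches", {
  cfg <- small_fixed_config(turnover = 0.2)
  r <- run_single(cfg, seed = 17, engine = "r", log_individuals = TRUE)
  lg <- r$log
  for (t in 2:max(lg$round)) {
    soc <- lg$patch[lg$round == t & lg$action == "learn_social"]
    prev <- lg$patch[lg$round == t - 1 & lg$action == "exploit"]
    expect_true(all(soc %in% prev))
  }
})

test_that("all-individual populations match a disabled social channel", {
  cfg <- small_fixed_config(init_alpha = "all_individual")
  cfg$max_rounds <- 200L
  r1 <- run_single(cfg, seed = 5)
  cfg2 <- cfg
  cfg2$force_individual_learning <- TRUE
  r2 <- run_single(cfg2, seed = 5)
  expect_identical(r1$rounds, r2$rounds)
  expect_identical(r1$final, r2$final)
})
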