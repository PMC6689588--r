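aged_pop <- function(ages, alpha = 0, sex = "none") {
  pop <- vector("list", length(ages))
  for (i in seq_along(ages))
    pop[[i]] <- new_individual(i, alpha, sex, ages[i])
  structure(pop, class = "sl_population")
}

test_that("mortality combines random death and a hard age limit", {
  sk <- skew_config("fixed_proportion", death_prob = 0, max_age = 100)
  pop <- aged_pop(c(10, 50, 99))
  m <- apply_mortality(pop, sk)
  expect_length(m$dead, 0)

  pop2 <- aged_pop(c(10, 100, 150))
  m2 <- apply_mortality(pop2, sk)
  expect_setequal(m2$dead, c(2L, 3L))
  expect_equal(unname(m2$dead_by_sex["none"]), 2L)

  # binomial expectation of random deaths
  set.seed(4)
  sk3 <- skew_config("fixed_proportion", death_prob = 0.01)
  pop3 <- aged_pop(rep(1L, 5000))
  k <- length(apply_mortality(pop3, sk3)$dead)
  expect_lt(abs(k - 50), 3 * sqrt(5000 * 0.01 * 0.99))
})

test_that("the parent pool is the top beta proportion by fitness", {
  set.seed(9)
  fit <- runif(1000)
  p <- eligible_parents(1:1000, fit, beta = 0.01)
  expect_equal(nrow(p), 10)  # ceiling(0.01 * 1000)
  expect_setequal(p$id, order(fit, decreasing = TRUE)[1:10])
  expect_true(all(p$weight == 0.1))  # minimum income: equal weights

  pall <- eligible_parents(1:1000, fit, beta = 1)
  expect_equal(nrow(pall), 1000)    # beta = 1: no selection
  expect_true(all(pall$weight == 1 / 1000))

  # relative income: weights proportional to the fitness proxy
  pr <- eligible_parents(1:2, c(3, 1), beta = 1, criterion = "relative_income")
  expect_equal(pr$weight[pr$id == 1], 0.75)
  expect_equal(pr$weight[pr$id == 2], 0.25)

  # the ceiling rule guarantees a pool of at least one
  p1 <- eligible_parents(1:5, runif(5), beta = 0.01)
  expect_equal(nrow(p1), 1)
})

test_that("asexual offspring inherit alpha, flipped only by mutation", {
  parents <- aged_pop(rep(10L, 3), alpha = 1)
  pool <- data.frame(id = 1:3, fitness = 1, weight = 1 / 3)
  off <- reproduce_asexual(5, pool, parents, mutation_rate = 0, next_ident = 10L)
  expect_true(all(vapply(off, `[[`, numeric(1), "alpha") == 1))
  expect_equal(vapply(off, `[[`, numeric(1), "ident"), 10:14)
  # newborns are naive
  expect_true(all(vapply(off, function(o) length(o$memory), integer(1)) == 0))
  expect_true(all(vapply(off, `[[`, integer(1), "age") == 0))
  # mutation_rate 1 flips every offspring
  off2 <- reproduce_asexual(5, pool, parents, mutation_rate = 1)
  expect_true(all(vapply(off2, `[[`, numeric(1), "alpha") == 0))
})

test_that("sexual inheritance is strictly sex-linked", {
  pop <- structure(list(
    new_individual(1, alpha = 1, sex = "female", age = 10),
    new_individual(2, alpha = 0, sex = "male", age = 10)
  ), class = "sl_population")
  pf <- data.frame(id = 1, fitness = 1, weight = 1)
  pm <- data.frame(id = 2, fitness = 1, weight = 1)
  off <- reproduce_sexual(40, pf, pm, pop, mutation_rate = 0,
                          sexes = rep(c("female", "male"), 20))
  a <- vapply(off, `[[`, numeric(1), "alpha")
  s <- vapply(off, `[[`, character(1), "sex")
  expect_true(all(a[s == "female"] == 1))  # mothers to daughters
  expect_true(all(a[s == "male"] == 0))    # fathers to sons

  # free sex assignment is a fair coin
  set.seed(21)
  off2 <- reproduce_sexual(2000, pf, pm, pop, mutation_rate = 0)
  s2 <- vapply(off2, `[[`, character(1), "sex")
  expect_lt(abs(mean(s2 == "female") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("fixed-proportion replacement copies the dead exactly", {
  dead <- list(new_individual(1, 1, "none", 80),
               new_individual(2, 0, "none", 100))
  off <- replace_fixed(dead, next_ident = 5L)
  expect_equal(vapply(off, `[[`, numeric(1), "alpha"), c(1, 0))
  expect_true(all(vapply(off, `[[`, integer(1), "age") == 0))
  expect_length(off[[1]]$memory, 0)
})

test_that("fixed-proportion runs freeze the strategy composition", {
  cfg <- small_fixed_config()
  r <- run_single(cfg, seed = 3)
  expect_true(all(r$rounds$freq_social == 0.5))
  expect_equal(r$termination$cause, "max_rounds")
  expect_equal(sum(r$final$alpha == 1), cfg$n_individuals / 2)
})

test_that("without mutation a lost strategy never reappears", {
  cfg <- small_asexual_config(beta = 0.3)
  cfg$skew$mutation_rate <- 0
  cfg$init_alpha <- "all_individual"
  cfg$max_rounds <- 300L
  r <- run_single(cfg, seed = 13)
  expect_true(all(r$rounds$freq_social == 0))
  expect_equal(r$termination$cause, "fixation")
  expect_equal(r$termination$round, 1L)  # monomorphic from the start
})

test_that("drift under beta = 1 is symmetric around the initial frequency", {
  # no selection, symmetric mutation: the mean final frequency across many
  # small-population replicates stays near the 50/50 start
  cfg <- sim_config(n_individuals = 50L, n_patches = 40L,
                    payoff_variance = 100, turnover = 0.05,
                    skew = skew_config("asexual", beta = 1),
                    max_rounds = 400L)
  reps <- run_replicates(cfg, 40, base_seed = 77)
  finals <- vapply(reps, social_learning_proportion, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), max(3 * se, 0.05))
})

test_that("population size is constant in every mode", {
  for (cfg in list(small_fixed_config(), small_asexual_config(),
                   small_sexual_config())) {
    cfg$max_rounds <- 80L
    r <- run_single(cfg, seed = 8)
    with_rounds <- r$rounds
    expect_true(all(with_rounds$n_learners + with_rounds$n_exploit_social +
                      with_rounds$n_exploit_individual == cfg$n_individuals))
    expect_equal(nrow(r$final), cfg$n_individuals)
  }
})
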