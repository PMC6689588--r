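# Minimal synthetic run objects for exercising the summary statistics
# without simulating.
fake_run <- function(collected_social, collected_individual,
                     freq = 0.5, config = NULL) {
  final <- data.frame(
    ident = seq_len(length(collected_social) + length(collected_individual)),
    alpha = rep(c(1, 0), c(length(collected_social),
                           length(collected_individual))),
    sex = "none", age = 10L, action = "exploit", patch = 1L,
    collected = c(collected_social, collected_individual),
    stringsAsFactors = FALSE)
  structure(list(
    rounds = data.frame(round = 1, freq_social = freq,
                        freq_social_f = NA_real_, freq_social_m = NA_real_),
    final = final,
    termination = list(round = 1L, cause = "max_rounds"),
    config = config %||% sim_config(n_individuals = nrow(final),
                                    n_patches = 10L,
                                    skew = skew_config("fixed_proportion"))
  ), class = "sl_run")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical strategy outcomes give a variance ratio of exactly 1", {
  reps <- list(fake_run(c(1, 2, 3), c(1, 2, 3)),
               fake_run(c(2, 4, 6), c(2, 4, 6)),
               fake_run(c(1, 5, 9), c(1, 5, 9)))
  for (m in c("within_round", "replicate_means")) {
    vr <- variance_ratio(reps, method = m, n_boot = 50)
    expect_equal(vr$ratio, 1)
  }
})

test_that("the two variance readings measure what they claim", {
  reps <- list(fake_run(c(1, 1), c(0, 4)),
               fake_run(c(2, 2), c(1, 5)),
               fake_run(c(3, 3), c(2, 6)))
  # within a round: social entries are constant (var 0), individual vary
  w <- variance_ratio(reps, "within_round", n_boot = 50)
  expect_equal(w$var_social, 0)
  expect_equal(w$var_individual, 8)  # mean over replicates of var(x, x+4) = 8
  expect_equal(w$ratio, 0)
  # across replicates the strategy means are 1,2,3 and 2,3,4: equal vars
  r <- variance_ratio(reps, "replicate_means", n_boot = 50)
  expect_equal(r$ratio, 1)
  expect_equal(r$per_replicate_social, c(1, 2, 3))
  expect_equal(r$per_replicate_individual, c(2, 3, 4))
})

test_that("replicates missing a strategy are excluded with a warning", {
  lone <- fake_run(numeric(0), c(1, 2, 3))
  reps <- list(fake_run(c(1, 2), c(2, 3)), fake_run(c(2, 3), c(3, 4)), lone)
  expect_warning(vr <- variance_ratio(reps, n_boot = 50), "excluded")
  expect_equal(vr$n_replicates, 2)
  expect_error(suppressWarnings(variance_ratio(list(lone, lone), n_boot = 10)),
               "usable")
})

test_that("bootstrap intervals bracket the point estimate", {
  set.seed(6)
  reps <- lapply(1:30, function(i)
    fake_run(rnorm(50, 4, 0.5), rnorm(50, 4, 1)))
  vr <- variance_ratio(reps, n_boot = 500)
  expect_lt(vr$ci_ratio[1], vr$ratio)
  expect_gt(vr$ci_ratio[2], vr$ratio)
  expect_lt(vr$ratio, 1)  # social draws built narrower by construction
})

test_that("social-learning proportion summarises trailing rounds", {
  r <- fake_run(1, 1)
  r$rounds <- data.frame(round = 1:10, freq_social = seq(0.1, 1, by = 0.1),
                         freq_social_f = 1, freq_social_m = 0)
  expect_equal(social_learning_proportion(r), 1)
  expect_equal(social_learning_proportion(r, window = 4),
               mean(c(0.7, 0.8, 0.9, 1)))
  by_sex <- social_learning_proportion(r, by_sex = TRUE)
  expect_equal(unname(by_sex), c(1, 1, 0))
  # fixation runs report their absorbed frequency
  fix0 <- fake_run(1, 1, freq = 0)
  expect_equal(social_learning_proportion(fix0), 0)
  fix1 <- fake_run(1, 1, freq = 1)
  expect_equal(social_learning_proportion(fix1), 1)
})

test_that("yield distribution means satisfy the pooling identity", {
  reps <- list(fake_run(c(1, 3, 5), c(2, 2)),
               fake_run(c(2, 2), c(4, 6, 8)))
  yd <- yield_distribution(reps)
  total <- sum(yd$means$mean * yd$means$n)
  expect_equal(total / sum(yd$means$n), yd$overall_mean)
  expect_equal(sum(yd$means$n), 10)
  # histogram densities integrate to one for each strategy
  for (s in c("social", "individual")) {
    h <- yd$histogram[yd$histogram$strategy == s, ]
    expect_equal(sum(h$density) * 0.25, 1)
  }
  # a round with no exploiters is flagged
  empty <- fake_run(1, 1)
  empty$final <- empty$final[0, ]
  expect_warning(yield_distribution(list(empty)), "no exploiting")
})
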