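test_that("gamma moment matching gives the documented shape and scale", {
  expect_equal(gamma_params(4, 1), list(shape = 16, scale = 0.25))
  expect_equal(gamma_params(4, 100), list(shape = 0.16, scale = 25))
  # moment matching inverts: shape * scale = mean, shape * scale^2 = var
  for (m in c(0.5, 4, 20)) {
    for (v in c(0.1, 1, 100)) {
      gp <- gamma_params(m, v)
      expect_equal(gp$shape * gp$scale, m)
      expect_equal(gp$shape * gp$scale^2, v)
    }
  }
  expect_error(gamma_params(0, 1), "positive")
  expect_error(gamma_params(4, -1), "positive")
})

test_that("environment creation validates arguments", {
  expect_error(create_environment(0), ">= 1")
  expect_error(create_environment(10, mean_payoff = -4), "positive")
  expect_error(create_environment(10, payoff_variance = 0), "positive")
  expect_error(create_environment(10, turnover = 1.5), "probability")
})

test_that("generated payoffs recover the stated mean and variance", {
  set.seed(101)
  n <- 1e5
  for (v in c(1, 100)) {
    env <- create_environment(n, mean_payoff = 4, payoff_variance = v,
                              turnover = 0)
    expect_true(all(env$payoffs >= 0))
    # 3-standard-error bands using exact gamma moments:
    # se(mean) = sigma/sqrt(n); var(s^2) ~ (mu4 - sigma^4 (n-3)/(n-1))/n
    # with mu4 = sigma^4 (3 + 6/shape) for a gamma distribution
    se_mean <- sqrt(v / n)
    mu4 <- v^2 * (3 + 6 / env$shape)
    se_var <- sqrt((mu4 - v^2 * (n - 3) / (n - 1)) / n)
    expect_lt(abs(mean(env$payoffs) - 4), 3 * se_mean)
    expect_lt(abs(var(env$payoffs) - v), 3 * se_var)
  }
})

test_that("turnover redraws each patch independently with probability tau", {
  set.seed(7)
  env <- create_environment(500, 4, 100, turnover = 0)
  expect_identical(apply_turnover(env)$payoffs, env$payoffs)

  env$turnover <- 1
  env2 <- apply_turnover(env)
  expect_true(all(attr(env2, "changed")))
  expect_true(all(env2$payoffs != env$payoffs))

  # changed-patch counts over many rounds are Binomial(M, tau):
  # chi-square goodness of fit on pooled bins at alpha = 0.01
  M <- 500
  tau <- 0.1
  env$turnover <- tau
  counts <- replicate(1000, sum(attr(apply_turnover(env), "changed")))
  lo <- qbinom(0.001, M, tau); hi <- qbinom(0.999, M, tau)
  bins <- c(-Inf, lo:hi, Inf)
  obs <- table(cut(counts, bins))
  p <- diff(pbinom(c(-Inf, lo:hi, Inf), M, tau))
  keep <- p * 1000 >= 5
  o <- as.numeric(obs[keep])
  pp <- p[keep]
  if (any(!keep)) {
    o <- c(o, sum(obs[!keep]))
    pp <- c(pp, sum(p[!keep]))
  }
  gof <- chisq.test(o, p = pp / sum(pp))
  expect_gt(gof$p.value, 0.01)
})

test_that("payoffs replenish: exploitation never alters next-round payoffs", {
  # with turnover 0 the environment payoffs are invariant over a whole run
  cfg <- small_fixed_config(turnover = 0)
  r <- run_single(cfg, seed = 5, engine = "r", log_individuals = TRUE)
  lg <- r$log[r$log$action == "exploit", ]
  # per (round, patch): collected * occupancy recovers the patch payoff,
  # and it is identical in every round the patch is exploited
  occ <- stats::aggregate(collected ~ round + patch, lg, function(x)
    sum(x))
  pay <- tapply(occ$collected, occ$patch, function(x) max(x) - min(x))
  expect_true(all(pay < 1e-9))
})
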