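#' Reproductive-skew configuration
#'
#' Controls mortality and replacement.  Reproductive skew is the
#' proportion `beta` of mature individuals (ranked by the fitness proxy in
#' the current round) that is eligible to reproduce: small `beta` means
#' only the very best foragers breed (high skew), `beta = 1` means no
#' selection.  Under the `"minimum_income"` criterion everyone in the top
#' `beta` fraction is equally likely to be drawn as a parent; under
#' `"relative_income"` the draw is proportional to the fitness proxy.
#'
#' @param mode `"fixed_proportion"` (dead individuals replaced by naive
#'   copies of themselves; no selection, composition frozen), `"asexual"`
#'   (one parent, direct inheritance of alpha) or `"sexual"` (a mother and
#'   a father drawn from sex-specific pools; offspring inherit alpha from
#'   the same-sex parent).
#' @param criterion `"minimum_income"` or `"relative_income"`.
#' @param beta proportion in (0, 1\] eligible to reproduce (asexual mode).
#' @param beta_f,beta_m sex-specific proportions for sexual mode.
#' @param mutation_rate probability per offspring that the inherited binary
#'   alpha flips; the string `"1/N"` (default) resolves to 1/N.
#' @param death_prob per-round random death probability (default 0.01).
#' @param max_age deterministic death age in rounds (default 100).
#' @param strict_sex_ratio if `TRUE`, each dead individual is replaced by
#'   an offspring of the same sex (sex counts exactly constant); default
#'   `FALSE` assigns offspring sex independently with probability 0.5,
#'   which keeps the ratio at 1:1 only in expectation.
#' @return An object of class `sl_skew_config`.
#' @export
skew_config <- function(mode = c("fixed_proportion", "asexual", "sexual"),
                        criterion = c("minimum_income", "relative_income"),
                        beta = 1, beta_f = NULL, beta_m = NULL,
                        mutation_rate = "1/N", death_prob = 0.01,
                        max_age = 100L, strict_sex_ratio = FALSE) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  chk_beta <- function(b, nm) {
    if (!is.numeric(b) || length(b) != 1L || b <= 0 || b > 1)
      stop(sprintf("`%s` must lie in (0, 1]", nm), call. = FALSE)
  }
  if (mode == "sexual") {
    if (is.null(beta_f) || is.null(beta_m))
      stop("sexual mode needs `beta_f` and `beta_m`", call. = FALSE)
    chk_beta(beta_f, "beta_f")
    chk_beta(beta_m, "beta_m")
  } else {
    chk_beta(beta, "beta")
  }
  if (!identical(mutation_rate, "1/N") &&
      (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1))
    stop("`mutation_rate` must be a probability or the string \"1/N\"",
         call. = FALSE)
  if (death_prob < 0 || death_prob > 1)
    stop("`death_prob` must be a probability", call. = FALSE)
  if (max_age < 1) stop("`max_age` must be >= 1", call. = FALSE)
  structure(list(mode = mode, criterion = criterion, beta = beta,
                 beta_f = beta_f, beta_m = beta_m,
                 mutation_rate = mutation_rate, death_prob = death_prob,
                 max_age = as.integer(max_age),
                 strict_sex_ratio = isTRUE(strict_sex_ratio)),
            class = "sl_skew_config")
}

#' Apply mortality
#'
#' Each individual dies independently with probability `death_prob`, and
#' deterministically once its age reaches `max_age`.
#'
#' @param pop an `sl_population`.
#' @param skew an `sl_skew_config`.
#' @return A list with integer vectors `survivors` and `dead`, and a named
#'   count `dead_by_sex`.
#' @export
apply_mortality <- function(pop, skew) {
  n <- length(pop)
  ages <- vapply(pop, `[[`, integer(1), "age")
  dies <- ages >= skew$max_age
  if (skew$death_prob > 0)
    dies <- dies | (runif(n) < skew$death_prob)
  sexes <- vapply(pop, `[[`, character(1), "sex")
  list(survivors = which(!dies), dead = which(dies),
       dead_by_sex = c(female = sum(dies & sexes == "female"),
                       male = sum(dies & sexes == "male"),
                       none = sum(dies & sexes == "none")))
}

#' Parent pool under reproductive skew
#'
#' Ranks mature candidates by their fitness proxy and keeps the top
#' `ceiling(beta * n)` of them (ties at the cutoff broken uniformly at
#' random).  Sampling weights are equal under the minimum-income criterion
#' and proportional to the fitness proxy under the relative-income
#' criterion (uniform if all pool fitnesses are zero).
#'
#' @param ids integer identifiers (or indices) of the mature candidates.
#' @param fitness their fitness proxies, same order.
#' @param beta proportion in (0, 1\].
#' @param criterion `"minimum_income"` or `"relative_income"`.
#' @return A data.frame with columns `id`, `fitness` and normalised
#'   `weight`, top-ranked first.
#' @export
eligible_parents <- function(ids, fitness, beta,
                             criterion = c("minimum_income",
                                           "relative_income")) {
  criterion <- match.arg(criterion)
  n <- length(ids)
  if (n == 0L)
    return(data.frame(id = integer(0), fitness = numeric(0),
                      weight = numeric(0)))
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]", call. = FALSE)
  ord <- order(-fitness, runif(n))  # random tie-break
  k <- min(n, max(1L, ceiling(beta * n)))
  top <- ord[seq_len(k)]
  w <- if (criterion == "relative_income" && sum(fitness[top]) > 0)
    fitness[top] / sum(fitness[top]) else rep(1 / k, k)
  data.frame(id = ids[top], fitness = fitness[top], weight = w)
}

#' Asexual offspring
#'
#' One parent is drawn (with replacement, per pool weights) for each dead
#' individual.  Offspring directly inherit the parent's alpha, flipped
#' with probability `mutation_rate`, and start as newborns: age 0, empty
#' memory, empty history.
#'
#' @param n_offspring number of replacements needed.
#' @param pool a parent pool from [eligible_parents()].
#' @param parents an `sl_population` (to read parent alpha/sex from).
#' @param mutation_rate probability of flipping the inherited binary alpha.
#' @param next_ident first identifier to assign to the offspring.
#' @return A list of newborn `sl_individual`s.
#' @export
reproduce_asexual <- function(n_offspring, pool, parents, mutation_rate,
                              next_ident = 1L) {
  if (nrow(pool) == 0L) stop("empty parent pool", call. = FALSE)
  picks <- pool$id[sample.int(nrow(pool), n_offspring, replace = TRUE,
                              prob = pool$weight)]
  out <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    p <- parents[[picks[k]]]
    a <- p$alpha
    if (mutation_rate > 0 && runif(1) < mutation_rate) a <- 1 - a
    out[[k]] <- new_individual(next_ident + k - 1L, a, p$sex, 0L)
  }
  out
}

#' Sexual offspring with sex-linked inheritance
#'
#' For each replacement one mother and one father are drawn (with
#' replacement) from the sex-specific parent pools; the same individual
#' can be chosen repeatedly.  Offspring sex is assigned with probability
#' 0.5 each, and alpha is copied from the same-sex parent (mothers to
#' daughters, fathers to sons), flipped with probability `mutation_rate`.
#'
#' @param n_offspring number of replacements needed.
#' @param pool_f,pool_m parent pools from [eligible_parents()] for females
#'   and males.
#' @param parents an `sl_population`.
#' @param mutation_rate probability of flipping the inherited binary alpha.
#' @param next_ident first identifier for the offspring.
#' @param sexes optional character vector of imposed offspring sexes (the
#'   strict 1:1 option); default `NULL` draws each sex fairly.
#' @return A list of newborn `sl_individual`s.
#' @export
reproduce_sexual <- function(n_offspring, pool_f, pool_m, parents,
                             mutation_rate, next_ident = 1L, sexes = NULL) {
  if (nrow(pool_f) == 0L || nrow(pool_m) == 0L)
    stop("both parent pools must be nonempty", call. = FALSE)
  out <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    mother <- parents[[pool_f$id[sample.int(nrow(pool_f), 1L,
                                            prob = pool_f$weight)]]]
    father <- parents[[pool_m$id[sample.int(nrow(pool_m), 1L,
                                            prob = pool_m$weight)]]]
    s <- if (is.null(sexes)) {
      if (runif(1) < 0.5) "female" else "male"
    } else sexes[k]
    a <- if (s == "female") mother$alpha else father$alpha
    if (mutation_rate > 0 && runif(1) < mutation_rate) a <- 1 - a
    out[[k]] <- new_individual(next_ident + k - 1L, a, s, 0L)
  }
  out
}

#' Replace dead individuals by naive copies of themselves
#'
#' The fixed-proportion (no-selection) rule: each dead individual is
#' replaced by a newborn with the same alpha and sex but an empty memory
#' and history, so the strategy composition of the population is frozen
#' for the whole run.
#'
#' @param dead a list of the dead `sl_individual`s.
#' @param next_ident first identifier for the replacements.
#' @return A list of newborn `sl_individual`s.
#' @export
replace_fixed <- function(dead, next_ident = 1L) {
  out <- vector("list", length(dead))
  for (k in seq_along(dead))
    out[[k]] <- new_individual(next_ident + k - 1L, dead[[k]]$alpha,
                               dead[[k]]$sex, 0L)
  out
}

# Dispatch replacement by mode; returns the population with dead slots
# refilled (population size is constant in every mode).
replace_dead <- function(pop, mort, config) {
  dead <- mort$dead
  if (length(dead) == 0L) return(pop)
  skew <- config$skew
  fp <- config$fitness
  mu <- resolved_mutation_rate(config)
  next_ident <- max(vapply(pop, `[[`, numeric(1), "ident")) + 1

  newborns <- if (skew$mode == "fixed_proportion") {
    replace_fixed(pop[dead], next_ident)
  } else {
    mat_age <- maturity_age(fp)
    surv <- mort$survivors
    mature <- surv[vapply(pop[surv], `[[`, integer(1), "age") >= mat_age]
    if (skew$mode == "asexual") {
      if (length(mature) == 0L) {
        warning("no mature survivors; drawing parents from all survivors")
        pool <- data.frame(id = surv, fitness = 0,
                           weight = rep(1 / length(surv), length(surv)))
      } else {
        fit <- vapply(mature, function(i) fitness_proxy(pop[[i]], fp),
                      numeric(1))
        pool <- eligible_parents(mature, fit, skew$beta, skew$criterion)
      }
      reproduce_asexual(length(dead), pool, pop, mu, next_ident)
    } else {
      sexes <- vapply(pop, `[[`, character(1), "sex")
      pool_for <- function(sx, beta) {
        cand <- mature[sexes[mature] == sx]
        if (length(cand) == 0L) {
          sv <- surv[sexes[surv] == sx]
          if (length(sv) == 0L)
            stop("no surviving ", sx, "s to reproduce", call. = FALSE)
          warning("no mature surviving ", sx,
                  "s; drawing parents from all surviving ", sx, "s")
          return(data.frame(id = sv, fitness = 0,
                            weight = rep(1 / length(sv), length(sv))))
        }
        fit <- vapply(cand, function(i) fitness_proxy(pop[[i]], fp),
                      numeric(1))
        eligible_parents(cand, fit, beta, skew$criterion)
      }
      pf <- pool_for("female", skew$beta_f)
      pm <- pool_for("male", skew$beta_m)
      imposed <- if (skew$strict_sex_ratio) sexes[dead] else NULL
      reproduce_sexual(length(dead), pf, pm, pop, mu, next_ident, imposed)
    }
  }
  for (k in seq_along(dead)) pop[[dead[k]]] <- newborns[[k]]
  pop
}
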