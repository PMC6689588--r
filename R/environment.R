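#' Gamma parameters from a mean and variance
#'
#' The patchy environments are described by the mean and variance of their
#' payoff distribution; internally payoffs are gamma-distributed, with the
#' shape/scale parameterisation obtained by moment matching:
#' shape = mean^2 / variance, scale = variance / mean.
#'
#' @param mean positive mean payoff per patch.
#' @param variance positive payoff variance across patches.
#' @return A list with elements `shape` and `scale`.
#' @examples
#' gamma_params(4, 1)    # shape 16,   scale 0.25
#' gamma_params(4, 100)  # shape 0.16, scale 25
#' @export
gamma_params <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
    stop("`mean` must be a single positive number", call. = FALSE)
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0)
    stop("`variance` must be a single positive number", call. = FALSE)
  list(shape = mean^2 / variance, scale = variance / mean)
}

#' Create a patchy resource environment
#'
#' Draws the initial payoff of each of `n_patches` patches i.i.d. from a
#' gamma distribution with the given mean and variance.  A variance of 1
#' (with the default mean of 4) gives an "even" world in which most patches
#' are close to the mean; a variance of 100 gives an "uneven" world in which
#' a few patches are very rich and most are poor.
#'
#' Uses the current R random number stream; call [set.seed()] first for
#' reproducibility.
#'
#' @param n_patches number of patches M (>= 1).
#' @param mean_payoff mean patch payoff (resource units per round); default 4.
#' @param payoff_variance variance of the patch payoff distribution.
#' @param turnover per-patch, per-round probability that a payoff is redrawn
#'   (see [apply_turnover()]).
#' @return An object of class `sl_env`: a list with fields `payoffs`
#'   (numeric vector of length `n_patches`), `mean_payoff`,
#'   `payoff_variance`, `turnover`, `shape` and `scale`.
#' @examples
#' set.seed(1)
#' env <- create_environment(10, mean_payoff = 4, payoff_variance = 100,
#'                           turnover = 0.1)
#' env$payoffs
#' @export
create_environment <- function(n_patches, mean_payoff = 4,
                               payoff_variance = 100,
                               turnover = 10^-1.5) {
  if (!is.numeric(n_patches) || length(n_patches) != 1L || n_patches < 1)
    stop("`n_patches` must be a single integer >= 1", call. = FALSE)
  n_patches <- as.integer(n_patches)
  if (!is.numeric(turnover) || turnover < 0 || turnover > 1)
    stop("`turnover` must be a probability in [0, 1]", call. = FALSE)
  gp <- gamma_params(mean_payoff, payoff_variance)
  env <- list(
    payoffs = rgamma(n_patches, shape = gp$shape, scale = gp$scale),
    mean_payoff = mean_payoff,
    payoff_variance = payoff_variance,
    turnover = turnover,
    shape = gp$shape,
    scale = gp$scale
  )
  class(env) <- "sl_env"
  env
}

#' Apply environmental turnover
#'
#' Each patch independently, with probability `env$turnover`, has its payoff
#' replaced by a fresh draw from the generating gamma distribution; all
#' other payoffs are unchanged.  Turnover is the only process that alters
#' patch payoffs: exploitation never depletes a patch (payoffs replenish
#' every round).
#'
#' @param env an `sl_env` object.
#' @return The updated environment.  The logical attribute `"changed"`
#'   marks the patches whose payoff was redrawn this call (a redraw counts
#'   as a change even if the new value happens to equal the old one).
#' @export
apply_turnover <- function(env) {
  stopifnot(inherits(env, "sl_env"))
  changed <- runif(length(env$payoffs)) < env$turnover
  n <- sum(changed)
  if (n > 0)
    env$payoffs[changed] <- rgamma(n, shape = env$shape, scale = env$scale)
  attr(env, "changed") <- changed
  env
}

#' @export
print.sl_env <- function(x, ...) {
  cat(sprintf(
    "<sl_env> %d patches, mean payoff %g, variance %g, turnover %g\n",
    length(x$payoffs), x$mean_payoff, x$payoff_variance, x$turnover))
  invisible(x)
}
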