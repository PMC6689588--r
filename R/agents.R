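#' Create an individual
#'
#' An individual carries a social-learning propensity `alpha` (the
#' probability that a learning turn is social rather than individual), a
#' sex, an age in rounds, a patch memory (the last expected payoff observed
#' for each known patch), and a payoff history holding its most recent
#' per-round collected payoffs, most recent first.  Newborns start with age
#' 0, an empty memory and an empty history; memories are never inherited.
#'
#' @param ident unique identifier.
#' @param alpha social-learning propensity in \[0, 1\] (0 and 1 give the
#'   pure individual- and social-learning strategies used in evolutionary
#'   runs).
#' @param sex `"female"`, `"male"` or `"none"` (asexual populations).
#' @param age non-negative integer age in rounds.
#' @return An object of class `sl_individual`.
#' @export
new_individual <- function(ident, alpha, sex = "none", age = 0L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  sex <- match.arg(sex, c("female", "male", "none"))
  ind <- list(
    ident = ident,
    alpha = alpha,
    sex = sex,
    age = as.integer(age),
    memory = numeric(0),   # named by patch index
    history = numeric(0)   # most recent first, length <= fitness window
  )
  class(ind) <- "sl_individual"
  ind
}

#' Fitness-proxy parameters
#'
#' In the default `"windowed"` mode an individual's fitness proxy is the
#' exponentially discounted sum of its last `window` per-round collected
#' payoffs, F = sum_{j=0}^{window-1} exp(-discount * j) * p_{t-j}; rounds
#' spent learning contribute 0.  Individuals reach reproductive maturity at
#' age `window`.  The `"single_round"` mode uses only the payoff of the
#' current round (F = p_t), with maturity at age 1.
#'
#' @param window integer window length delta >= 1 (default 5).
#' @param discount temporal discount rate r >= 0 (default 0.2).
#' @param mode `"windowed"` or `"single_round"`.
#' @return An object of class `sl_fitness_params`.
#' @export
fitness_params <- function(window = 5L, discount = 0.2,
                           mode = c("windowed", "single_round")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || window < 1)
    stop("`window` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(discount) || discount < 0)
    stop("`discount` must be >= 0", call. = FALSE)
  structure(list(window = as.integer(window), discount = discount,
                 mode = mode),
            class = "sl_fitness_params")
}

#' Maturity age implied by the fitness parameters
#' @param params an `sl_fitness_params` object.
#' @return Integer age at which individuals become eligible to reproduce.
#' @export
maturity_age <- function(params) {
  if (params$mode == "windowed") params$window else 1L
}

#' Fitness proxy of an individual
#'
#' Computes the discounted payoff window (or the single-round payoff; see
#' [fitness_params()]).  In windowed mode the individual must have lived at
#' least `window` rounds; callers rank only mature individuals, so calling
#' this on an immature individual is an error rather than a zero.
#'
#' @param ind an `sl_individual`.
#' @param params an `sl_fitness_params` object.
#' @return A non-negative number.
#' @examples
#' p <- fitness_params(window = 5, discount = 0.2)
#' i <- new_individual(1, alpha = 0, age = 10)
#' i$history <- rep(1, 5)
#' fitness_proxy(i, p)  # sum(exp(-0.2 * 0:4)) = 3.6275...
#' @export
fitness_proxy <- function(ind, params) {
  stopifnot(inherits(params, "sl_fitness_params"))
  if (params$mode == "single_round") {
    if (length(ind$history) == 0) return(0)
    return(ind$history[[1L]])
  }
  if (ind$age < params$window)
    stop(sprintf(
      "individual %s is immature (age %d < window %d); filter to mature individuals before ranking",
      ind$ident, ind$age, params$window), call. = FALSE)
  w <- params$window
  h <- c(ind$history, numeric(w))[seq_len(w)]  # zero-pad short histories
  sum(exp(-params$discount * (seq_len(w) - 1)) * h)
}

#' Record a collected payoff in an individual's history
#'
#' Pushes the payoff collected this round (0 for rounds spent learning)
#' onto the front of the history, keeping at most `window` entries.
#'
#' @param ind an `sl_individual`.
#' @param payoff non-negative payoff collected this round.
#' @param window fitness window length.
#' @return The updated individual.
#' @export
push_payoff <- function(ind, payoff, window) {
  if (payoff < 0) stop("collected payoffs cannot be negative", call. = FALSE)
  ind$history <- c(payoff, ind$history)
  if (length(ind$history) > window)
    ind$history <- ind$history[seq_len(window)]
  ind
}

#' Store an observed expected payoff in memory
#'
#' Sets the remembered expected payoff for a patch, overwriting any
#' previous entry for that patch; other entries are untouched.  Information
#' persists until it is updated again or the individual dies.
#'
#' @param ind an `sl_individual`.
#' @param patch patch index (1-based).
#' @param observed observed expected payoff, >= 0.
#' @return The updated individual.
#' @export
update_memory <- function(ind, patch, observed) {
  if (!is.numeric(observed) || observed < 0)
    stop("`observed` must be a non-negative payoff", call. = FALSE)
  ind$memory[[as.character(patch)]] <- observed
  ind
}

#' Best remembered patch
#'
#' Returns the patch with the highest remembered expected payoff, breaking
#' ties uniformly at random; `NA` if the memory is empty.
#'
#' @param ind an `sl_individual`.
#' @return A patch index, or `NA_integer_` for an empty memory.
#' @export
best_remembered_patch <- function(ind) {
  m <- ind$memory
  if (length(m) == 0) return(NA_integer_)
  best <- which(m == max(m))
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  as.integer(names(m)[pick])
}

#' @export
print.sl_individual <- function(x, ...) {
  cat(sprintf("<sl_individual %s> alpha=%g sex=%s age=%d, %d patches known\n",
              x$ident, x$alpha, x$sex, x$age, length(x$memory)))
  invisible(x)
}
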