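#' Monte-Carlo simulation configuration
#'
#' @param n_steps Total chain steps (default 2e6).
#' @param burn_in Initial steps discarded before averaging (default 2e5).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param initial_i Starting number of cooperators; defaults to \code{N/2}
#'   at run time when \code{NULL}.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_steps = 2e6, burn_in = 2e5, seed, initial_i = NULL) {
  check_count(n_steps, "n_steps", lower = 1L)
  check_count(burn_in, "burn_in", lower = 0L)
  if (burn_in >= n_steps)
    stop("burn_in must be smaller than n_steps", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducibility",
                          call. = FALSE)
  check_count(seed, "seed")
  if (!is.null(initial_i)) check_count(initial_i, "initial_i")
  structure(list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), initial_i = initial_i),
            class = "sim_config")
}

#' One step of the aspiration chain
#'
#' Draws the next state of the birth-death chain from the current RNG
#' stream: \code{i + 1}, \code{i - 1} or \code{i} with probabilities
#' \eqn{T_i^+}, \eqn{T_i^-}, \eqn{T_i^0}. The state never leaves
#' \code{[0, N]}.
#'
#' @inheritParams transition_probs
#' @return The next cooperator count.
#' @export
mc_step <- function(i, gp, ap, tab = payoff_table(gp)) {
  tr <- transition_probs(i, gp, ap, tab)
  u <- stats::runif(1)
  if (u < tr[["Tplus"]]) i + 1L
  else if (u < tr[["Tplus"]] + tr[["Tminus"]]) i - 1L
  else i
}

#' Monte-Carlo estimate of the average abundance
#'
#' Simulates a single long trajectory of the aspiration chain (valid by
#' ergodicity: the Fermi rates are interior, so the chain is irreducible for
#' any \eqn{\delta \in [0,1]}) and time-averages \eqn{j/N} after burn-in.
#' The standard error comes from 20 equal post-burn-in batch means. This
#' simulator is the package's independent cross-check of the analytic
#' stationary results.
#'
#' @inheritParams transition_probs
#' @param sim A [sim_config()].
#' @param n_batches Number of batches for the batch-means standard error
#'   (default 20).
#' @param trajectory_file Optional path; when given, the trajectory is
#'   written as a CSV with columns \code{step, i}.
#' @return An object of class \code{"sim_estimate"}: list with
#'   \code{abundance_mean}, \code{std_error}, \code{empirical_dist} (visit
#'   frequencies over \code{j = 0..N}, summing to 1), and the config.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' ap <- aspiration_params(omega = 4, alpha = 1, delta = 0.03)
#' est <- estimate_abundance(gp, ap, sim_config(n_steps = 5e4,
#'                                              burn_in = 5e3, seed = 1))
#' est$abundance_mean
#' @export
estimate_abundance <- function(gp, ap, sim, n_batches = 20L,
                               trajectory_file = NULL) {
  stopifnot(inherits(gp, "game_params"), inherits(ap, "aspiration_params"),
            inherits(sim, "sim_config"))
  N <- gp$N
  i0 <- if (is.null(sim$initial_i)) N %/% 2L else sim$initial_i
  if (i0 < 0L || i0 > N) stop("initial_i must lie in 0..N", call. = FALSE)

  # Precompute the transition probabilities for every state once; the chain
  # itself is then a table lookup per step.
  tab <- payoff_table(gp)
  prof <- payoff_profiles(gp, tab)                 # pi_A(i+1), pi_B(i), i=0..N-1
  iall <- 0:N
  fB <- c(fermi(prof$piB, ap), 0)                  # pi_B(N) never used: T+(N)=0
  fA <- c(0, fermi(prof$piA_next, ap))             # pi_A(0) never used: T-(0)=0
  Tp <- (1 - ap$delta) * (N - iall) / N * fB + ap$delta * (N - iall) / N
  Tm <- (1 - ap$delta) * iall / N * fA + ap$delta * iall / N

  set.seed(sim$seed)
  u <- stats::runif(sim$n_steps)
  traj <- integer(sim$n_steps)
  i <- i0
  for (t in seq_len(sim$n_steps)) {
    if (u[t] < Tp[i + 1L]) i <- i + 1L
    else if (u[t] < Tp[i + 1L] + Tm[i + 1L]) i <- i - 1L
    traj[t] <- i
  }

  keep <- traj[(sim$burn_in + 1L):sim$n_steps]
  xbar <- mean(keep) / N
  n_batches <- max(2L, as.integer(n_batches))
  bsize <- length(keep) %/% n_batches
  bm <- vapply(seq_len(n_batches), function(b)
    mean(keep[((b - 1L) * bsize + 1L):(b * bsize)]) / N, numeric(1))
  se <- stats::sd(bm) / sqrt(n_batches)
  emp <- tabulate(keep + 1L, nbins = N + 1L) / length(keep)

  if (!is.null(trajectory_file))
    utils::write.csv(data.frame(step = seq_along(traj), i = traj),
                     trajectory_file, row.names = FALSE)

  structure(list(abundance_mean = xbar, std_error = se,
                 empirical_dist = emp, config = sim),
            class = "sim_estimate")
}

#' @export
print.sim_estimate <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo abundance estimate: X_A = %.5f (batch-means SE %.2g)\n",
    x$abundance_mean, x$std_error))
  cat(sprintf("  %d steps, %d burn-in, seed %d\n", x$config$n_steps,
              x$config$burn_in, x$config$seed))
  invisible(x)
}
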