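#' Game parameters for the threshold public goods game
#'
#' Bundles the structural parameters of the multi-player threshold public
#' goods game played in a finite well-mixed population: groups of size
#' \code{d} are sampled from a population of size \code{N}; the common pot
#' pays out, multiplied by \code{r}, only when at least \code{m} of the
#' \code{d} members contribute the endowment \code{c}; and a fraction
#' \code{tau} of every realised payoff is surrendered to a group pot that is
#' redistributed equally among the \code{d} members (the "second-order
#' payment").
#'
#' @param N Population size (integer, \code{N >= d}).
#' @param d Group size (integer, \code{2 <= d <= N}).
#' @param m Cooperation threshold (integer, \code{1 <= m <= d}). \code{m = d}
#'   is admitted; in that case the defector payoff vector is identically zero
#'   because a group containing a defector can never reach the threshold.
#' @param r Multiplication factor applied to the common pot (\code{r > 0}).
#' @param c Endowment / contribution cost in payoff units (\code{c > 0}).
#' @param tau Redistribution proportion in \code{[0, 1]}. \code{tau = 0}
#'   recovers the plain threshold public goods game. Values with
#'   \code{tau > r} are permitted but reverse the payoff ordering and emit a
#'   warning.
#'
#' @return An object of class \code{"game_params"}.
#' @seealso [aspiration_params()], [payoff_table()]
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' gp
#' @export
game_params <- function(N, d, m, r, c = 1, tau = 0) {
  check_count(N, "N", lower = 2L)
  check_count(d, "d", lower = 2L)
  check_count(m, "m", lower = 1L)
  if (d > N) stop("group size d = ", d, " exceeds population size N = ", N,
                  " (require 2 <= d <= N)", call. = FALSE)
  if (m > d) stop("threshold m = ", m, " exceeds group size d = ", d,
                  " (require 1 <= m <= d)", call. = FALSE)
  check_scalar(r, "r"); check_scalar(c, "c"); check_scalar(tau, "tau")
  if (r <= 0) stop("multiplication factor r must be > 0 (got ", r, ")",
                   call. = FALSE)
  if (c <= 0) stop("cost c must be > 0 (got ", c, ")", call. = FALSE)
  if (tau < 0 || tau > 1)
    stop("redistribution proportion tau must lie in [0, 1] (got ", tau, ")",
         call. = FALSE)
  if (tau > r)
    warning("tau > r: redistribution exceeds the pot multiplier, ",
            "payoff ordering in k reverses", call. = FALSE)
  structure(list(N = as.integer(N), d = as.integer(d), m = as.integer(m),
                 r = r, c = c, tau = tau),
            class = "game_params")
}

#' Aspiration-dynamics parameters
#'
#' Parameters of the self-referential update rule: an individual compares its
#' expected payoff to the aspiration level \code{alpha} through a Fermi
#' function with sharpness \code{omega}, and with probability \code{delta}
#' switches strategy at random instead (mutation).
#'
#' @param omega Selection intensity (\code{omega >= 0}); \code{omega = 0} is
#'   neutral drift.
#' @param alpha Aspiration level, in payoff units.
#' @param delta Mutation rate in \code{[0, 1]}.
#'
#' @return An object of class \code{"aspiration_params"}.
#' @examples
#' aspiration_params(omega = 4, alpha = 1, delta = 0.03)
#' @export
aspiration_params <- function(omega, alpha = 1, delta = 0) {
  check_scalar(omega, "omega"); check_scalar(alpha, "alpha")
  check_scalar(delta, "delta")
  if (omega < 0) stop("selection intensity omega must be >= 0 (got ", omega,
                      ")", call. = FALSE)
  if (delta < 0 || delta > 1)
    stop("mutation rate delta must lie in [0, 1] (got ", delta, ")",
         call. = FALSE)
  structure(list(omega = omega, alpha = alpha, delta = delta),
            class = "aspiration_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Threshold public goods game parameters\n")
  cat(sprintf("  N = %d, d = %d, m = %d, r = %g, c = %g, tau = %g\n",
              x$N, x$d, x$m, x$r, x$c, x$tau))
  invisible(x)
}

#' @export
print.aspiration_params <- function(x, ...) {
  cat("Aspiration dynamics parameters\n")
  cat(sprintf("  omega = %g, alpha = %g, delta = %g\n",
              x$omega, x$alpha, x$delta))
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop(name, " must be a single integer (got ",
         paste(x, collapse = ","), ")", call. = FALSE)
  if (x < lower)
    stop(name, " must be >= ", lower, " (got ", x, ")", call. = FALSE)
  invisible(TRUE)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
  invisible(TRUE)
}
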